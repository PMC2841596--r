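test_that("normalize_affinity matches the 2x2 closed form", {
  S <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  norm <- normalize_affinity(S)
  expect_equal(as.matrix(norm$L), matrix(0.5, 2, 2),
               ignore_attr = TRUE)
  e <- eigen(as.matrix(norm$L), symmetric = TRUE)$values
  expect_equal(e, c(1, 0))

  # identity affinity normalizes to the identity
  I3 <- diag(3); dimnames(I3) <- list(letters[1:3], letters[1:3])
  expect_equal(as.matrix(normalize_affinity(I3)$L), diag(3),
               ignore_attr = TRUE)
})

test_that("top eigenvalue of a connected normalized matrix is 1", {
  set.seed(21)
  for (rep_i in 1:10) {
    n <- sample(5:15, 1)
    W <- random_weighted_graph(n, p = 0.9)
    norm <- normalize_affinity(affinity_from_adjacency(W))
    vals <- eigen(as.matrix(norm$L), symmetric = TRUE)$values
    expect_equal(max(vals), 1, tolerance = 1e-8)
    expect_true(all(vals >= -1 - 1e-10 & vals <= 1 + 1e-10))
  }
})

test_that("top_eigenpairs agrees with the dense solver on random matrices", {
  set.seed(33)
  for (rep_i in 1:10) {
    M <- matrix(rnorm(225), 15)
    M <- (M + t(M)) / 2
    full <- eigen(M, symmetric = TRUE)
    for (k in c(1, 3, 7, 12)) {
      got <- top_eigenpairs(M, k)
      expect_equal(got$values, full$values[seq_len(k)], tolerance = 1e-8)
      # eigenvectors up to sign
      for (i in seq_len(k)) {
        expect_equal(abs(sum(got$vectors[, i] * full$vectors[, i])), 1,
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("top_eigenpairs meets the residual contract through the sparse path", {
  set.seed(4)
  sim <- generate_planted(planted_spec(c(15, 15), seed = 4))
  S <- build_affinity(sim$records)
  norm <- normalize_affinity(S)
  eig <- top_eigenpairs(norm$L, 5)
  expect_equal(order(eig$values, decreasing = TRUE), 1:5)
  for (i in 1:5) {
    resid <- as.vector(norm$L %*% eig$vectors[, i]) -
      eig$values[i] * eig$vectors[, i]
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("select_k scans eigengap ratios correctly", {
  expect_equal(select_k(c(1.0, 0.99, 0.97, 0.50), 1.02), 2L)
  expect_equal(select_k(c(1.0, 0.5, 0.4), 1.02), 1L)
  # non-positive successor counts as an immediate gap
  expect_equal(select_k(c(1.0, 1.0, 0, -0.5), 1.02), 2L)
  # flat spectrum: automatic mode falls through with a warning
  expect_warning(k <- select_k(rep(0.9, 5), 1.02), "no eigengap")
  expect_equal(k, 5L)
  # bounded mode scans below k_max only
  expect_equal(select_k(c(1.0, 0.99, 0.97, 0.50), 1.02, k_max = 2), 2L)
  expect_equal(select_k(rep(0.9, 6), 1.02, k_max = 3), 3L)
  expect_error(select_k(numeric(0)), "empty")
})

test_that("raising epsilon never selects a smaller K when a gap exists", {
  # a smaller threshold is crossed no later than a bigger one, so for spectra
  # that do contain a gap at the larger epsilon, K(eps=1.02) <= K(eps=1.5)
  set.seed(12)
  for (rep_i in 1:20) {
    vals <- c(sort(runif(8, 0.5, 1), decreasing = TRUE),
              sort(runif(4, 0, 0.05), decreasing = TRUE))
    k_low <- select_k(vals, 1.02)
    k_high <- select_k(vals, 1.5)
    expect_lte(k_low, k_high)
  }
})

test_that("embedding rows are unit length, K=1 collapses to signs", {
  set.seed(2)
  M <- matrix(rnorm(100), 10)
  M <- (M + t(M)) / 2
  eig <- top_eigenpairs(M, 3)
  emb <- embed_eigenvectors(eig, 3)
  expect_equal(unname(sqrt(rowSums(emb$points^2))), rep(1, 10))
  emb1 <- embed_eigenvectors(eig, 1)
  expect_true(all(abs(abs(emb1$points) - 1) < 1e-12 | emb1$degenerate))
})

test_that("ideal two-block embedding collapses to two orthogonal vectors", {
  S <- as.matrix(Matrix::bdiag(matrix(1, 5, 5), matrix(1, 5, 5)))
  dimnames(S) <- list(sprintf("s%02d", 1:10), sprintf("s%02d", 1:10))
  eig <- top_eigenpairs(as.matrix(normalize_affinity(S)$L), 2)
  emb <- embed_eigenvectors(eig, 2)
  pts <- unique(round(emb$points, 6))
  expect_equal(nrow(pts), 2L)
  expect_equal(abs(sum(pts[1, ] * pts[2, ])), 0, tolerance = 1e-6)
})

test_that("orthogonal_init greedily picks mutually orthogonal points", {
  basis <- diag(3)
  idx <- orthogonal_init(basis, 3, seed = 1)
  expect_setequal(idx, 1:3)

  # orthogonal pair beats near-duplicates
  pts <- rbind(c(1, 0), c(0.999, 0.04), c(0, 1), c(0.998, 0.06))
  for (s in 1:5) {
    idx2 <- orthogonal_init(pts, 2, seed = s)
    expect_true(all(sort(idx2) %in% c(1, 3) | sort(idx2) %in% c(2, 3) |
                      sort(idx2) %in% c(3, 4)))
    expect_true(3 %in% idx2)  # the truly orthogonal direction is always taken
  }
  expect_equal(length(orthogonal_init(pts, 1, seed = 2)), 1L)
  expect_error(orthogonal_init(pts, 5), "fewer points")
})

test_that("kmeans_lloyd recovers separated blobs and handles fixed points", {
  set.seed(14)
  pts <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
               matrix(rnorm(40, 5, 0.3), ncol = 2))
  km <- kmeans_lloyd(pts, c(1L, 21L))
  expect_true(km$converged)
  expect_equal(length(unique(km$labels[1:20])), 1L)
  expect_equal(length(unique(km$labels[21:40])), 1L)
  expect_false(km$labels[1] == km$labels[21])
  # agrees with the reference implementation on this easy geometry
  ref <- stats::kmeans(pts, pts[c(1, 21), ], algorithm = "Lloyd")
  expect_equal(unname(table(km$labels, ref$cluster) > 0) %*% c(1, 1),
               matrix(1, 2, 1))

  # K = 1: centroid is the mean
  km1 <- kmeans_lloyd(pts, matrix(colMeans(pts), 1))
  expect_equal(km1$centers[1, ], colMeans(pts), ignore_attr = TRUE)

  # points equal to centroids: immediate fixed point
  fixed <- kmeans_lloyd(diag(3), diag(3))
  expect_true(fixed$converged)
  expect_equal(fixed$labels, 1:3)
  expect_equal(fixed$iterations, 1L)
})

test_that("automatic eigengap selection recovers c bridged cliques", {
  for (c_cliques in 2:6) {
    recs <- clique_records(rep(6, c_cliques))
    part <- spectral_cluster(build_affinity(recs),
                             spectral_opts(mode = "automatic", seed = 3))
    expect_equal(attr(part, "K"), c_cliques)
    got <- partition_sets(part)
    want <- bfs_components(names(part),
                           recs$query, recs$subject)
    expect_equal(got, want)
  }
})

test_that("exact mode on disjoint cliques returns the cliques", {
  recs <- clique_records(c(7, 6, 5))
  part <- spectral_cluster(build_affinity(recs),
                           spectral_opts(mode = "exact", k_exact = 3, seed = 5))
  expect_equal(partition_sets(part),
               bfs_components(names(part), recs$query, recs$subject))
})

test_that("small inputs skip the spectral stage as single clusters", {
  recs <- clique_records(4)
  part <- spectral_cluster(build_affinity(recs))
  expect_equal(length(unique(part)), 1L)
  expect_null(attr(part, "K"))
})

test_that("the pipeline is deterministic under a fixed seed", {
  sim <- generate_planted(planted_spec(c(15, 15, 15), seed = 6))
  S <- build_affinity(sim$records)
  p1 <- spectral_cluster(S, spectral_opts(seed = 123))
  p2 <- spectral_cluster(S, spectral_opts(seed = 123))
  expect_identical(p1, p2)
})
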