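test_that("mass fraction hits its analytic anchors", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["b", "a"] <- 1
  W["c", "d"] <- W["d", "c"] <- 1
  g <- similarity_graph(affinity_from_adjacency(W))
  one <- setNames(rep(1L, 4), letters[1:4])
  expect_equal(mass_fraction(g, one), 1)
  # one intra, one inter edge
  half <- setNames(c(1L, 1L, 1L, 2L), letters[1:4])
  expect_equal(mass_fraction(g, half), 0.5)
  # all singletons: zero (self-similarities excluded)
  singletons <- setNames(1:4, letters[1:4])
  expect_equal(mass_fraction(g, singletons), 0)
})

test_that("modularity anchors: one cluster scores zero, two cliques 0.5", {
  set.seed(19)
  for (rep_i in 1:5) {
    W <- random_weighted_graph(6, 0.6)
    g <- similarity_graph(affinity_from_adjacency(W))
    one <- setNames(rep(1L, 6), rownames(W))
    expect_lt(abs(modularity_score(g, one)), 1e-12)
  }
  # two disjoint 3-cliques with unit weights, clustered as the cliques
  W <- as.matrix(Matrix::bdiag(matrix(1, 3, 3), matrix(1, 3, 3)))
  diag(W) <- 0
  dimnames(W) <- list(letters[1:6], letters[1:6])
  g <- similarity_graph(affinity_from_adjacency(W))
  cliques <- setNames(rep(1:2, each = 3), letters[1:6])
  expect_equal(modularity_score(g, cliques), 0.5)
})

test_that("modularity and mass fraction match brute force over all partitions", {
  set.seed(23)
  for (n in c(5, 8)) {
    W <- random_weighted_graph(n, 0.5)
    g <- similarity_graph(affinity_from_adjacency(W))
    parts <- all_partitions(n)
    for (labels in parts[seq(1, length(parts), by = 7)]) {
      part <- setNames(labels, rownames(W))
      expect_lt(abs(modularity_score(g, part) - brute_modularity(W, labels)),
                1e-12)
      expect_lt(abs(mass_fraction(g, part) - brute_mass_fraction(W, labels)),
                1e-12)
    }
  }
})

test_that("modularity stays within [-1, 1] across random partitions", {
  set.seed(29)
  for (rep_i in 1:20) {
    n <- sample(4:10, 1)
    W <- random_weighted_graph(n, 0.6)
    g <- similarity_graph(affinity_from_adjacency(W))
    part <- setNames(sample(1:3, n, replace = TRUE), rownames(W))
    q <- modularity_score(g, part)
    expect_gte(q, -1); expect_lte(q, 1)
    # cross-check against the graph library's weighted modularity
    ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(q, igraph::modularity(ig, part[igraph::V(ig)$name],
                                       weights = igraph::E(ig)$weight),
                 tolerance = 1e-10)
  }
})

test_that("mass fraction never decreases when clusters merge", {
  set.seed(31)
  for (rep_i in 1:10) {
    W <- random_weighted_graph(8, 0.5)
    g <- similarity_graph(affinity_from_adjacency(W))
    part <- setNames(sample(1:4, 8, replace = TRUE), rownames(W))
    labs <- unique(part)
    if (length(labs) < 2) next
    merged <- part
    merged[merged == labs[2]] <- labs[1]
    expect_gte(mass_fraction(g, merged), mass_fraction(g, part))
  }
})

test_that("contingency_table counts and rates match hand calculation", {
  gold <- c(A = "f1", B = "f1", C = "f2")
  pred <- c(A = 1L, B = 1L, C = 1L)
  tab <- contingency_table(gold, pred)
  expect_equal(tab$n, 3L)
  expect_equal(unname(tab$counts[, 1]), c(2L, 1L))
  expect_equal(unname(tab$precision[, 1]), c(2 / 3, 1 / 3))
  expect_equal(unname(tab$recall[, 1]), c(1, 1))

  # identical partitions give a diagonal table
  tab2 <- contingency_table(gold, c(A = 1L, B = 1L, C = 2L))
  expect_equal(unname(sort(diag(tab2$counts))), c(1L, 2L))
  expect_error(contingency_table(gold, c(A = 1L, B = 1L)), "differ")
})

test_that("combined F-score matches hand-derived values", {
  gold <- c(A = 1L, B = 1L, C = 2L)
  expect_equal(combined_fscore(gold, gold), 1)
  expect_equal(combined_fscore(gold, c(A = 1L, B = 1L, C = 1L)), 0.7)
  # one family of 4 predicted as singletons: F = 2/(4+1)
  gold4 <- setNames(rep(1L, 4), letters[1:4])
  singles <- setNames(1:4, letters[1:4])
  expect_equal(combined_fscore(gold4, singles), 0.4)
})

test_that("F-score is 1 exactly for relabelings and below 1 otherwise", {
  set.seed(37)
  for (rep_i in 1:10) {
    n <- sample(5:30, 1)
    ids <- sprintf("x%02d", 1:n)
    part <- setNames(sample(1:4, n, replace = TRUE), ids)
    shuffled <- setNames(match(part, sample(unique(part))), ids)
    expect_equal(combined_fscore(part, shuffled), 1)
    other <- setNames(sample(1:4, n, replace = TRUE), ids)
    f <- combined_fscore(part, other)
    expect_gte(f, 0); expect_lte(f, 1)
    if (!identical(partition_sets(part), partition_sets(other)))
      expect_lt(f, 1)
  }
})

test_that("rearrange_matrix produces contiguous blocks ordered by size", {
  sim <- generate_planted(planted_spec(c(12, 8), density_inter = 0.1,
                                       seed = 10))
  S <- build_affinity(sim$records)
  ra <- rearrange_matrix(S, sim$gold)
  expect_equal(ra$boundaries, c(12L, 20L))
  M <- ra$matrix
  in1 <- M[1:12, 1:12][upper.tri(M[1:12, 1:12])]
  in2 <- M[13:20, 13:20][upper.tri(M[13:20, 13:20])]
  off <- M[1:12, 13:20]
  expect_gt(mean(c(in1, in2)), 10 * mean(off))

  # a random partition shows no block separation
  set.seed(11)
  rand <- setNames(sample(rep(1:2, c(12, 8))), names(sim$gold))
  rb <- rearrange_matrix(S, rand)
  M2 <- rb$matrix
  rin <- mean(M2[1:12, 1:12][upper.tri(M2[1:12, 1:12])])
  roff <- mean(M2[1:12, 13:20])
  expect_lt(rin / roff, 3)

  # single cluster: size-sort only, matrix is a permutation of the input
  ra1 <- rearrange_matrix(S, setNames(rep(1L, 20), names(sim$gold)))
  expect_equal(ra1$boundaries, 20L)
  expect_equal(sort(ra1$order), sort(rownames(S)))
})

test_that("hypergeometric enrichment p-values match the exact tail", {
  ids <- sprintf("y%03d", 1:100)
  part <- setNames(c(rep(1L, 5), rep(2L, 95)), ids)
  ann <- data.frame(id = ids, term = c(rep("T", 4), rep("U", 1),
                                       rep("T", 6), rep("U", 89)))
  enr <- cluster_enrichment(part, ann)
  row <- enr$tests[enr$tests$cluster == 1 & enr$tests$term == "T", ]
  # exact upper tail: P[X >= 4], X ~ Hypergeom(N=100, K=10, n=5)
  # = (choose(10,4)*90 + choose(10,5)) / choose(100,5) = 2.5438e-4
  oracle <- sum(dhyper(4:5, 10, 90, 5))
  expect_equal(row$p, oracle, tolerance = 1e-10)
  expect_equal(row$p, 2.5438e-4, tolerance = 1e-4)

  # a term carried by everyone is never enriched
  ann_all <- data.frame(id = ids, term = "Z")
  enr2 <- cluster_enrichment(part, ann_all)
  expect_true(all(enr2$tests$p == 1))
})

test_that("BH adjustment follows the step-up procedure", {
  ids <- letters[1:9]
  part <- setNames(rep(1:3, each = 3), ids)
  # three clusters, one term each with controlled raw p-values is awkward to
  # stage exactly; check p.adjust consistency on the emitted family instead
  sim <- generate_planted(planted_spec(c(6, 6), seed = 3))
  ann <- data.frame(id = names(sim$gold),
                    term = sample(c("a", "b", "c"), 12, replace = TRUE))
  enr <- cluster_enrichment(sim$gold, ann)
  expect_equal(enr$tests$p_adj, p.adjust(enr$tests$p, "BH"))
  expect_true(all(enr$tests$p_adj >= enr$tests$p))
  # the documented worked values for the step-up rule
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
})

test_that("enrichment summary ratios are restricted to eligible clusters", {
  ids <- sprintf("z%02d", 1:12)
  part <- setNames(c(rep(1L, 6), rep(2L, 4), rep(3L, 2)), ids)
  ann <- data.frame(id = ids[1:10], term = c(rep("T", 6), rep("U", 4)))
  enr <- cluster_enrichment(part, ann, min_cluster_size = 3)
  # cluster 3 has 0 annotated members and is excluded entirely
  expect_equal(sort(enr$clusters$cluster), c(1L, 2L))
  expect_equal(enr$summary$size_total, 10L)
  expect_gte(enr$summary$count_ratio, 0)
  expect_lte(enr$summary$count_ratio, 1)
  expect_error(cluster_enrichment(part, data.frame(id = "nope", term = "T")),
               "no annotated ids")
})
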