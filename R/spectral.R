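#' Options for the spectral clustering pipeline
#'
#' @param mode How the number of clusters K is chosen: `"automatic"` scans
#'   eigengaps over the whole computed spectrum; `"bounded"` scans at most
#'   `k_max` eigenvalues and falls back to `k_max` when no gap is found;
#'   `"exact"` uses `k_exact` as given.
#' @param epsilon Eigengap ratio threshold; K is the smallest k with
#'   `lambda_k / lambda_{k+1} > epsilon`. Default 1.02. Larger values tend to
#'   produce finer clusterings.
#' @param k_max Upper bound on K for bounded mode.
#' @param k_exact Fixed K for exact mode.
#' @param min_component_size Components smaller than this are peeled off
#'   before the spectral stage and re-attached as final clusters (default 5).
#' @param bridge_weight Weight of the random bridging edges, in (0, 0.01).
#' @param seed Integer seed controlling bridging, eigensolver start vector
#'   and k-means initialization.
#' @param max_eigen In automatic mode, at most `min(n - 1, max_eigen)`
#'   eigenpairs are computed before the gap scan (default 200).
#' @param kmeans_max_iter,kmeans_tol Lloyd iteration limits.
#' @return A list of class `"spectral_opts"`.
#' @export
spectral_opts <- function(mode = c("automatic", "bounded", "exact"),
                          epsilon = 1.02, k_max = NULL, k_exact = NULL,
                          min_component_size = 5L, bridge_weight = 0.005,
                          seed = 1L, max_eigen = 200L,
                          kmeans_max_iter = 300L, kmeans_tol = 1e-6) {
  mode <- match.arg(mode)
  if (epsilon <= 1) stop("epsilon must exceed 1")
  if (mode == "bounded" && (is.null(k_max) || k_max < 1L))
    stop("bounded mode requires k_max >= 1")
  if (mode == "exact" && (is.null(k_exact) || k_exact < 1L))
    stop("exact mode requires k_exact >= 1")
  structure(list(mode = mode, epsilon = epsilon, k_max = k_max,
                 k_exact = k_exact,
                 min_component_size = as.integer(min_component_size),
                 bridge_weight = bridge_weight, seed = as.integer(seed),
                 max_eigen = as.integer(max_eigen),
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 kmeans_tol = kmeans_tol),
            class = "spectral_opts")
}

#' Degree-normalized similarity matrix
#'
#' Computes `L = D^(-1/2) S' D^(-1/2)` where `D` holds the vertex degrees
#' `d_i = sum_j s_ij` (diagonal included, so every degree is at least 1 and
#' strictly positive). For a connected graph the largest eigenvalue of `L`
#' is 1 with multiplicity one; the whole spectrum lies in [-1, 1].
#'
#' @param S Affinity matrix (reduced, i.e. after component peeling).
#' @return List with `L` (sparse symmetric matrix) and `degree`.
#' @export
normalize_affinity <- function(S) {
  S <- as_affinity(S)
  d <- Matrix::rowSums(S)
  if (any(d <= 0)) stop("isolated vertex with zero self-similarity")
  inv_sqrt <- Matrix::Diagonal(x = 1 / sqrt(d))
  L <- inv_sqrt %*% S %*% inv_sqrt
  L <- Matrix::forceSymmetric(L)
  dimnames(L) <- dimnames(S)
  list(L = L, degree = stats::setNames(d, rownames(S)))
}

#' Top eigenpairs of a symmetric matrix
#'
#' Computes the `k` algebraically largest eigenvalues and eigenvectors in
#' descending order. Large sparse problems go through the implicitly
#' restarted Arnoldi method (ARPACK, via [igraph::arpack()]); small problems,
#' or `k` close to `n`, use the dense symmetric solver. Each returned pair
#' satisfies `||L u - lambda u|| <= 1e-6`; the Arnoldi result is verified
#' against that residual and recomputed densely if it fails.
#'
#' @param L Symmetric matrix (sparse or dense), e.g. from
#'   [normalize_affinity()].
#' @param k Number of eigenpairs, `1 <= k <= n`.
#' @return List with `values` (descending) and `vectors` (columns aligned,
#'   unit norm).
#' @export
top_eigenpairs <- function(L, k) {
  if (is.list(L) && !is.null(L$L)) L <- L$L
  n <- nrow(L)
  stopifnot(k >= 1L, k <= n)
  dense <- function() {
    e <- eigen(as.matrix(L), symmetric = TRUE)
    list(values = e$values[seq_len(k)],
         vectors = e$vectors[, seq_len(k), drop = FALSE])
  }
  if (n < 10L || k > n - 2L) return(dense())
  res <- tryCatch({
    mult <- function(x, extra) as.vector(extra %*% x)
    ncv <- min(n, max(2L * k + 2L, 20L))
    a <- igraph::arpack(mult, extra = L, sym = TRUE,
                        options = list(n = n, nev = k, ncv = ncv,
                                       which = "LA", maxiter = 3000L))
    vals <- a$values
    vecs <- if (is.matrix(a$vectors)) a$vectors else matrix(a$vectors, ncol = 1L)
    ord <- order(vals, decreasing = TRUE)
    list(values = vals[ord], vectors = vecs[, ord, drop = FALSE])
  }, error = function(e) NULL)
  if (is.null(res)) return(dense())
  resid <- vapply(seq_len(k), function(i) {
    max(abs(as.vector(L %*% res$vectors[, i]) - res$values[i] * res$vectors[, i]))
  }, 0)
  if (any(resid > 1e-6)) return(dense())
  res
}

#' Select the number of clusters from the eigengap
#'
#' K is the smallest integer k such that `lambda_k / lambda_{k+1} > epsilon`,
#' scanning k = 1, 2, .... A non-positive `lambda_{k+1}` counts as an
#' immediate gap (ratios across zero or negative eigenvalues are
#' meaningless). In bounded mode only k < `k_max` is scanned and `k_max` is
#' returned when no gap is found; in automatic mode the full scan length is
#' returned with a warning.
#'
#' @param eigenvalues Numeric vector, descending.
#' @param epsilon Gap ratio threshold (> 1), default 1.02.
#' @param k_max Optional bound (bounded mode).
#' @return Integer K.
#' @export
select_k <- function(eigenvalues, epsilon = 1.02, k_max = NULL) {
  if (!length(eigenvalues)) stop("empty eigenvalue spectrum")
  if (epsilon <= 1) stop("epsilon must exceed 1")
  upper <- length(eigenvalues) - 1L
  if (!is.null(k_max)) upper <- min(upper, k_max - 1L)
  for (k in seq_len(max(upper, 0L))) {
    lk1 <- eigenvalues[k + 1L]
    if (lk1 <= 0 || eigenvalues[k] / lk1 > epsilon) return(k)
  }
  if (!is.null(k_max)) return(as.integer(min(k_max, length(eigenvalues))))
  warning("no eigengap found; using the full computed spectrum length")
  length(eigenvalues)
}

#' Row-normalized spectral embedding
#'
#' Takes the first `K` eigenvectors as columns and rescales every row to unit
#' Euclidean length. Rows with norm below 1e-12 cannot be normalized and are
#' flagged degenerate; the pipeline assigns them afterwards from their
#' strongest neighbor in the similarity graph.
#'
#' @param eigsys Result of [top_eigenpairs()].
#' @param K Embedding dimension, at most the number of computed pairs.
#' @return List with `points` (n x K matrix, unit rows) and `degenerate`
#'   (logical vector).
#' @export
embed_eigenvectors <- function(eigsys, K) {
  stopifnot(K >= 1L, K <= ncol(eigsys$vectors))
  U <- eigsys$vectors[, seq_len(K), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  degenerate <- norms < 1e-12
  scale <- ifelse(degenerate, 1, norms)
  list(points = U / scale, degenerate = degenerate)
}

#' Orthogonal centroid initialization
#'
#' Seeds k-means with data points chosen to be as mutually orthogonal as
#' possible: the first centroid is a uniformly drawn point; each next one is
#' the point minimizing the maximum absolute cosine similarity to the
#' centroids already chosen (ties by lowest row index).
#'
#' @param points Matrix of embedded points (unit rows).
#' @param K Number of centroids, at most `nrow(points)`.
#' @param seed Optional seed for the first draw.
#' @return Integer vector of `K` row indices.
#' @export
orthogonal_init <- function(points, K, seed = NULL) {
  n <- nrow(points)
  if (K > n) stop("fewer points than requested centroids")
  if (!is.null(seed)) set.seed(seed)
  chosen <- sample.int(n, 1L)
  if (K == 1L) return(chosen)
  norms <- sqrt(rowSums(points^2))
  norms[norms == 0] <- 1
  unit <- points / norms
  # running maximum |cos| to the chosen set, for every candidate
  maxcos <- abs(unit %*% unit[chosen, ])
  for (step in seq_len(K - 1L)) {
    cand <- setdiff(seq_len(n), chosen)
    nxt <- cand[which.min(maxcos[cand])]
    chosen <- c(chosen, nxt)
    maxcos <- pmax(maxcos, abs(unit %*% unit[nxt, ]))
  }
  chosen
}

#' Lloyd k-means with farthest-point re-seeding
#'
#' Standard Lloyd iterations: assign each point to the nearest centroid in
#' Euclidean distance, recompute centroids as means, stop when assignments
#' are unchanged, every centroid moved less than `tol`, or `max_iter` is
#' reached. A cluster that empties is re-seeded with the point farthest from
#' its current centroid, keeping exactly `K` clusters.
#'
#' @param points Numeric matrix, one row per point.
#' @param centers Initial centroid matrix, or integer row indices into
#'   `points`.
#' @param max_iter,tol Iteration limits.
#' @return List with `labels`, `centers`, `iterations`, `converged`.
#' @export
kmeans_lloyd <- function(points, centers, max_iter = 300L, tol = 1e-6) {
  points <- as.matrix(points)
  if (!is.matrix(centers)) centers <- points[centers, , drop = FALSE]
  K <- nrow(centers)
  stopifnot(K >= 1L)
  labels <- integer(nrow(points))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d2 <- outer(rowSums(points^2), rep(1, K)) -
      2 * points %*% t(centers) + outer(rep(1, nrow(points)), rowSums(centers^2))
    new_labels <- max.col(-d2, ties.method = "first")
    for (k in seq_len(K)) {
      if (!any(new_labels == k)) {
        far <- which.max(d2[cbind(seq_len(nrow(points)), new_labels)])
        new_labels[far] <- k
      }
    }
    new_centers <- centers
    for (k in seq_len(K)) {
      members <- new_labels == k
      if (any(members))
        new_centers[k, ] <- colMeans(points[members, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    same <- identical(new_labels, labels)
    labels <- new_labels
    centers <- new_centers
    if (same || shift < tol) { converged <- TRUE; break }
  }
  list(labels = labels, centers = centers, iterations = iter,
       converged = converged)
}

#' Spectral clustering of an affinity matrix
#'
#' The full pipeline: peel connected components smaller than
#' `min_component_size`, bridge the remaining components with light random
#' edges, build the degree-normalized matrix, compute the leading eigenpairs,
#' choose K (eigengap, bound, or fixed), row-normalize the spectral
#' embedding, run seeded k-means with orthogonal initialization, and finally
#' append every peeled component as its own cluster. Each input id is
#' assigned to exactly one cluster. If fewer than two vertices survive
#' peeling the spectral stage is skipped.
#'
#' @param S Affinity matrix, see [build_affinity()].
#' @param opts A [spectral_opts()] list.
#' @return Named integer vector of cluster labels, with attributes
#'   `"eigenvalues"` and `"K"` describing the spectral stage (both `NULL`
#'   when it was skipped).
#' @examples
#' toy <- toy_worked_example()
#' part <- spectral_cluster(build_affinity(toy$records),
#'                          spectral_opts(mode = "exact", k_exact = 3))
#' table(part)
#' @export
spectral_cluster <- function(S, opts = spectral_opts()) {
  S <- as_affinity(S)
  stopifnot(inherits(opts, "spectral_opts"))
  set.seed(opts$seed)
  graph <- similarity_graph(S)
  peel <- peel_small_components(graph, opts$min_component_size)
  retained <- peel$reduced$ids
  clusters <- peel$peeled

  eigenvalues <- NULL
  K <- NULL
  if (length(retained) >= 2L) {
    bridged <- bridge_components(peel$reduced, opts$bridge_weight)
    Sr <- graph_to_affinity(bridged)
    norm <- normalize_affinity(Sr)
    n <- length(retained)
    nev <- switch(opts$mode,
                  automatic = min(n, opts$max_eigen),
                  bounded = min(n, opts$k_max + 1L),
                  exact = min(n, opts$k_exact))
    eig <- top_eigenpairs(norm$L, nev)
    eigenvalues <- eig$values
    K <- switch(opts$mode,
                automatic = select_k(eigenvalues, opts$epsilon),
                bounded = select_k(eigenvalues, opts$epsilon, opts$k_max),
                exact = min(opts$k_exact, n))
    emb <- embed_eigenvectors(eig, K)
    ok <- !emb$degenerate
    labels <- integer(n)
    if (sum(ok) >= 1L) {
      pts <- emb$points[ok, , drop = FALSE]
      Keff <- min(K, nrow(pts))
      init <- orthogonal_init(pts, Keff)
      km <- kmeans_lloyd(pts, init, opts$kmeans_max_iter, opts$kmeans_tol)
      labels[ok] <- km$labels
    }
    if (any(!ok)) {
      # nearest non-degenerate neighbor in the retained similarity graph
      for (i in which(!ok)) {
        sims <- Sr[i, ]
        sims[i] <- 0
        sims[!ok] <- 0
        if (any(sims > 0)) {
          labels[i] <- labels[which.max(sims)]
        } else {
          labels[i] <- max(labels) + 1L
        }
      }
    }
    spectral_groups <- split(retained, labels)
    clusters <- c(clusters, unname(spectral_groups))
  } else if (length(retained) == 1L) {
    clusters <- c(clusters, list(retained))
  }

  part <- integer(0)
  for (k in seq_along(clusters)) {
    part <- c(part, stats::setNames(rep(k, length(clusters[[k]])),
                                    clusters[[k]]))
  }
  part <- relabel_partition(part)
  attr(part, "eigenvalues") <- eigenvalues
  attr(part, "K") <- K
  part
}
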