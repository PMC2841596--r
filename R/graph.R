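#' Weighted similarity graph from an affinity matrix
#'
#' Builds the weighted undirected graph view of an affinity matrix: the edge
#' set is the strictly positive off-diagonal entries (self-similarities are
#' excluded), vertex weights are `d_i = sum_j s_ij` over those edges, and the
#' total weight is `m = sum_{i > j} s_ij`.
#'
#' @param S Affinity matrix (sparse or dense, symmetric; see
#'   [build_affinity()]).
#' @return An object of class `"sim_graph"`: list with `ids`, `edges` (data
#'   frame from/to/weight with from < to), `vertex_weight`, `total_weight`.
#' @export
similarity_graph <- function(S) {
  S <- as_affinity(S)
  ids <- rownames(S)
  Sg <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  keep <- Sg@i < Sg@j & Sg@x > 0
  edges <- data.frame(from = ids[Sg@i[keep] + 1L],
                      to = ids[Sg@j[keep] + 1L],
                      weight = Sg@x[keep],
                      stringsAsFactors = FALSE)
  make_sim_graph(ids, edges)
}

make_sim_graph <- function(ids, edges) {
  stopifnot(all(edges$weight > 0))
  swap <- edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  d <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(edges)) {
    t1 <- tapply(edges$weight, edges$from, sum)
    t2 <- tapply(edges$weight, edges$to, sum)
    d[names(t1)] <- d[names(t1)] + t1
    d[names(t2)] <- d[names(t2)] + t2
  }
  structure(list(ids = ids, edges = edges, vertex_weight = d,
                 total_weight = sum(edges$weight)),
            class = "sim_graph")
}

#' @export
print.sim_graph <- function(x, ...) {
  cat(sprintf("Similarity graph: %d vertices, %d edges, total weight %.4g\n",
              length(x$ids), nrow(x$edges), x$total_weight))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = data.frame(name = graph$ids))
}

# Rebuild an affinity matrix (unit diagonal restored) from a sim_graph.
graph_to_affinity <- function(graph) {
  ids <- graph$ids
  n <- length(ids)
  i <- match(graph$edges$from, ids)
  j <- match(graph$edges$to, ids)
  Matrix::sparseMatrix(i = c(i, seq_len(n)), j = c(j, seq_len(n)),
                       x = c(graph$edges$weight, rep(1, n)),
                       dims = c(n, n), dimnames = list(ids, ids),
                       symmetric = TRUE)
}

#' Connected components of a similarity graph
#'
#' Maximal sets of vertices mutually reachable through edges of any positive
#' weight. Accepts a `"sim_graph"` or an affinity matrix.
#'
#' @param x A `"sim_graph"` or affinity matrix.
#' @return List with `components` (list of id vectors, decreasing size, ties
#'   broken by first id), `membership` (named integer vector), and
#'   `no` (component count).
#' @export
connected_components <- function(x) {
  if (!inherits(x, "sim_graph")) x <- similarity_graph(x)
  if (!length(x$ids))
    return(list(components = list(), membership = integer(), no = 0L))
  comp <- igraph::components(as_igraph(x))
  membership <- comp$membership[x$ids]
  groups <- split(names(membership), membership)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, "", 1L))
  groups <- unname(groups[ord])
  relabel <- stats::setNames(seq_along(groups),
                             vapply(groups, `[`, "", 1L))
  memb <- integer(length(x$ids))
  names(memb) <- x$ids
  for (k in seq_along(groups)) memb[groups[[k]]] <- k
  list(components = groups, membership = memb, no = length(groups))
}

#' Remove small connected components before the spectral stage
#'
#' Components with fewer than `min_size` sequences are unlikely to need
#' further subdivision, so they are peeled off; the reduced graph keeps only
#' the vertices of components of size `>= min_size`. Peeled components are
#' returned so they can be merged back as final clusters.
#'
#' @param graph A `"sim_graph"`.
#' @param min_size Minimum component size kept for spectral clustering
#'   (default 5).
#' @return List with `reduced` (a `"sim_graph"`) and `peeled` (list of id
#'   vectors).
#' @export
peel_small_components <- function(graph, min_size = 5L) {
  stopifnot(inherits(graph, "sim_graph"), min_size >= 1L)
  cc <- connected_components(graph)
  small <- cc$components[lengths(cc$components) < min_size]
  keep_ids <- sort(unlist(cc$components[lengths(cc$components) >= min_size]))
  keep_edges <- graph$edges[graph$edges$from %in% keep_ids &
                              graph$edges$to %in% keep_ids, , drop = FALSE]
  list(reduced = make_sim_graph(as.character(keep_ids), keep_edges),
       peeled = small)
}

#' Connect residual components with light random bridges
#'
#' Iterative eigensolvers converge poorly when the top eigenvalue has
#' multiplicity above one, which happens when the graph is disconnected. A
#' chain of `c - 1` random low-weight edges (weight below 0.01) over the `c`
#' components restores multiplicity one while perturbing the spectrum only
#' marginally. The component order and the endpoint chosen inside each
#' component are drawn from R's RNG; pass `seed` for reproducibility.
#'
#' @param graph A `"sim_graph"` with at least one vertex.
#' @param bridge_weight Weight of every added edge; must lie in (0, 0.01).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A connected `"sim_graph"`; the input is returned unchanged if it
#'   is already connected.
#' @export
bridge_components <- function(graph, bridge_weight = 0.005, seed = NULL) {
  stopifnot(inherits(graph, "sim_graph"))
  if (!length(graph$ids)) stop("cannot bridge an empty graph")
  if (!(bridge_weight > 0 && bridge_weight < 0.01))
    stop("bridge_weight must be in (0, 0.01)")
  cc <- connected_components(graph)
  if (cc$no <= 1L) return(graph)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(cc$no)
  ends <- vapply(cc$components[ord],
                 function(v) v[sample.int(length(v), 1L)], "")
  new_edges <- data.frame(from = ends[-length(ends)], to = ends[-1L],
                          weight = bridge_weight, stringsAsFactors = FALSE)
  make_sim_graph(graph$ids, rbind(graph$edges, new_edges))
}

records_partition <- function(ids, membership) {
  part <- integer(length(ids))
  names(part) <- ids
  part[names(membership)] <- membership
  relabel_partition(part)
}

# Contiguous labels 1..K ordered by decreasing cluster size, ties by the
# lexicographically smallest member id.
relabel_partition <- function(partition) {
  stopifnot(!is.null(names(partition)))
  groups <- split(names(partition), partition)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, "", 1L))
  groups <- groups[ord]
  out <- integer(length(partition))
  names(out) <- names(partition)
  for (k in seq_along(groups)) out[groups[[k]]] <- k
  out
}

partition_to_clusters <- function(partition) {
  groups <- split(names(partition), partition)
  lapply(unname(groups), sort)
}

#' Connected component analysis baseline
#'
#' Thresholding baseline: keep only pairs whose minimum-direction E-value is
#' at most `evalue_threshold`, then report the connected components of what
#' remains. The default threshold 1e-6 is the value classically used by
#' E-value-thresholding family detectors.
#'
#' @param records E-value records (query, subject, evalue).
#' @param evalue_threshold Largest E-value retained as an edge.
#' @return Named integer vector: cluster label per sequence id.
#' @export
cca_cluster <- function(records, evalue_threshold = 1e-6) {
  stopifnot(evalue_threshold > 0)
  ids <- record_ids(records)
  pairs <- min_evalue_pairs(records)
  pairs <- pairs[pairs$evalue <= evalue_threshold, , drop = FALSE]
  g <- make_sim_graph(ids, data.frame(from = pairs$id1, to = pairs$id2,
                                      weight = rep(1, nrow(pairs)),
                                      stringsAsFactors = FALSE))
  cc <- connected_components(g)
  records_partition(ids, cc$membership)
}

#' Average-linkage hierarchical clustering baseline
#'
#' Agglomerative clustering on the raw E-value scale with the average
#' distance metric. Pairs where BLAST reported no E-value are assigned
#' `missing_evalue` (default 10, the BLAST report ceiling); asymmetric pairs
#' are symmetrized by the minimum. Merging stops at the first merge whose
#' average linkage distance exceeds `cut_evalue`; the forest at that point is
#' the clustering (average linkage is monotone, so this equals cutting the
#' dendrogram at height `cut_evalue`).
#'
#' @param records E-value records.
#' @param cut_evalue Linkage distance above which merging stops (default 1e-6).
#' @param missing_evalue Distance substituted for unreported pairs.
#' @return Named integer vector: cluster label per sequence id.
#' @export
hierarchical_cluster <- function(records, cut_evalue = 1e-6,
                                 missing_evalue = 10) {
  stopifnot(cut_evalue > 0)
  ids <- record_ids(records)
  n <- length(ids)
  if (n < 1L) stop("no sequences to cluster")
  if (n == 1L) return(stats::setNames(1L, ids))
  D <- matrix(missing_evalue, n, n, dimnames = list(ids, ids))
  pairs <- min_evalue_pairs(records)
  if (nrow(pairs)) {
    i <- match(pairs$id1, ids); j <- match(pairs$id2, ids)
    D[cbind(i, j)] <- pairs$evalue
    D[cbind(j, i)] <- pairs$evalue
  }
  diag(D) <- 0
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  relabel_partition(stats::cutree(tree, h = cut_evalue))
}
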