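partition_from <- function(x) {
  if (is.list(x) && length(x) && all(vapply(x, is.character, TRUE))) {
    out <- integer(0)
    for (k in seq_along(x))
      out <- c(out, stats::setNames(rep(k, length(x[[k]])), x[[k]]))
    return(out)
  }
  if (is.null(names(x))) stop("partition must be a named vector (id -> label)")
  stats::setNames(as.integer(factor(x)), names(x))
}

check_partition_covers <- function(partition, ids) {
  missing <- setdiff(ids, names(partition))
  if (length(missing))
    stop("partition does not cover: ", paste(utils::head(missing, 5L),
                                             collapse = ", "))
}

#' Mass fraction of a clustering
#'
#' Fraction of the total edge weight that falls inside clusters:
#' `sum(s_ij * delta_ij) / sum(s_ij)` over the (off-diagonal) edges of the
#' graph, where `delta_ij` is 1 when i and j share a cluster.
#' Self-similarities are excluded from both sums, so the all-singletons
#' partition scores exactly 0 and the single-cluster partition exactly 1.
#' Maximal for the trivial one-cluster partition, so it is a sanity measure,
#' not a model selector.
#'
#' @param graph A `"sim_graph"` (or affinity matrix).
#' @param partition Named cluster label vector covering the graph's vertices.
#' @return Numeric in \[0, 1\].
#' @export
mass_fraction <- function(graph, partition) {
  if (!inherits(graph, "sim_graph")) graph <- similarity_graph(graph)
  partition <- partition_from(partition)
  check_partition_covers(partition, graph$ids)
  if (graph$total_weight <= 0) stop("graph has zero total edge weight")
  intra <- partition[graph$edges$from] == partition[graph$edges$to]
  sum(graph$edges$weight[intra]) / graph$total_weight
}

#' Weighted modularity of a clustering
#'
#' Newman's weighted modularity: the intra-cluster weight minus its
#' expectation under degree-preserving random rewiring,
#' `Q = (1/2m) * sum_ij (s_ij - d_i d_j / (2m)) delta_ij`
#' over ordered vertex pairs (self-pairs included with `s_ii = 0`), where
#' `d_i` is the vertex weight and `m` the total edge weight. The partition
#' placing every vertex in one cluster scores exactly 0; positive values mean
#' more intra-cluster weight than expected by chance.
#'
#' @inheritParams mass_fraction
#' @return Numeric in \[-1, 1\].
#' @export
modularity_score <- function(graph, partition) {
  if (!inherits(graph, "sim_graph")) graph <- similarity_graph(graph)
  partition <- partition_from(partition)
  check_partition_covers(partition, graph$ids)
  m <- graph$total_weight
  if (m <= 0) stop("graph has zero total edge weight")
  # aggregate per-cluster form: sum_c [ w_in(c)/m - (d(c)/2m)^2 ]
  intra <- partition[graph$edges$from] == partition[graph$edges$to]
  w_in <- tapply(graph$edges$weight[intra], partition[graph$edges$from][intra],
                 sum)
  d_c <- tapply(graph$vertex_weight, partition[names(graph$vertex_weight)], sum)
  sum(w_in) / m - sum((d_c / (2 * m))^2)
}

#' Contingency table between a gold-standard and a predicted clustering
#'
#' Cross-tabulates gold families (rows) against predicted clusters (columns)
#' and attaches the per-pair precision `p_ij = n_ij / n_.j` and recall
#' `r_ij = n_ij / n_i.`.
#'
#' @param gold,predicted Named label vectors over the same identifiers.
#' @return List of class `"cluster_contingency"` with `n`, `counts`,
#'   `row_totals`, `col_totals`, `precision`, `recall`.
#' @export
contingency_table <- function(gold, predicted) {
  gold <- partition_from(gold)
  predicted <- partition_from(predicted)
  extra_g <- setdiff(names(gold), names(predicted))
  extra_p <- setdiff(names(predicted), names(gold))
  if (length(extra_g) || length(extra_p))
    stop("id sets differ; only in gold: ",
         paste(utils::head(extra_g, 5L), collapse = ", "),
         "; only in predicted: ",
         paste(utils::head(extra_p, 5L), collapse = ", "))
  predicted <- predicted[names(gold)]
  counts <- unclass(table(gold = gold, predicted = predicted))
  row_totals <- rowSums(counts)
  col_totals <- colSums(counts)
  structure(list(n = length(gold), counts = counts,
                 row_totals = row_totals, col_totals = col_totals,
                 precision = sweep(counts, 2L, pmax(col_totals, 1L), "/"),
                 recall = sweep(counts, 1L, pmax(row_totals, 1L), "/")),
            class = "cluster_contingency")
}

#' Combined F-score against a gold standard
#'
#' Size-weighted best-match F-score between a predicted clustering and a
#' gold-standard family assignment:
#' `F = (1/n) * sum_i n_i. * max_j 2 p_ij r_ij / (p_ij + r_ij)`,
#' with the per-pair term taken as 0 when precision and recall are both
#' zero. Reaches its maximum of 1 exactly when the two partitions are
#' identical up to label renaming.
#'
#' @param gold Gold-standard labels, or a `"cluster_contingency"` (then
#'   `predicted` is ignored).
#' @param predicted Predicted labels.
#' @return Numeric in \[0, 1\].
#' @examples
#' gold <- c(a = 1, b = 1, c = 2)
#' combined_fscore(gold, c(a = 1, b = 1, c = 1))
#' @export
combined_fscore <- function(gold, predicted = NULL) {
  tab <- if (inherits(gold, "cluster_contingency")) gold
         else contingency_table(gold, predicted)
  f <- 2 * tab$precision * tab$recall / (tab$precision + tab$recall)
  f[!is.finite(f)] <- 0
  best <- apply(f, 1L, max)
  sum(tab$row_totals * best) / tab$n
}

#' Rearrange an affinity matrix by cluster blocks
#'
#' Permutes rows and columns so that same-cluster sequences are consecutive,
#' with clusters ordered by decreasing size (ties by first id). A good
#' clustering shows up as dark diagonal blocks in the resulting heatmap.
#'
#' @param S Affinity matrix.
#' @param partition Named cluster labels covering the matrix ids.
#' @return List with `matrix` (dense, permuted), `boundaries` (cumulative
#'   block end indices) and `order` (the id permutation).
#' @export
rearrange_matrix <- function(S, partition) {
  S <- as_affinity(S)
  partition <- partition_from(partition)
  check_partition_covers(partition, rownames(S))
  partition <- relabel_partition(partition[rownames(S)])
  groups <- partition_to_clusters(partition)
  ord <- unlist(groups)
  list(matrix = as.matrix(S[ord, ord]),
       boundaries = cumsum(lengths(groups)),
       order = ord)
}

#' Hypergeometric term enrichment of clusters
#'
#' For every cluster with at least `min_cluster_size` annotated members and
#' every annotation term occurring in it, tests over-representation with the
#' one-sided hypergeometric upper tail (population = all annotated ids,
#' successes = carriers of the term, draws = annotated cluster members).
#' P-values are corrected with Benjamini-Hochberg FDR over the full
#' (cluster, term) family by default (`adjust_by = "global"`), or within each
#' cluster (`adjust_by = "cluster"`). A cluster is significant when at least
#' one of its terms passes at level `alpha`.
#'
#' @param partition Named cluster labels.
#' @param annotations Two-column data frame (id, term) with one row per
#'   id-term assignment, or a named list of term vectors.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param min_cluster_size Smallest annotated cluster assessed (default 3).
#' @param adjust_by `"global"` or `"cluster"`.
#' @return List of class `"cluster_enrichment"`: `tests` (per cluster-term
#'   data frame with p and adjusted p), `clusters` (per-cluster significance),
#'   and `summary` with significant/total cluster counts and sizes and both
#'   ratios.
#' @export
cluster_enrichment <- function(partition, annotations, alpha = 0.05,
                               min_cluster_size = 3L,
                               adjust_by = c("global", "cluster")) {
  stopifnot(alpha > 0, alpha < 1)
  adjust_by <- match.arg(adjust_by)
  partition <- partition_from(partition)
  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- data.frame(
      id = rep(names(annotations), lengths(annotations)),
      term = as.character(unlist(annotations)), stringsAsFactors = FALSE)
  }
  annotations <- as.data.frame(annotations)[, 1:2]
  names(annotations) <- c("id", "term")
  annotations$id <- as.character(annotations$id)
  annotations$term <- as.character(annotations$term)
  annotations <- unique(annotations[annotations$id %in% names(partition), ])
  if (!nrow(annotations)) stop("no annotated ids overlap the partition")

  pop_ids <- unique(annotations$id)
  N <- length(pop_ids)
  term_count <- table(annotations$term)
  memb <- partition[annotations$id]

  rows <- list()
  for (k in sort(unique(partition))) {
    in_cluster <- annotations[memb == k, , drop = FALSE]
    size_k <- length(unique(in_cluster$id))
    if (size_k < min_cluster_size) next
    for (term in sort(unique(in_cluster$term))) {
      q <- sum(in_cluster$term == term)
      m_t <- term_count[[term]]
      p <- stats::phyper(q - 1L, m_t, N - m_t, size_k, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = k, term = term, cluster_size = size_k,
                   in_cluster = q, in_population = m_t, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no cluster reaches min_cluster_size among annotated ids")
  tests <- do.call(rbind, rows)
  if (adjust_by == "global") {
    tests$p_adj <- stats::p.adjust(tests$p, method = "BH")
  } else {
    tests$p_adj <- stats::ave(tests$p, tests$cluster,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  }
  tests$significant <- tests$p_adj <= alpha

  sizes <- tapply(tests$cluster_size, tests$cluster, `[`, 1L)
  sig <- tapply(tests$significant, tests$cluster, any)
  clusters <- data.frame(cluster = as.integer(names(sizes)),
                         size = as.integer(sizes),
                         significant = as.logical(sig))
  summary <- list(
    n_significant = sum(clusters$significant),
    n_total = nrow(clusters),
    count_ratio = sum(clusters$significant) / nrow(clusters),
    size_significant = sum(clusters$size[clusters$significant]),
    size_total = sum(clusters$size),
    size_ratio = sum(clusters$size[clusters$significant]) / sum(clusters$size))
  structure(list(tests = tests, clusters = clusters, summary = summary,
                 alpha = alpha, min_cluster_size = min_cluster_size),
            class = "cluster_enrichment")
}

#' @export
print.cluster_enrichment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Cluster enrichment (alpha = %g, min size %d):\n",
              x$alpha, x$min_cluster_size))
  cat(sprintf("  significant clusters: %d / %d (ratio %.3f)\n",
              s$n_significant, s$n_total, s$count_ratio))
  cat(sprintf("  significant sizes:    %d / %d (ratio %.3f)\n",
              s$size_significant, s$size_total, s$size_ratio))
  invisible(x)
}
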