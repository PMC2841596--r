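#' Cluster protein sequences from pairwise E-values
#'
#' Front end for the whole workflow. Takes pairwise E-value records (or a
#' prebuilt affinity matrix), converts E-values to relatedness probabilities
#' with the logistic `model`, and partitions the similarity graph with the
#' chosen method: spectral clustering of the degree-normalized affinity
#' matrix (the default), connected component analysis at an E-value
#' threshold, or average-linkage hierarchical clustering on the raw E-value
#' scale. Quality statistics (mass fraction, weighted modularity, and the
#' combined F-score when a gold standard is supplied) are computed on the
#' original, un-bridged similarity graph.
#'
#' @param x E-value records: a data frame with columns query, subject,
#'   evalue (see [read_blast_tab()], [generate_planted()]); or, for
#'   `method = "spectral"`, an affinity matrix.
#' @param method `"spectral"`, `"cca"` or `"hierarchical"`.
#' @param model Logistic similarity model used to build the affinity matrix;
#'   default [default_model()].
#' @param opts [spectral_opts()] for the spectral method.
#' @param gold Optional named gold-standard labels for F-score evaluation.
#' @param evalue_threshold CCA edge-removal threshold.
#' @param cut_evalue,missing_evalue Hierarchical baseline parameters.
#' @return An object of class `"specfam"` with the partition, per-cluster
#'   membership, quality scores, and (for the spectral method) the computed
#'   eigenvalues and selected K.
#' @examples
#' toy <- toy_worked_example()
#' fit <- specfam(toy$records, method = "cca", gold = toy$gold)
#' fit
#' @export
specfam <- function(x, method = c("spectral", "cca", "hierarchical"),
                    model = default_model(), opts = spectral_opts(),
                    gold = NULL, evalue_threshold = 1e-6,
                    cut_evalue = 1e-6, missing_evalue = 10) {
  method <- match.arg(method)
  cl <- match.call()
  is_affinity <- is.matrix(x) || methods::is(x, "Matrix")
  if (is_affinity && method != "spectral")
    stop("baseline methods need raw E-value records, not an affinity matrix")
  S <- if (is_affinity) as_affinity(x) else build_affinity(x, model)

  partition <- switch(method,
    spectral = spectral_cluster(S, opts),
    cca = cca_cluster(x, evalue_threshold),
    hierarchical = hierarchical_cluster(x, cut_evalue, missing_evalue))
  eigenvalues <- attr(partition, "eigenvalues")
  K <- attr(partition, "K")
  attributes(partition) <- list(names = names(partition))
  partition <- partition[rownames(S)]

  graph <- similarity_graph(S)
  mf <- if (graph$total_weight > 0) mass_fraction(graph, partition) else NA_real_
  q <- if (graph$total_weight > 0) modularity_score(graph, partition) else NA_real_
  fscore <- if (!is.null(gold)) combined_fscore(gold, partition) else NULL

  structure(list(partition = partition,
                 clusters = partition_to_clusters(relabel_partition(partition)),
                 method = method, n = length(partition),
                 K = K, eigenvalues = eigenvalues,
                 mass_fraction = mf, modularity = q, fscore = fscore,
                 affinity = S, graph = graph, opts = opts, model = model,
                 call = cl),
            class = "specfam")
}

#' @export
print.specfam <- function(x, ...) {
  cat(sprintf("Protein family clustering (%s): %d sequences in %d clusters\n",
              x$method, x$n, length(x$clusters)))
  cat(sprintf("  mass fraction %.4f, modularity %.4f\n",
              x$mass_fraction, x$modularity))
  if (!is.null(x$fscore))
    cat(sprintf("  combined F-score vs gold standard: %.4f\n", x$fscore))
  invisible(x)
}

#' @param object,x A `"specfam"` fit.
#' @param ... Unused.
#' @rdname specfam
#' @export
summary.specfam <- function(object, ...) {
  sizes <- lengths(object$clusters)
  out <- list(method = object$method, n = object$n,
              n_clusters = length(sizes), sizes = sizes,
              mass_fraction = object$mass_fraction,
              modularity = object$modularity, fscore = object$fscore,
              K = object$K, eigenvalues = object$eigenvalues)
  class(out) <- "summary.specfam"
  out
}

#' @export
print.summary.specfam <- function(x, ...) {
  cat(sprintf("%s clustering of %d sequences\n", x$method, x$n))
  cat(sprintf("Clusters: %d (sizes: %s)\n", x$n_clusters,
              paste(x$sizes, collapse = ", ")))
  if (!is.null(x$K))
    cat(sprintf("Spectral K = %d; leading eigenvalues: %s\n", x$K,
                paste(formatC(utils::head(x$eigenvalues, min(6L, length(x$eigenvalues))),
                              digits = 4, format = "f"), collapse = ", ")))
  cat(sprintf("Mass fraction: %.4f\nModularity:    %.4f\n",
              x$mass_fraction, x$modularity))
  if (!is.null(x$fscore))
    cat(sprintf("Combined F-score: %.4f\n", x$fscore))
  invisible(x)
}

#' Heatmap of the cluster-rearranged similarity matrix
#'
#' Plots the affinity matrix with rows and columns permuted so same-cluster
#' sequences are consecutive (greyscale, darker = more similar). Block
#' structure along the diagonal is the visual signature of a good
#' clustering.
#'
#' @param boundaries Draw cluster boundary lines.
#' @rdname specfam
#' @export
plot.specfam <- function(x, boundaries = TRUE, ...) {
  ra <- rearrange_matrix(x$affinity, x$partition)
  n <- nrow(ra$matrix)
  graphics::image(seq_len(n), seq_len(n), t(ra$matrix[n:1, , drop = FALSE]),
                  col = grDevices::gray(seq(1, 0, length.out = 256)),
                  xlab = "", ylab = "", axes = FALSE, useRaster = TRUE, ...)
  graphics::box()
  if (boundaries && length(ra$boundaries) > 1L) {
    b <- ra$boundaries[-length(ra$boundaries)] + 0.5
    graphics::abline(v = b, h = n - b + 1, col = "red", lwd = 0.5)
  }
  invisible(ra)
}

#' @export
as.data.frame.specfam <- function(x, ...) {
  data.frame(id = names(x$partition), cluster = unname(x$partition),
             stringsAsFactors = FALSE)
}
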