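#' Logistic E-value similarity model
#'
#' Constructs the logistic model mapping a BLAST E-value to the probability
#' that the two sequences are evolutionarily related. The model operates on
#' the feature `x = -log10(max(E, evalue_floor))`, so for a positive slope the
#' similarity decreases monotonically with the E-value. BLAST reports `E = 0`
#' for very strong hits; the floor keeps the log transform defined.
#'
#' @param intercept Intercept `a` of the linear predictor `a + b * x`.
#' @param slope Slope `b`; positive means smaller E-values map to higher
#'   similarity.
#' @param evalue_floor Positive E-value below which inputs are clamped before
#'   the log transform. Default `1e-180`.
#' @return An object of class `"logistic_similarity"`.
#' @seealso [fit_logistic()], [evalue_to_similarity()], [default_model()]
#' @export
similarity_model <- function(intercept, slope, evalue_floor = 1e-180) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept),
            is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(evalue_floor), length(evalue_floor) == 1L,
            evalue_floor > 0)
  structure(list(intercept = as.numeric(intercept),
                 slope = as.numeric(slope),
                 evalue_floor = as.numeric(evalue_floor)),
            class = "logistic_similarity")
}

#' @export
print.logistic_similarity <- function(x, ...) {
  cat("Logistic E-value similarity model\n")
  cat(sprintf("  s(E) = 1 / (1 + exp(-(%.4f + %.4f * x))),  x = -log10(max(E, %.3g))\n",
              x$intercept, x$slope, x$evalue_floor))
  if (x$slope > 0) {
    cat(sprintf("  posterior 0.5 at x = %.3f (E ~ %.3g)\n",
                -x$intercept / x$slope, 10^(x$intercept / x$slope)))
  }
  invisible(x)
}

#' Default similarity model
#'
#' Logistic coefficients obtained by fitting [fit_logistic()] to the bundled
#' synthetic training set ([generate_training_pairs()] with its default
#' intra/inter log10 E-value distributions, 10,000 pairs per class, seed 42).
#' A regression test refits the generator and checks agreement, so these
#' frozen numbers cannot silently drift from the generator they came from.
#' Override by fitting your own labelled pairs or constructing a
#' [similarity_model()] directly.
#'
#' @return A `"logistic_similarity"` model.
#' @export
default_model <- function() {
  similarity_model(intercept = .default_coef["intercept"],
                   slope = .default_coef["slope"])
}

# frozen from fit_logistic(generate_training_pairs(seed = 42)); see test suite
.default_coef <- c(intercept = -3.475281, slope = 0.733667)

#' Fit the E-value logistic model from labelled pairs
#'
#' Maximum-likelihood logistic regression of intra- vs inter-family labels on
#' the transformed E-value `x = -log10(max(E, evalue_floor))`. The fitted
#' posterior probability of the intra class is the similarity score used by
#' the clustering pipeline.
#'
#' When the two classes are linearly separable in `x` the likelihood has no
#' finite maximizer; the fit is then capped by rescaling the coefficients so
#' the largest absolute linear predictor over the training set is 30 (the
#' decision boundary is unchanged by rescaling) and a warning is raised.
#'
#' @param evalues Numeric vector of non-negative E-values.
#' @param labels Vector the same length as `evalues`, with values `"intra"`
#'   (same family) or `"inter"` (different family); logicals are accepted
#'   (`TRUE` = intra).
#' @param evalue_floor Clamp for the log transform, see [similarity_model()].
#' @return A `"logistic_similarity"` model.
#' @examples
#' pairs <- generate_training_pairs(n_per_class = 500, seed = 1)
#' fit_logistic(pairs$evalue, pairs$label)
#' @export
fit_logistic <- function(evalues, labels, evalue_floor = 1e-180) {
  evalues <- as.numeric(evalues)
  if (any(!is.finite(evalues)) || any(evalues < 0))
    stop("E-values must be finite and non-negative")
  if (is.logical(labels)) labels <- ifelse(labels, "intra", "inter")
  labels <- as.character(labels)
  if (!all(labels %in% c("intra", "inter")))
    stop("labels must be 'intra' or 'inter'")
  if (length(unique(labels)) < 2L)
    stop("degenerate training set: both intra and inter labels are required")
  if (length(evalues) != length(labels))
    stop("evalues and labels differ in length")

  x <- -log10(pmax(evalues, evalue_floor))
  y <- as.integer(labels == "intra")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  a <- unname(stats::coef(fit)[1L])
  b <- unname(stats::coef(fit)[2L])

  eta <- a + b * x
  fitted <- 1 / (1 + exp(-eta))
  separated <- all(abs(fitted - y) < 1e-6)
  if (separated) {
    if (max(abs(eta)) > 30) {
      # boundary -a/b is invariant under rescaling
      scale <- 30 / max(abs(eta))
      a <- a * scale
      b <- b * scale
    }
    warning("perfectly separated training classes; coefficients capped")
  }
  similarity_model(a, b, evalue_floor)
}

#' Transform E-values to similarity scores
#'
#' Evaluates the logistic posterior `sigma(a + b * x)` with
#' `x = -log10(max(E, evalue_floor))`. Strictly monotone decreasing in the
#' E-value when the slope is positive; output is strictly inside (0, 1).
#'
#' @param model A `"logistic_similarity"` model.
#' @param evalue Numeric vector of non-negative E-values.
#' @return Numeric vector of similarities in (0, 1).
#' @export
evalue_to_similarity <- function(model, evalue) {
  stopifnot(inherits(model, "logistic_similarity"))
  evalue <- as.numeric(evalue)
  if (any(!is.finite(evalue)) || any(evalue < 0))
    stop("E-values must be finite and non-negative")
  x <- -log10(pmax(evalue, model$evalue_floor))
  s <- 1 / (1 + exp(-(model$intercept + model$slope * x)))
  # keep the output strictly inside (0, 1) where the sigmoid saturates
  pmin(pmax(s, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

# Validate and canonicalize a record data.frame (query, subject, evalue).
as_records <- function(records) {
  records <- as.data.frame(records)
  if (ncol(records) < 3L)
    stop("records need three columns: query, subject, evalue")
  records <- records[, 1:3]
  names(records) <- c("query", "subject", "evalue")
  records$query <- as.character(records$query)
  records$subject <- as.character(records$subject)
  records$evalue <- as.numeric(records$evalue)
  if (any(!nzchar(records$query)) || any(!nzchar(records$subject)))
    stop("sequence identifiers must be non-empty")
  if (any(!is.finite(records$evalue)) || any(records$evalue < 0))
    stop("E-values must be finite and non-negative")
  records
}

# Minimum observed E-value per unordered pair, self-pairs dropped.
# Symmetrization rule: of the two BLAST directions (and any duplicate HSPs)
# keep the smaller E-value, i.e. the higher similarity.
min_evalue_pairs <- function(records) {
  records <- as_records(records)
  a <- pmin(records$query, records$subject)
  b <- pmax(records$query, records$subject)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; e <- records$evalue[keep]
  if (!length(a))
    return(data.frame(id1 = character(), id2 = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  key <- paste(a, b, sep = "\r")
  agg <- tapply(e, key, min)
  ord <- sort(names(agg))
  parts <- strsplit(ord, "\r", fixed = TRUE)
  data.frame(id1 = vapply(parts, `[`, "", 1L),
             id2 = vapply(parts, `[`, "", 2L),
             evalue = unname(agg[ord]),
             stringsAsFactors = FALSE)
}

record_ids <- function(records) {
  records <- as_records(records)
  sort(unique(c(records$query, records$subject)))
}

#' Build the symmetric affinity matrix from E-value records
#'
#' Assembles the sparse symmetric affinity matrix `S`. Every identifier seen
#' in `records` becomes a row/column (sorted, so the result does not depend
#' on record order). For each unordered pair the smaller E-value over both
#' BLAST directions and all HSPs is transformed with `model`; the main
#' diagonal is set to exactly 1 regardless of self-hits, and pairs never
#' reported stay structurally zero.
#'
#' @param records Data frame (or coercible) with columns query, subject,
#'   evalue, e.g. from [read_blast_tab()] or [generate_planted()].
#' @param model A `"logistic_similarity"` model; default [default_model()].
#' @return A symmetric sparse [Matrix::Matrix] with unit diagonal and the
#'   sequence identifiers as dimnames.
#' @examples
#' toy <- toy_worked_example()
#' S <- build_affinity(toy$records)
#' Matrix::isSymmetric(S)
#' @export
build_affinity <- function(records, model = default_model()) {
  pairs <- min_evalue_pairs(records)
  ids <- record_ids(records)
  if (!length(ids)) stop("records contain no identifiers")
  n <- length(ids)
  i <- match(pairs$id1, ids)
  j <- match(pairs$id2, ids)
  s <- if (nrow(pairs)) evalue_to_similarity(model, pairs$evalue) else numeric()
  S <- Matrix::sparseMatrix(i = c(i, seq_len(n)), j = c(j, seq_len(n)),
                            x = c(s, rep(1, n)), dims = c(n, n),
                            dimnames = list(ids, ids), symmetric = TRUE)
  S
}

# Coerce an affinity-like square symmetric matrix with dimnames; forces the
# unit diagonal. Accepts dense or sparse input.
as_affinity <- function(S) {
  if (is.matrix(S)) S <- methods::as(S, "CsparseMatrix")
  if (!methods::is(S, "Matrix")) stop("affinity must be a matrix")
  if (nrow(S) != ncol(S)) stop("affinity must be square")
  if (is.null(rownames(S))) {
    dimnames(S) <- list(as.character(seq_len(nrow(S))),
                        as.character(seq_len(nrow(S))))
  }
  if (!Matrix::isSymmetric(S, tol = 1e-10))
    stop("affinity must be symmetric")
  Matrix::diag(S) <- 1
  Matrix::forceSymmetric(S)
}
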