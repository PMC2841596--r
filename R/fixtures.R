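#' Specification of a planted-partition E-value generator
#'
#' Describes a synthetic all-vs-all BLAST result with planted cluster
#' structure: within-cluster pairs draw log10 E-values from one normal
#' distribution, between-cluster pairs from another, and each pair is
#' reported at all only with the corresponding density. This emulates the
#' bimodal intra- vs inter-superfamily E-value structure seen in real
#' sequence sets; it does not emulate multi-domain chaining, compositional
#' bias, or HSP-level detail.
#'
#' The defaults are the conditions used throughout the test-bench: three
#' families of 20 sequences, intra log10 E ~ N(-50, 5) reported with density
#' 0.9, inter log10 E ~ N(0, 1) with density 0.05. Values are clipped to
#' `[1e-180, 10]`, matching BLAST's strongest reportable hit and its default
#' report ceiling.
#'
#' @param cluster_sizes Integer sizes of the planted families.
#' @param intra_mean,intra_sd Mean/sd of log10 E within a family.
#' @param inter_mean,inter_sd Mean/sd of log10 E between families.
#' @param density_intra,density_inter Probability that a pair is reported.
#' @param asymmetric If `TRUE` both BLAST directions are emitted with
#'   independent log10 jitter (`asym_sd`), exercising the min-E-value
#'   symmetrization rule.
#' @param asym_sd Sd of the per-direction jitter when `asymmetric`.
#' @param seed Integer seed.
#' @return List of class `"planted_spec"`.
#' @export
planted_spec <- function(cluster_sizes = c(20L, 20L, 20L),
                         intra_mean = -50, intra_sd = 5,
                         inter_mean = 0, inter_sd = 1,
                         density_intra = 0.9, density_inter = 0.05,
                         asymmetric = FALSE, asym_sd = 0.5, seed = 1L) {
  stopifnot(all(cluster_sizes >= 1L),
            density_intra >= 0, density_intra <= 1,
            density_inter >= 0, density_inter <= 1,
            intra_sd >= 0, inter_sd >= 0)
  structure(list(cluster_sizes = as.integer(cluster_sizes),
                 intra_mean = intra_mean, intra_sd = intra_sd,
                 inter_mean = inter_mean, inter_sd = inter_sd,
                 density_intra = density_intra, density_inter = density_inter,
                 asymmetric = asymmetric, asym_sd = asym_sd,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

clip_evalue <- function(log10e) 10^pmin(pmax(log10e, -180), 1)

#' Generate a planted-partition E-value list with gold labels
#'
#' Draws synthetic pairwise records according to a [planted_spec()]:
#' every intra-family pair is reported with probability `density_intra` at
#' `E = 10^N(intra_mean, intra_sd)` (clipped to `[1e-180, 10]`), analogously
#' for inter-family pairs. Deterministic under the spec's seed.
#'
#' @param spec A [planted_spec()].
#' @return List with `records` (query, subject, evalue) and `gold` (named
#'   integer family labels over all generated ids).
#' @examples
#' sim <- generate_planted(planted_spec(c(10, 10), seed = 7))
#' head(sim$records)
#' @export
generate_planted <- function(spec = planted_spec()) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(spec$seed)
  sizes <- spec$cluster_sizes
  n <- sum(sizes)
  ids <- sprintf("seq%03d", seq_len(n))
  fam <- rep(seq_along(sizes), sizes)
  gold <- stats::setNames(fam, ids)

  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  intra <- fam[pair_i] == fam[pair_j]
  density <- ifelse(intra, spec$density_intra, spec$density_inter)
  reported <- stats::runif(length(pair_i)) < density
  pi <- pair_i[reported]; pj <- pair_j[reported]; is_intra <- intra[reported]
  log10e <- stats::rnorm(length(pi),
                         mean = ifelse(is_intra, spec$intra_mean, spec$inter_mean),
                         sd = ifelse(is_intra, spec$intra_sd, spec$inter_sd))
  if (spec$asymmetric) {
    fwd <- data.frame(query = ids[pi], subject = ids[pj],
                      evalue = clip_evalue(log10e +
                        stats::rnorm(length(pi), 0, spec$asym_sd)),
                      stringsAsFactors = FALSE)
    rev <- data.frame(query = ids[pj], subject = ids[pi],
                      evalue = clip_evalue(log10e +
                        stats::rnorm(length(pi), 0, spec$asym_sd)),
                      stringsAsFactors = FALSE)
    records <- rbind(fwd, rev)
  } else {
    records <- data.frame(query = ids[pi], subject = ids[pj],
                          evalue = clip_evalue(log10e),
                          stringsAsFactors = FALSE)
  }
  list(records = records, gold = gold)
}

#' Generate labelled E-value pairs for training the logistic model
#'
#' Samples `n_per_class` intra-family and `n_per_class` inter-family
#' E-values (default 10,000 each) from the log10-normal distributions of a
#' [planted_spec()]. The training default distributions (intra log10 E ~
#' N(-20, 10), inter ~ N(0, 2)) overlap, giving a finite, well-conditioned
#' logistic fit with a decision boundary in the biologically conventional
#' E ~ 1e-5 region.
#'
#' @param spec A [planted_spec()] supplying the two distributions.
#' @param n_per_class Samples per class.
#' @param seed Integer seed.
#' @return Data frame with columns `evalue` and `label`
#'   (`"intra"`/`"inter"`).
#' @export
generate_training_pairs <- function(spec = planted_spec(intra_mean = -20,
                                                        intra_sd = 10,
                                                        inter_mean = 0,
                                                        inter_sd = 2),
                                    n_per_class = 10000L, seed = 42L) {
  stopifnot(inherits(spec, "planted_spec"), n_per_class >= 1L)
  set.seed(seed)
  intra <- clip_evalue(stats::rnorm(n_per_class, spec$intra_mean, spec$intra_sd))
  inter <- clip_evalue(stats::rnorm(n_per_class, spec$inter_mean, spec$inter_sd))
  data.frame(evalue = c(intra, inter),
             label = rep(c("intra", "inter"), each = n_per_class),
             stringsAsFactors = FALSE)
}

#' Fixed 12-sequence worked example
#'
#' A hand-written instance of three 4-member families (globin-, EF-hand- and
#' cupredoxin-flavoured ids) with strong intra-family hits (E <= 1e-20) and a
#' few weak inter-family hits (E >= 0.5) that keep the similarity graph
#' connected. Small enough to verify by hand: connected component analysis at
#' threshold 1e-6 yields the three families, and spectral clustering with
#' K = 3 recovers them exactly.
#'
#' @return List with `records` and `gold`, as in [generate_planted()].
#' @export
toy_worked_example <- function() {
  tab <- c(
    "glb1 glb2 1e-40", "glb1 glb3 1e-35", "glb1 glb4 1e-28",
    "glb2 glb3 1e-42", "glb2 glb4 1e-30", "glb3 glb4 1e-25",
    "efh1 efh2 1e-38", "efh1 efh3 1e-26", "efh1 efh4 1e-33",
    "efh2 efh3 1e-45", "efh2 efh4 1e-22", "efh3 efh4 1e-31",
    "cup1 cup2 1e-36", "cup1 cup3 1e-29", "cup1 cup4 1e-41",
    "cup2 cup3 1e-24", "cup2 cup4 1e-37", "cup3 cup4 1e-20",
    "glb4 efh1 0.8", "efh4 cup1 1.5", "glb1 cup4 3.0", "glb2 efh2 5.0")
  parts <- strsplit(tab, " ", fixed = TRUE)
  records <- data.frame(query = vapply(parts, `[`, "", 1L),
                        subject = vapply(parts, `[`, "", 2L),
                        evalue = as.numeric(vapply(parts, `[`, "", 3L)),
                        stringsAsFactors = FALSE)
  ids <- c(paste0("glb", 1:4), paste0("efh", 1:4), paste0("cup", 1:4))
  gold <- stats::setNames(rep(1:3, each = 4L), ids)
  list(records = records, gold = gold)
}
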