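# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (BFS reachability, exhaustive double sums, full
# enumeration) so they share no code with the implementation they check.

# Reachability components by BFS over an edge list of character ids.
bfs_components <- function(ids, from, to) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  seen <- character(0)
  comps <- list()
  for (v in ids) {
    if (v %in% seen) next
    queue <- v
    comp <- character(0)
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- comp
  }
  comps[order(-lengths(comps), vapply(comps, `[`, "", 1L))]
}

# All set partitions of 1..n as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(k + 1L)) recurse(c(labels, lab), max(k, lab))
  }
  recurse(integer(0), 0L)
  out
}

# Brute-force modularity: ordered-pair double sum of the defining formula,
# with s_ii = 0, d_i the row sums and m the total edge weight.
brute_modularity <- function(W, labels) {
  diag(W) <- 0
  m <- sum(W) / 2
  d <- unname(rowSums(W))
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j])
        q <- q + W[i, j] - d[i] * d[j] / (2 * m)
    }
  }
  q / (2 * m)
}

# Brute-force mass fraction: intra edge weight over total, diagonal excluded.
brute_mass_fraction <- function(W, labels) {
  diag(W) <- 0
  intra <- 0
  n <- nrow(W)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (labels[i] == labels[j]) intra <- intra + W[i, j]
    }
  }
  intra / (sum(W) / 2)
}

# Random symmetric weighted adjacency with unit-diagonal affinity view.
random_weighted_graph <- function(n, p = 0.5) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1) < p) W[i, j] <- W[j, i] <- stats::runif(1)
    }
  }
  dimnames(W) <- list(letters[seq_len(n)], letters[seq_len(n)])
  W
}

# Affinity (unit diagonal) from a weighted adjacency matrix.
affinity_from_adjacency <- function(W) {
  S <- W
  diag(S) <- 1
  S
}

# Random record list with duplicated/asymmetric entries.
random_records <- function(n_ids = 8L, n_records = 30L) {
  ids <- sprintf("p%02d", seq_len(n_ids))
  q <- sample(ids, n_records, replace = TRUE)
  s <- sample(ids, n_records, replace = TRUE)
  data.frame(query = q, subject = s,
             evalue = 10^stats::runif(n_records, -60, 1),
             stringsAsFactors = FALSE)
}

# Partition (named labels) as a list of sorted id sets, ordered like
# bfs_components output for direct comparison.
partition_sets <- function(partition) {
  groups <- lapply(split(names(partition), partition), sort)
  unname(groups[order(-lengths(groups), vapply(groups, `[`, "", 1L))])
}

# c disjoint cliques of the given sizes as an E-value record list with
# uniformly strong intra-clique hits.
clique_records <- function(sizes, evalue = 1e-30) {
  recs <- NULL
  start <- 0L
  for (c in seq_along(sizes)) {
    ids <- sprintf("c%d_%02d", c, seq_len(sizes[c]))
    for (i in seq_len(sizes[c] - 1L)) {
      for (j in (i + 1L):sizes[c]) {
        recs <- rbind(recs, data.frame(query = ids[i], subject = ids[j],
                                       evalue = evalue,
                                       stringsAsFactors = FALSE))
      }
    }
    start <- start + sizes[c]
  }
  recs
}
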