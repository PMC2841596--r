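#' Read protein sequences from a FASTA file
#'
#' Standard FASTA parsing (wrapped sequence lines are joined). The sequence
#' identifier is the first whitespace-delimited token of the header, matching
#' BLAST's own id handling, so FASTA ids line up with tabular hit ids.
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("no FASTA records in ", path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("malformed FASTA header with empty id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  res <- as.character(seqs)
  if (any(!nzchar(res)))
    stop("empty sequence for id: ",
         paste(ids[!nzchar(res)], collapse = ", "))
  data.frame(id = ids, description = desc, sequence = unname(res),
             stringsAsFactors = FALSE)
}

#' Read pairwise E-values from tabular BLAST output
#'
#' Supports the 12-column BLAST tabular format (outfmt 6; fields 1, 2 and 11
#' are query, subject and E-value) and a bare 3-column whitespace-separated
#' triplet format. Comment lines starting with `#` and blank lines are
#' skipped.
#'
#' @param path Input path.
#' @param dialect `"auto"` (decide from the column count of the first data
#'   line), `"outfmt6"` or `"triplet"`.
#' @return Data frame with columns `query`, `subject`, `evalue`.
#' @export
read_blast_tab <- function(path, dialect = c("auto", "outfmt6", "triplet")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop("no data lines in ", path)
  parse_line <- function(i) {
    ln <- trimws(lines[i], which = "right")
    fields <- strsplit(ln, "\\s+")[[1]]
    d <- dialect
    if (d == "auto") d <- if (length(fields) >= 12L) "outfmt6" else "triplet"
    if (d == "outfmt6") {
      if (length(fields) < 12L)
        stop(sprintf("line %d: expected 12 tab-separated columns, got %d",
                     i, length(fields)))
      fields <- fields[c(1L, 2L, 11L)]
    } else if (length(fields) != 3L) {
      stop(sprintf("line %d: expected 3 columns, got %d", i, length(fields)))
    }
    ev <- suppressWarnings(as.numeric(fields[3L]))
    if (is.na(ev))
      stop(sprintf("line %d: non-numeric E-value '%s'", i, fields[3L]))
    list(q = fields[1L], s = fields[2L], e = ev)
  }
  parsed <- lapply(keep, parse_line)
  as_records(data.frame(
    query = vapply(parsed, `[[`, "", "q"),
    subject = vapply(parsed, `[[`, "", "s"),
    evalue = vapply(parsed, `[[`, 0, "e"),
    stringsAsFactors = FALSE))
}

#' All-against-all BLAST adapter
#'
#' Builds a temporary protein database from the FASTA input with
#' `makeblastdb` and runs `blastp` against itself with tabular output, which
#' is then parsed by [read_blast_tab()]. Requires the NCBI BLAST+
#' executables; a missing binary raises an error naming it (never a silent
#' fallback).
#'
#' @param fasta_path Protein FASTA file.
#' @param evalue_max E-value report ceiling passed to blastp (default 10).
#' @param blastp,makeblastdb Executable paths, located on `PATH` by default.
#' @return Data frame of E-value records.
#' @export
run_blast_all_vs_all <- function(fasta_path, evalue_max = 10,
                                 blastp = Sys.which("blastp"),
                                 makeblastdb = Sys.which("makeblastdb")) {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  if (!nzchar(blastp))
    stop("blastp executable not found; install NCBI BLAST+ or pass its path")
  if (!nzchar(makeblastdb))
    stop("makeblastdb executable not found; install NCBI BLAST+ or pass its path")
  db <- file.path(tempfile("blastdb"), "db")
  dir.create(dirname(db))
  on.exit(unlink(dirname(db), recursive = TRUE), add = TRUE)
  st <- system2(makeblastdb, c("-in", shQuote(fasta_path), "-dbtype", "prot",
                               "-out", shQuote(db)),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("makeblastdb failed with exit status ", st)
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  st <- system2(blastp, c("-query", shQuote(fasta_path), "-db", shQuote(db),
                          "-outfmt", "6", "-evalue", format(evalue_max),
                          "-out", shQuote(out)),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("blastp failed with exit status ", st)
  read_blast_tab(out, dialect = "outfmt6")
}

#' Write a clustering as flat text
#'
#' One cluster per line, member ids tab-separated and sorted; clusters
#' ordered by decreasing size, ties by the lexicographically smallest id.
#'
#' @param partition Named cluster label vector.
#' @param path Output path.
#' @export
write_clusters_txt <- function(partition, path) {
  partition <- relabel_partition(partition_from(partition))
  clusters <- partition_to_clusters(partition)
  writeLines(vapply(clusters, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' Read a flat cluster text file
#'
#' @param path File written by [write_clusters_txt()].
#' @return Named integer cluster label vector.
#' @export
read_clusters_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  partition_from(lapply(lines, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]]))
}

#' Read a two-column id/label TSV
#'
#' Used for gold-standard partitions (id, family label) and, with repeated
#' ids, for annotation files (id, term).
#'
#' @param path Two-column tab- or whitespace-separated file; `#` comments
#'   skipped.
#' @return Data frame with columns `id` and `label`.
#' @export
read_membership_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          colClasses = "character",
                          col.names = c("id", "label"))
  df
}

#' Write a similarity graph with cluster labels as XGMML
#'
#' Minimal XGMML (node/edge/att elements): one node per id carrying its
#' cluster label as an attribute, one edge per graph edge carrying its
#' weight. The output loads into Cytoscape for downstream network
#' visualization.
#'
#' @param graph A `"sim_graph"` (or affinity matrix).
#' @param partition Named cluster label vector covering the vertices.
#' @param path Output path.
#' @param label Graph label attribute.
#' @export
write_xgmml <- function(graph, partition, path, label = "specfam") {
  if (!inherits(graph, "sim_graph")) graph <- similarity_graph(graph)
  partition <- partition_from(partition)
  check_partition_covers(partition, graph$ids)
  doc <- xml2::xml_new_root("graph", label = label, directed = "0",
                            xmlns = "http://www.cs.rpi.edu/XGMML")
  for (id in graph$ids) {
    node <- xml2::xml_add_child(doc, "node", id = id, label = id)
    xml2::xml_add_child(node, "att", name = "cluster", type = "integer",
                        value = as.character(partition[[id]]))
  }
  if (nrow(graph$edges)) {
    for (i in seq_len(nrow(graph$edges))) {
      edge <- xml2::xml_add_child(doc, "edge",
                                  source = graph$edges$from[i],
                                  target = graph$edges$to[i])
      xml2::xml_add_child(edge, "att", name = "weight", type = "real",
                          value = formatC(graph$edges$weight[i], digits = 6,
                                          format = "g"))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a rearranged similarity matrix as a greyscale heatmap PNG
#'
#' Each matrix cell becomes a `pixels_per_cell` square block; intensity is
#' proportional to similarity with darker pixels for higher similarity.
#'
#' @param mat Dense matrix with entries in \[0, 1\], e.g.
#'   `rearrange_matrix(...)$matrix`.
#' @param path Output PNG path.
#' @param pixels_per_cell Integer block size per cell (default 1).
#' @export
write_heatmap_png <- function(mat, path, pixels_per_cell = 1L) {
  mat <- as.matrix(mat)
  mat[mat < 0] <- 0
  mat[mat > 1] <- 1
  img <- 1 - mat  # darker = more similar
  if (pixels_per_cell > 1L) {
    img <- img[rep(seq_len(nrow(img)), each = pixels_per_cell),
               rep(seq_len(ncol(img)), each = pixels_per_cell), drop = FALSE]
  }
  png::writePNG(img, target = path)
  invisible(path)
}
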