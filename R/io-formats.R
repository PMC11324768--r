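# Readers and writers for the external representations the pipeline touches:
# FASTA transcript sets, typed interaction edge tables, and GML network
# export for Cytoscape-style downstream viewing.

EDGE_CLASSES <- c("rbp_lnc", "mi_lnc", "mi_rbp")

#' Read a FASTA file of transcript sequences
#'
#' Parses a (possibly multi-line) FASTA file into a named
#' [Biostrings::DNAStringSet]. Sequences are normalized on ingest: `U`/`u`
#' becomes `T`, everything is case-folded to upper case, and stray carriage
#' returns from CRLF files are stripped. The transcript identifier is the
#' header token up to the first whitespace.
#'
#' Non-ACGT characters (e.g. `N`) are retained; the k-mer stage skips
#' windows that contain them.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by transcript identifier.
#'   Empty files yield an empty set.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1", "acgu", ">tx2 some description", "GGGTTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    return(Biostrings::DNAStringSet())
  }
  headers <- trimws(gsub("\r", "", names(raw), fixed = TRUE))
  ids <- vapply(strsplit(headers, "[ \t]+"), function(tok) {
    if (length(tok) == 0L) "" else tok[[1L]]
  }, character(1))
  if (any(ids == "")) {
    bad <- which(ids == "")[1L]
    stop(sprintf("malformed FASTA header without an identifier (record %d)", bad),
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate transcript identifier(s) in FASTA: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(chartr("Uu", "Tt", gsub("\r", "", as.character(raw), fixed = TRUE)))
  if (any(nchar(seqs) == 0L)) {
    stop("zero-length sequence for: ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write transcript sequences to FASTA
#'
#' Companion writer to [read_fasta()]; output re-read with [read_fasta()]
#' is identical to the input set.
#'
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("'seqs' must be named", call. = FALSE)
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Read a typed interaction edge table
#'
#' Reads a TSV of pairwise interactions into a canonical edge data frame
#' with columns `source`, `target`, `edge_class`, `evidence`. Values are
#' whitespace-trimmed; exact duplicate (source, target) rows are dropped
#' with a message; self-edges are dropped with a warning.
#'
#' Column naming conventions (and hence node roles) per edge class:
#' \describe{
#'   \item{`rbp_lnc`}{source = lncRNA, target = RBP}
#'   \item{`mi_lnc`}{source = miRNA, target = lncRNA}
#'   \item{`mi_rbp`}{source = miRNA, target = RBP (mRNA)}
#' }
#'
#' @param path Path to a TSV file with a header row.
#' @param edge_class One of `"rbp_lnc"`, `"mi_lnc"`, `"mi_rbp"`.
#' @param source_col,target_col,evidence_col Column names in the file;
#'   supplementary tables from different databases spell these
#'   differently, so they are configurable. `evidence_col` is optional in
#'   the file.
#' @return A data frame with columns `source`, `target`, `edge_class`,
#'   `evidence` (row order of the file preserved after dropping
#'   duplicates).
#' @export
read_edge_table <- function(path, edge_class,
                            source_col = "source",
                            target_col = "target",
                            evidence_col = "evidence") {
  edge_class <- match.arg(edge_class, EDGE_CLASSES)
  if (!file.exists(path)) stop("edge table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(c(source_col, target_col), names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("edge table %s lacks mandatory column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  src <- trimws(df[[source_col]])
  tgt <- trimws(df[[target_col]])
  ev <- if (evidence_col %in% names(df)) trimws(df[[evidence_col]]) else
    rep(NA_character_, nrow(df))
  self <- !is.na(src) & src == tgt
  if (any(self)) {
    warning(sprintf("dropped %d self-edge(s) from %s", sum(self), path),
            call. = FALSE)
    src <- src[!self]; tgt <- tgt[!self]; ev <- ev[!self]
  }
  key <- paste(src, tgt, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("dropped %d duplicate edge row(s) from %s", sum(dup), path))
  }
  data.frame(source = src[!dup], target = tgt[!dup],
             edge_class = rep(edge_class, sum(!dup)),
             evidence = ev[!dup],
             stringsAsFactors = FALSE)
}

#' Write an edge table to TSV
#'
#' @param edges Edge data frame as returned by [read_edge_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  write_tsv(edges[, c("source", "target", "edge_class", "evidence")], path)
}

#' Export a network to GML
#'
#' Writes a bipartite interaction network (or any igraph object) as GML,
#' readable by standard graph libraries and by Cytoscape. Node `role` and
#' `log2fc` attributes are preserved.
#'
#' @param network A `bipartite_network` (see [build_network()]) or an
#'   [igraph::igraph] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_gml()]
#' @export
write_gml <- function(network, path) {
  g <- if (inherits(network, "igraph")) network else as_igraph(network)
  igraph::write_graph(g, file = path, format = "gml")
  # igraph stamps a creation date into the Creator line; replace it so
  # identical networks always serialize to identical bytes
  lines <- readLines(path)
  lines[grepl("^Creator", lines)] <- "Creator \"lnctriad\""
  writeLines(lines, path)
  invisible(path)
}

#' Read a GML network file
#'
#' @param path Path to a GML file written by [write_gml()] or another tool.
#' @return An [igraph::igraph] object.
#' @export
read_gml <- function(path) {
  igraph::read_graph(path, format = "gml")
}
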