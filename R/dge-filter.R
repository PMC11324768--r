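# Differential-expression consensus filtering: per-gene dysregulation
# classification, cross-dataset consensus sets, and the sex-biased subset.

BIOTYPES <- c("lncRNA", "protein_coding", "miRNA", "other")

#' Dysregulation filter criteria
#'
#' Thresholds for calling a gene dysregulated from a differential-expression
#' table. Defaults are the permissive cut-offs commonly used for holistic
#' lncRNA screens: |log2 fold change| > 0.1 with unadjusted p < 0.05. All
#' inequalities are strict.
#'
#' @param fc_up Upper log2 fold-change threshold (must be > 0).
#' @param fc_down Lower log2 fold-change threshold (must be < 0).
#' @param alpha Significance level on the (unadjusted) p-value.
#' @return An object of class `filter_criteria`.
#' @examples
#' filter_criteria()
#' filter_criteria(fc_up = 1, fc_down = -1, alpha = 0.01)
#' @export
filter_criteria <- function(fc_up = 0.1, fc_down = -0.1, alpha = 0.05) {
  stop_if_not_scalar_number(fc_up, "fc_up")
  stop_if_not_scalar_number(fc_down, "fc_down")
  stop_if_not_scalar_number(alpha, "alpha")
  if (!(fc_down < 0 && 0 < fc_up)) {
    stop("filter criteria require fc_down < 0 < fc_up", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(fc_up = fc_up, fc_down = fc_down, alpha = alpha),
            class = "filter_criteria")
}

#' @export
print.filter_criteria <- function(x, ...) {
  cat(sprintf("Dysregulation criteria: log2FC > %g (up) or < %g (down), p < %g\n",
              x$fc_up, x$fc_down, x$alpha))
  invisible(x)
}

#' Classify per-gene regulation status
#'
#' Vectorized classification of differential-expression evidence into
#' `"up"`, `"down"` or `"not_significant"`. A gene is up iff
#' `log2fc > fc_up` and `pvalue < alpha`; down iff `log2fc < fc_down` and
#' `pvalue < alpha`; otherwise not significant. All comparisons strict, so
#' a gene sitting exactly on a threshold is not called.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param pvalue Numeric vector of p-values in \[0, 1\].
#' @param criteria A [filter_criteria()] object.
#' @return Character vector over `{"up", "down", "not_significant"}`.
#' @examples
#' classify_regulation(c(0.15, 0.1, -0.2), c(0.01, 0.001, 0.06))
#' @export
classify_regulation <- function(log2fc, pvalue, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  if (length(log2fc) != length(pvalue)) {
    stop("log2fc and pvalue must have equal length", call. = FALSE)
  }
  if (any(!is.finite(log2fc))) {
    stop("non-finite log2fc value(s)", call. = FALSE)
  }
  if (any(!is.finite(pvalue) | pvalue < 0 | pvalue > 1)) {
    stop("pvalue(s) outside [0, 1] or non-finite", call. = FALSE)
  }
  sig <- pvalue < criteria$alpha
  out <- rep("not_significant", length(log2fc))
  out[sig & log2fc > criteria$fc_up] <- "up"
  out[sig & log2fc < criteria$fc_down] <- "down"
  out
}

#' Read a differential-expression table
#'
#' Expects a TSV with at least `gene_id`, `biotype`, `log2fc`, `pvalue`;
#' `symbol`, `padj` and `dataset_id` are optional. When the file lacks a
#' `dataset_id` column, `dataset_id` (argument) is required.
#'
#' @param path Path to the TSV.
#' @param dataset_id Identifier for the dataset the table came from.
#' @return Data frame of per-gene evidence.
#' @export
read_dge_table <- function(path, dataset_id = NULL) {
  df <- read_tsv(path)
  needed <- c("gene_id", "biotype", "log2fc", "pvalue")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("DE table %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!"dataset_id" %in% names(df)) {
    if (is.null(dataset_id)) {
      stop("DE table has no dataset_id column; supply dataset_id=", call. = FALSE)
    }
    df$dataset_id <- dataset_id
  }
  if (!"symbol" %in% names(df)) df$symbol <- NA_character_
  df$log2fc <- as.numeric(df$log2fc)
  df$pvalue <- as.numeric(df$pvalue)
  df
}

#' Cross-dataset consensus dysregulated set
#'
#' Returns the genes of the requested biotype that are significantly
#' dysregulated (up or down, judged independently per dataset) in every
#' supplied table. Genes with discordant directions across datasets are
#' retained: expression of the same transcript can move opposite ways in
#' different case cohorts, and excluding them would hide exactly the
#' candidates a holistic screen wants to keep. Genes absent from any one
#' table are treated as not significant there and hence excluded.
#'
#' @param tables List of DE data frames (see [read_dge_table()]), one per
#'   dataset, with distinct `dataset_id`s.
#' @param biotype Biotype to keep: `"lncRNA"`, `"protein_coding"`,
#'   `"miRNA"`, or `"other"`.
#' @param criteria A [filter_criteria()] object.
#' @param canonical_map Optional data frame with columns `gene_id`,
#'   `transcript_id` mapping genes to canonical transcripts; unmapped
#'   genes are dropped with a message and returned IDs are transcript IDs.
#' @param use_padj If `TRUE`, use the `padj` column instead of `pvalue`
#'   for the significance test (stricter FDR-style screening).
#' @return An object of class `consensus_set`: a list with `ids` (sorted
#'   character vector) and `evidence` (long data frame of per-dataset
#'   log2fc/pvalue/status for the consensus genes).
#' @examples
#' t1 <- data.frame(gene_id = c("g1", "g2"), biotype = "lncRNA",
#'                  log2fc = c(1.2, 0.02), pvalue = c(1e-4, 0.5),
#'                  dataset_id = "A")
#' t2 <- data.frame(gene_id = c("g1", "g2"), biotype = "lncRNA",
#'                  log2fc = c(-0.9, 1.4), pvalue = c(1e-3, 1e-3),
#'                  dataset_id = "B")
#' consensus_dysregulated_set(list(t1, t2), "lncRNA")$ids  # "g1" only
#' @export
consensus_dysregulated_set <- function(tables, biotype,
                                       criteria = filter_criteria(),
                                       canonical_map = NULL,
                                       use_padj = FALSE) {
  if (!is.list(tables) || length(tables) == 0L ||
      inherits(tables, "data.frame")) {
    stop("'tables' must be a non-empty list of DE data frames", call. = FALSE)
  }
  biotype <- match.arg(biotype, BIOTYPES)
  dataset_ids <- vapply(tables, function(t) unique(t$dataset_id)[1L], character(1))
  if (anyDuplicated(dataset_ids)) {
    stop("dataset_id values must be distinct across tables", call. = FALSE)
  }
  per_table <- lapply(tables, function(t) {
    t <- t[t$biotype == biotype, , drop = FALSE]
    p <- if (use_padj) {
      if (!"padj" %in% names(t)) stop("use_padj=TRUE but no padj column", call. = FALSE)
      as.numeric(t$padj)
    } else t$pvalue
    status <- classify_regulation(t$log2fc, p, criteria)
    t$status <- status
    t[t$status != "not_significant", , drop = FALSE]
  })
  ids <- Reduce(intersect, lapply(per_table, function(t) unique(t$gene_id)))
  ids <- sort(ids)
  evidence <- do.call(rbind, lapply(per_table, function(t) {
    t <- t[t$gene_id %in% ids,
           c("gene_id", "dataset_id", "log2fc", "pvalue", "status"),
           drop = FALSE]
    t[order(t$gene_id), , drop = FALSE]
  }))
  rownames(evidence) <- NULL
  if (!is.null(canonical_map)) {
    stopifnot(all(c("gene_id", "transcript_id") %in% names(canonical_map)))
    idx <- match(ids, canonical_map$gene_id)
    unmapped <- is.na(idx)
    if (any(unmapped)) {
      message(sprintf("dropped %d consensus gene(s) without a canonical transcript",
                      sum(unmapped)))
    }
    tx <- canonical_map$transcript_id[idx[!unmapped]]
    evidence <- evidence[evidence$gene_id %in% ids[!unmapped], , drop = FALSE]
    evidence$transcript_id <-
      canonical_map$transcript_id[match(evidence$gene_id, canonical_map$gene_id)]
    ids <- sort(unique(tx))
  }
  structure(list(ids = ids, evidence = evidence, biotype = biotype,
                 criteria = criteria, datasets = dataset_ids),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("Consensus %s set: %d IDs significant in all %d dataset(s) [%s]\n",
              x$biotype, length(x$ids), length(x$datasets),
              paste(x$datasets, collapse = ", ")))
  invisible(x)
}

#' Sex-biased subset of a dysregulated gene set
#'
#' From male-vs-female differential-expression contrasts run separately in
#' the disease and control cohorts, returns the members of `base_set` that
#' are significantly sex-biased in the disease cohort but not in the
#' control cohort (disease-specific sex bias).
#'
#' @param ad_sex_de DE data frame for the male-vs-female contrast in the
#'   disease cohort.
#' @param control_sex_de DE data frame for the same contrast in controls.
#' @param base_set Character vector of gene IDs to restrict to.
#' @param criteria A [filter_criteria()] object.
#' @return Sorted character vector of gene IDs.
#' @export
sex_biased_subset <- function(ad_sex_de, control_sex_de, base_set,
                              criteria = filter_criteria()) {
  sig_ids <- function(t) {
    if (is.null(t) || nrow(t) == 0L) return(character(0))
    t <- t[t$gene_id %in% base_set, , drop = FALSE]
    if (nrow(t) == 0L) return(character(0))
    status <- classify_regulation(t$log2fc, t$pvalue, criteria)
    unique(t$gene_id[status != "not_significant"])
  }
  sort(setdiff(sig_ids(ad_sex_de), sig_ids(control_sex_de)))
}
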