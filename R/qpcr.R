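# Relative quantification of qPCR validation experiments by the 2^-ddCt
# method, with replicate summaries and significance stars.

#' Significance stars from p-values
#'
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001; `NA` stays `NA` (significance not computable).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
                    ifelse(p[ok] < 0.01, "**",
                           ifelse(p[ok] < 0.05, "*", "ns")))
  out
}

#' 2^-ddCt fold changes from a Ct measurement table
#'
#' For each gene: dCt = Ct(target) - Ct(reference) per replicate;
#' ddCt = dCt(treated) - mean(dCt(control)); fold change = 2^-ddCt per
#' treated replicate, reported as mean +/- SEM. Significance is an
#' unpaired two-sided t-test on the dCt values (not on fold changes) —
#' dCt is the approximately normal log-scale quantity, so testing there is
#' standard practice and consistent with displaying SEM on fold changes.
#'
#' Fold changes are invariant to adding a constant to all Ct values, and
#' swapping the treated/control labels inverts `2^-mean(ddCt)`.
#'
#' @param measurements Data frame with columns `sample_group`
#'   (`"control"`/`"treated"`), `gene`, `ct_target`, `ct_reference`; a
#'   `replicate` column is allowed but not required.
#' @return Data frame with one row per gene: `gene`, `n_control`,
#'   `n_treated`, `ddct_mean`, `fold_change` (mean over treated
#'   replicates), `sem`, `log2_fold_change` (`-ddct_mean`), `p_value`
#'   (NA when either group has < 2 replicates), `significance`.
#' @examples
#' ct <- data.frame(
#'   sample_group = rep(c("control", "treated"), each = 3),
#'   gene = "LNC1",
#'   ct_target = c(25, 25.1, 24.9, 24, 24.1, 23.9),
#'   ct_reference = rep(15, 6))
#' ddct_fold_change(ct)  # ~2-fold up
#' @export
ddct_fold_change <- function(measurements) {
  needed <- c("sample_group", "gene", "ct_target", "ct_reference")
  if (!all(needed %in% names(measurements))) {
    stop("Ct table needs columns sample_group, gene, ct_target, ct_reference",
         call. = FALSE)
  }
  ct_cols <- c(measurements$ct_target, measurements$ct_reference)
  if (any(!is.finite(ct_cols)) || any(ct_cols <= 0)) {
    stop("Ct values must be positive and finite", call. = FALSE)
  }
  if (!all(measurements$sample_group %in% c("control", "treated"))) {
    stop("sample_group must be 'control' or 'treated'", call. = FALSE)
  }
  rows <- lapply(unique(measurements$gene), function(g) {
    m <- measurements[measurements$gene == g, , drop = FALSE]
    dct <- m$ct_target - m$ct_reference
    dct_c <- dct[m$sample_group == "control"]
    dct_t <- dct[m$sample_group == "treated"]
    if (length(dct_c) == 0L || length(dct_t) == 0L) {
      stop(sprintf("gene %s lacks one of the sample groups", g), call. = FALSE)
    }
    ddct <- dct_t - mean(dct_c)
    fc <- 2^(-ddct)
    p <- if (length(dct_c) >= 2L && length(dct_t) >= 2L) {
      # degenerate (constant) data leave the t statistic undefined
      tryCatch(stats::t.test(dct_t, dct_c, var.equal = FALSE)$p.value,
               error = function(e) NA_real_)
    } else NA_real_
    data.frame(gene = g,
               n_control = length(dct_c),
               n_treated = length(dct_t),
               ddct_mean = mean(ddct),
               fold_change = mean(fc),
               sem = if (length(fc) >= 2L) stats::sd(fc) / sqrt(length(fc))
                     else NA_real_,
               log2_fold_change = -mean(ddct),
               p_value = p,
               significance = significance_stars(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
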