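# Subcellular-localization consensus voting across prediction tools and
# per-community compartment distributions.

COMPARTMENTS <- c("cytoplasm", "nucleus", "ribosome", "exosome", "other")

# Tool-specific labels mapped onto the canonical vocabulary. The three
# usual lncRNA localization predictors spell compartments differently
# ("Cytosol" vs "Cytoplasm", "Nucleus" vs "nuclear", ...).
.compartment_synonyms <- c(
  cytoplasm  = "cytoplasm", cytosol = "cytoplasm", cytoplasmic = "cytoplasm",
  nucleus    = "nucleus", nuclear = "nucleus", nucleoplasm = "nucleus",
  ribosome   = "ribosome", ribosomal = "ribosome",
  exosome    = "exosome", exosomal = "exosome",
  other      = "other"
)

#' Normalize compartment labels to the canonical vocabulary
#'
#' Case-insensitive mapping of tool-specific compartment spellings onto
#' `{cytoplasm, nucleus, ribosome, exosome, other}`. Unknown labels map to
#' `"other"` with a message.
#'
#' @param x Character vector of compartment labels.
#' @return Character vector over the canonical vocabulary.
#' @export
normalize_compartment <- function(x) {
  key <- tolower(trimws(x))
  out <- unname(.compartment_synonyms[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    message(sprintf("%d unknown compartment label(s) mapped to 'other': %s",
                    sum(unknown),
                    paste(unique(x[unknown]), collapse = ", ")))
    out[unknown] <- "other"
  }
  out
}

#' Consensus subcellular localization across prediction tools
#'
#' A transcript is assigned to a compartment only when it has a top-ranked
#' prediction from EVERY required tool and all of them agree after
#' vocabulary normalization; otherwise it is left unassigned. This
#' all-tools-agree vote trades coverage for confidence.
#'
#' @param predictions Data frame with columns `transcript_id`, `tool`,
#'   `compartment` (one row per transcript/tool pair).
#' @param required_tools Character vector of tool names that must agree.
#' @return An object of class `localization_consensus`: list with
#'   `assignments` (named list compartment -> character vector of
#'   transcript IDs, all canonical compartments present) and `unassigned`
#'   (transcripts covered by some tool but lacking full agreement or full
#'   coverage).
#' @export
consensus_localization <- function(predictions, required_tools) {
  needed <- c("transcript_id", "tool", "compartment")
  if (!all(needed %in% names(predictions))) {
    stop("'predictions' needs columns transcript_id, tool, compartment",
         call. = FALSE)
  }
  if (length(required_tools) == 0L) {
    stop("'required_tools' must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(predictions[, c("transcript_id", "tool")])) {
    stop("more than one prediction per (transcript, tool) pair", call. = FALSE)
  }
  predictions$compartment <- normalize_compartment(predictions$compartment)
  pred <- predictions[predictions$tool %in% required_tools, , drop = FALSE]
  assignments <- stats::setNames(
    vector("list", length(COMPARTMENTS)), COMPARTMENTS)
  assignments[] <- list(character(0))
  unassigned <- character(0)
  for (tx in unique(predictions$transcript_id)) {
    rows <- pred[pred$transcript_id == tx, , drop = FALSE]
    if (!all(required_tools %in% rows$tool)) {
      unassigned <- c(unassigned, tx)
      next
    }
    comps <- unique(rows$compartment[rows$tool %in% required_tools])
    if (length(comps) == 1L) {
      assignments[[comps]] <- c(assignments[[comps]], tx)
    } else {
      unassigned <- c(unassigned, tx)
    }
  }
  assignments <- lapply(assignments, sort)
  n_missing <- sum(!unassigned %in% pred$transcript_id)
  if (length(unassigned) > 0L) {
    message(sprintf("%d transcript(s) without full-agreement consensus (%d lacking tool coverage)",
                    length(unassigned), n_missing))
  }
  structure(list(assignments = assignments, unassigned = sort(unassigned),
                 required_tools = required_tools),
            class = "localization_consensus")
}

#' @export
print.localization_consensus <- function(x, ...) {
  counts <- vapply(x$assignments, length, integer(1))
  cat(sprintf("Localization consensus over tools [%s]:\n",
              paste(x$required_tools, collapse = ", ")))
  for (comp in names(counts)) {
    cat(sprintf("  %-10s %d transcript(s)\n", comp, counts[[comp]]))
  }
  cat(sprintf("  unassigned %d transcript(s)\n", length(x$unassigned)))
  invisible(x)
}

#' Compartment distribution of one tool's predictions
#'
#' Percentage of `members` assigned to each canonical compartment by a
#' single tool, over the members that tool actually predicted. Percentages
#' sum to 100 (within floating-point rounding).
#'
#' @param predictions Prediction data frame (see
#'   [consensus_localization()]).
#' @param tool Tool name present in the table.
#' @param members Character vector of transcript IDs (e.g. one
#'   community's lncRNAs).
#' @return Named numeric vector over the canonical compartments.
#' @export
compartment_distribution <- function(predictions, tool, members) {
  if (!tool %in% predictions$tool) {
    stop(sprintf("tool '%s' absent from prediction table", tool), call. = FALSE)
  }
  rows <- predictions[predictions$tool == tool &
                        predictions$transcript_id %in% members, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("no member predicted by tool '%s'", tool), call. = FALSE)
  }
  comp <- normalize_compartment(rows$compartment)
  counts <- table(factor(comp, levels = COMPARTMENTS))
  stats::setNames(100 * as.numeric(counts) / nrow(rows), COMPARTMENTS)
}
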