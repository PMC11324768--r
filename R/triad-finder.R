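# Enumeration of lncRNA-miRNA-RBP regulatory triads and per-community
# participation statistics. A triad (L, M, P) captures the competing
# endogenous RNA hypothesis locally: the lncRNA L binds the RBP P, the
# miRNA M targets L, and M also targets P's mRNA — so by sponging M, L can
# relieve repression of P and thereby modulate its own binding partner.

#' Enumerate lncRNA-miRNA-RBP regulatory triads
#'
#' Returns exactly the set
#' \deqn{\{(L, M, P) : (L, P) \in rbp\_lnc \wedge (M, L) \in mi\_lnc
#'   \wedge (M, P) \in mi\_rbp\}.}
#' The implementation indexes edges by miRNA and joins, but the result is
#' defined set-theoretically and is invariant to input edge order.
#'
#' Edge tables follow the [read_edge_table()] role conventions:
#' `rbp_lnc` has source = lncRNA / target = RBP; `mi_lnc` has
#' source = miRNA / target = lncRNA; `mi_rbp` has source = miRNA /
#' target = RBP.
#'
#' @param rbp_lnc,mi_lnc,mi_rbp Edge data frames (deduplicated, IDs
#'   normalized consistently, e.g. via [normalize_mirna_ids()]).
#' @return Data frame with columns `lncRNA_id`, `miRNA_id`, `rbp_id`,
#'   one row per unique triad, sorted for determinism.
#' @examples
#' rl <- data.frame(source = "L1", target = "P1", edge_class = "rbp_lnc")
#' ml <- data.frame(source = "M1", target = "L1", edge_class = "mi_lnc")
#' mp <- data.frame(source = "M1", target = "P1", edge_class = "mi_rbp")
#' find_triads(rl, ml, mp)
#' @export
find_triads <- function(rbp_lnc, mi_lnc, mi_rbp) {
  empty <- data.frame(lncRNA_id = character(0), miRNA_id = character(0),
                      rbp_id = character(0), stringsAsFactors = FALSE)
  if (nrow(rbp_lnc) == 0L || nrow(mi_lnc) == 0L || nrow(mi_rbp) == 0L) {
    return(empty)
  }
  lp_key <- unique(paste(rbp_lnc$source, rbp_lnc$target, sep = "\r"))
  lnc_by_mi <- split(mi_lnc$target, mi_lnc$source)
  rbp_by_mi <- split(mi_rbp$target, mi_rbp$source)
  shared_mi <- intersect(names(lnc_by_mi), names(rbp_by_mi))
  if (length(shared_mi) == 0L) return(empty)
  parts <- lapply(shared_mi, function(m) {
    grid <- expand.grid(lncRNA_id = unique(lnc_by_mi[[m]]),
                        rbp_id = unique(rbp_by_mi[[m]]),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[paste(grid$lncRNA_id, grid$rbp_id, sep = "\r") %in% lp_key, ,
                 drop = FALSE]
    if (nrow(grid) == 0L) return(NULL)
    data.frame(lncRNA_id = grid$lncRNA_id, miRNA_id = m,
               rbp_id = grid$rbp_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- unique(out)
  out <- out[order(out$lncRNA_id, out$miRNA_id, out$rbp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-community triad participation statistics
#'
#' For each community, counts the member lncRNAs that appear in at least
#' one regulatory triad and reports the participation percentage over ALL
#' community members (including lncRNAs with no retained interaction
#' edges). Percentages are kept at full precision; round only when
#' reporting.
#'
#' @param triads Triad data frame from [find_triads()] (duplicates are
#'   harmless).
#' @param members Named list mapping community label to the character
#'   vector of its lncRNA IDs (see [community_members()]), or a
#'   `community_assignment`.
#' @return Data frame with columns `community_label`, `n_lncRNAs`,
#'   `n_participating`, `participation_pct`.
#' @export
triad_participation <- function(triads, members) {
  if (inherits(members, "community_assignment")) {
    members <- community_members(members)
  }
  if (!is.list(members) || is.null(names(members))) {
    stop("'members' must be a named list of community member vectors",
         call. = FALSE)
  }
  participating <- unique(triads$lncRNA_id)
  rows <- lapply(names(members), function(lab) {
    ids <- members[[lab]]
    if (length(ids) == 0L) {
      stop(sprintf("community %s has zero members", lab), call. = FALSE)
    }
    n_part <- sum(unique(ids) %in% participating)
    data.frame(community_label = lab,
               n_lncRNAs = length(unique(ids)),
               n_participating = n_part,
               participation_pct = 100 * n_part / length(unique(ids)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Triad set -> Cytoscape-ready network
#'
#' Each triad contributes its three supporting edges; node roles are
#' recorded so viewers can shape-code the three molecular classes.
#'
#' @param triads Triad data frame from [find_triads()].
#' @return An undirected [igraph::igraph] with a `role` vertex attribute.
#' @export
triads_as_igraph <- function(triads) {
  edges <- unique(rbind(
    data.frame(from = triads$lncRNA_id, to = triads$rbp_id,
               interaction = "rbp_lnc", stringsAsFactors = FALSE),
    data.frame(from = triads$miRNA_id, to = triads$lncRNA_id,
               interaction = "mi_lnc", stringsAsFactors = FALSE),
    data.frame(from = triads$miRNA_id, to = triads$rbp_id,
               interaction = "mi_rbp", stringsAsFactors = FALSE)))
  vertices <- unique(rbind(
    data.frame(name = triads$lncRNA_id, role = "lncRNA", stringsAsFactors = FALSE),
    data.frame(name = triads$miRNA_id, role = "miRNA", stringsAsFactors = FALSE),
    data.frame(name = triads$rbp_id, role = "RBP", stringsAsFactors = FALSE)))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}
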