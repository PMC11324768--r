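# Per-community bipartite lncRNA-vs-interactor networks in AD-restricted
# and comprehensive modes, plus degree-centrality rankings.

#' Normalize miRNA identifiers
#'
#' Strips the species prefix (`hsa-`) and lower-cases the identifier while
#' keeping the mature-arm suffix (`-5p`/`-3p`), so the same miRNA spelled
#' differently by different interaction databases compares equal.
#'
#' @param ids Character vector of miRNA identifiers.
#' @return Normalized character vector.
#' @examples
#' normalize_mirna_ids(c("hsa-miR-16-5p", "miR-16-5p", "MIR-16-5P"))
#' @export
normalize_mirna_ids <- function(ids) {
  tolower(sub("^hsa-", "", ids, ignore.case = TRUE))
}

#' Build a bipartite lncRNA interaction network
#'
#' Restricts an edge table to one lncRNA community and, in `"AD"` mode,
#' to interactors that are themselves members of the supplied dysregulated
#' set; `"comprehensive"` mode keeps every experimentally supported
#' interactor. Multiple evidence rows for the same pair collapse to a
#' single edge (degree later counts distinct partners, not citations).
#' Community lncRNAs with no retained edge stay in the network as isolated
#' nodes — they matter as denominators for participation statistics.
#'
#' @param edges Edge data frame from [read_edge_table()] with a single
#'   `edge_class` of `"rbp_lnc"` (source = lncRNA) or `"mi_lnc"`
#'   (target = lncRNA).
#' @param community_members Character vector of the community's lncRNA IDs.
#' @param mode `"AD"` (disease-restricted) or `"comprehensive"`.
#' @param dysregulated_interactors Character vector of interactor IDs that
#'   passed the dysregulation filter; required in AD mode.
#' @param lnc_log2fc Optional named numeric vector of log2 fold changes
#'   attached to lncRNA nodes.
#' @param community_label Optional integer label recorded on the network.
#' @param edge_class Fallback edge class when `edges` has zero rows (it is
#'   otherwise inferred from the table).
#' @return An object of class `bipartite_network`: list with `edges`
#'   (data frame `lncRNA_id`, `interactor_id`), `nodes` (data frame
#'   `node`, `role`, `log2fc`), `mode`, `edge_class`, `community_label`.
#' @export
build_network <- function(edges, community_members,
                          mode = c("AD", "comprehensive"),
                          dysregulated_interactors = NULL,
                          lnc_log2fc = NULL,
                          community_label = NA_integer_,
                          edge_class = NULL) {
  mode <- match.arg(mode)
  if (length(community_members) == 0L) {
    stop("community_members must be non-empty", call. = FALSE)
  }
  cls <- unique(edges$edge_class)
  if (length(cls) == 0L) cls <- edge_class %||% "rbp_lnc"
  if (length(cls) != 1L) {
    stop("edge table must hold a single edge_class", call. = FALSE)
  }
  if (!cls %in% c("rbp_lnc", "mi_lnc")) {
    stop("network edge_class must be rbp_lnc or mi_lnc", call. = FALSE)
  }
  if (cls == "rbp_lnc") {
    lnc <- edges$source; inter <- edges$target; inter_role <- "RBP"
  } else {
    lnc <- edges$target; inter <- edges$source; inter_role <- "miRNA"
  }
  keep <- lnc %in% community_members
  if (mode == "AD") {
    if (is.null(dysregulated_interactors) ||
        length(dysregulated_interactors) == 0L) {
      warning("AD mode with an empty dysregulated interactor set: network has no edges",
              call. = FALSE)
      keep <- keep & FALSE
    } else {
      keep <- keep & inter %in% dysregulated_interactors
    }
  }
  pair <- unique(data.frame(lncRNA_id = lnc[keep], interactor_id = inter[keep],
                            stringsAsFactors = FALSE))
  pair <- pair[order(pair$lncRNA_id, pair$interactor_id), , drop = FALSE]
  rownames(pair) <- NULL
  interactors <- sort(unique(pair$interactor_id))
  nodes <- data.frame(
    node = c(sort(unique(community_members)), interactors),
    role = c(rep("lncRNA", length(unique(community_members))),
             rep(inter_role, length(interactors))),
    stringsAsFactors = FALSE)
  nodes$log2fc <- if (is.null(lnc_log2fc)) NA_real_ else
    unname(lnc_log2fc[nodes$node])
  structure(list(edges = pair, nodes = nodes, mode = mode,
                 edge_class = cls, community_label = community_label),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("Bipartite %s network (%s mode%s): %d lncRNA node(s), %d %s node(s), %d edge(s)\n",
              x$edge_class, x$mode,
              if (is.na(x$community_label)) "" else
                sprintf(", community %d", x$community_label),
              sum(x$nodes$role == "lncRNA"),
              sum(x$nodes$role != "lncRNA"),
              setdiff(unique(x$nodes$role), "lncRNA") %||% "interactor",
              nrow(x$edges)))
  invisible(x)
}

#' Convert a bipartite network to igraph
#'
#' Node `role` and `log2fc` attributes are carried over (`log2fc` is
#' written as 0 for nodes without a value, since GML cannot encode NA).
#'
#' @param network A `bipartite_network`.
#' @return An undirected [igraph::igraph] object.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes$node,
                          role = network$nodes$role,
                          log2fc = ifelse(is.na(network$nodes$log2fc), 0,
                                          network$nodes$log2fc),
                          stringsAsFactors = FALSE))
  g
}

#' Cytoscape-friendly edge table export
#'
#' Writes `source`, `target`, `interaction`, `source_log2fc` columns,
#' with the lncRNA as the source node.
#'
#' @param network A `bipartite_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edge_tsv <- function(network, path) {
  fc <- stats::setNames(network$nodes$log2fc, network$nodes$node)
  df <- data.frame(source = network$edges$lncRNA_id,
                   target = network$edges$interactor_id,
                   interaction = network$edge_class,
                   source_log2fc = unname(fc[network$edges$lncRNA_id]),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Degree-centrality ranking of one side of a bipartite network
#'
#' Degree is the number of distinct partners. Entries are sorted by degree
#' descending with alphabetical tie-breaking; tied degrees share a rank
#' (dense ranking), mirroring the cluster-of-equal-degree presentation of
#' network analysis tools. On the lncRNA side, isolated community members
#' appear with degree 0.
#'
#' @param network A `bipartite_network`.
#' @param side `"lncRNA"` or `"interactor"`.
#' @return An object of class `degree_ranking`: data frame with columns
#'   `node_id`, `degree`, `rank`.
#' @export
degree_ranking <- function(network, side = c("lncRNA", "interactor")) {
  stopifnot(inherits(network, "bipartite_network"))
  side <- match.arg(side)
  if (side == "lncRNA") {
    nodes <- network$nodes$node[network$nodes$role == "lncRNA"]
    deg <- vapply(nodes, function(n) {
      length(unique(network$edges$interactor_id[network$edges$lncRNA_id == n]))
    }, integer(1))
  } else {
    nodes <- network$nodes$node[network$nodes$role != "lncRNA"]
    deg <- vapply(nodes, function(n) {
      length(unique(network$edges$lncRNA_id[network$edges$interactor_id == n]))
    }, integer(1))
  }
  if (length(nodes) == 0L) {
    out <- data.frame(node_id = character(0), degree = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("degree_ranking", class(out))
    return(out)
  }
  ord <- order(-deg, nodes)
  nodes <- nodes[ord]; deg <- unname(deg[ord])
  rank <- match(deg, sort(unique(deg), decreasing = TRUE))
  out <- data.frame(node_id = nodes, degree = deg, rank = rank,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("degree_ranking", class(out))
  out
}
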