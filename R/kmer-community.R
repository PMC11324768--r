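# k-mer based community segregation: SEEKR-style standardized 6-mer
# profiles, Pearson-correlation adjacency, and Louvain communities with
# size-ordered labels and a pooled null community.

#' Count overlapping k-mers per sequence
#'
#' Counts every overlapping window of length `k` over the alphabet
#' \{A, C, G, T\} for each sequence. Windows containing any other character
#' (e.g. `N`) are skipped. Columns are all 4^k k-mers in lexicographic
#' order (A < C < G < T).
#'
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector;
#'   `U` is normalized to `T` and case is folded.
#' @param k Word length (>= 1).
#' @return Integer matrix, one row per sequence, 4^k columns named by
#'   k-mer. For pure-ACGT sequences each row sums to `length - k + 1`.
#' @export
count_kmers <- function(seqs, k = 6L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  seqs <- as_sequence_set(seqs)
  if (length(seqs) == 0L) stop("empty sequence set", call. = FALSE)
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = as.integer(k),
                                                 step = 1L)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, names(counts)))
  rownames(counts) <- names(seqs)
  counts
}

as_sequence_set <- function(seqs) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
    seqs <- Biostrings::DNAStringSet(toupper(chartr("Uu", "Tt", seqs)))
  }
  if (!methods::is(seqs, "DNAStringSet")) {
    stop("'seqs' must be a DNAStringSet or named character vector", call. = FALSE)
  }
  seqs
}

#' SEEKR-style standardized k-mer profiles
#'
#' For each transcript, counts overlapping k-mers ([count_kmers()]),
#' converts counts to densities per kilobase of full transcript length,
#' log2-transforms after adding a pseudocount, then z-scores each k-mer
#' column across the transcript set. This is the normalization chain of
#' sequence-comparison-by-k-mer approaches: length normalization makes
#' transcripts of different sizes comparable, the log tames the skew of
#' k-mer abundance, and column standardization lets Pearson correlation
#' act as a profile-similarity measure.
#'
#' Columns with zero variance across the set (including the degenerate
#' single-transcript case) are set to 0.
#'
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector.
#' @param k Word length; 6 balances specificity and profile density for
#'   transcripts in the 0.2-20 kb range and is the conventional choice.
#' @param pseudocount Added to the density before log2; 1 keeps absent
#'   k-mers finite at log-density 0.
#' @return Numeric matrix of z-scores (transcripts x 4^k), with attributes
#'   `k` and `pseudocount`.
#' @examples
#' seqs <- c(tx1 = "ACGTACGTACGT", tx2 = "GGGGCCCCGGGG", tx3 = "ATATATATATAT")
#' pr <- seekr_profile(seqs, k = 2)
#' round(colMeans(pr), 12)  # each k-mer column centred at 0
#' @export
seekr_profile <- function(seqs, k = 6L, pseudocount = 1.0) {
  stop_if_not_scalar_number(pseudocount, "pseudocount")
  counts <- count_kmers(seqs, k)
  len <- Biostrings::width(as_sequence_set(seqs))
  density <- counts / (len / 1000)
  logd <- log2(density + pseudocount)
  centred <- scale(logd, center = TRUE, scale = TRUE)
  centred[!is.finite(centred)] <- 0  # zero-variance columns (or n = 1)
  out <- matrix(as.numeric(centred), nrow = nrow(logd),
                dimnames = dimnames(logd))
  attr(out, "k") <- as.integer(k)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Pearson-correlation adjacency of k-mer profiles
#'
#' Computes the transcript-by-transcript Pearson correlation matrix of
#' profile vectors. Correlations involving a zero-variance profile are
#' defined as 0 (with a warning); the diagonal is always 1.
#'
#' @param profiles Matrix from [seekr_profile()] (transcripts in rows).
#' @return Symmetric correlation matrix with unit diagonal, dimnames set
#'   to the transcript IDs.
#' @export
pearson_adjacency <- function(profiles) {
  if (!is.matrix(profiles) || nrow(profiles) < 2L) {
    stop("need a profile matrix with at least 2 transcripts", call. = FALSE)
  }
  sds <- apply(profiles, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(profiles)))
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance profile(s); their correlations set to 0",
                    sum(sds == 0)), call. = FALSE)
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  dimnames(r) <- list(rownames(profiles), rownames(profiles))
  r
}

#' Louvain community segregation of a correlation network
#'
#' Builds a weighted graph with an edge (i, j), i != j, wherever
#' `adj[i, j] > edge_threshold` (weight = the correlation), then runs
#' Louvain modularity optimization. Because Louvain is order-dependent,
#' `restarts` runs are performed from consecutive seeds and the
#' max-modularity partition is kept (ties broken by the earliest seed),
#' making the result reproducible.
#'
#' Communities are relabeled 0, 1, 2, ... in non-increasing size order.
#' Transcripts the procedure fails to place — nodes isolated under the
#' threshold, or members of communities of at most `pool_max_size`
#' members — are pooled into a trailing "null" community carrying the
#' largest label.
#'
#' @param adj Correlation matrix from [pearson_adjacency()].
#' @param edge_threshold Keep edges with correlation strictly above this
#'   value, in \[-1, 1). The default 0 keeps positive correlations only:
#'   Pearson r is almost never exactly zero, so thresholding is what makes
#'   the graph sparse, and negative correlations are not meaningful
#'   positive edge weights for modularity.
#' @param resolution Louvain resolution parameter (1 = classic modularity).
#' @param seed Base RNG seed for the restarts.
#' @param restarts Number of Louvain restarts.
#' @param pool_max_size Communities with at most this many members are
#'   pooled into the null community (default 1: singletons).
#' @return An object of class `community_assignment`: list with `labels`
#'   (named integer vector), `null_label` (integer or `NA` if every node
#'   was placed), `sizes`, `modularity`, and the thresholded `graph`.
#' @export
louvain_communities <- function(adj, edge_threshold = 0, resolution = 1,
                                seed = 0L, restarts = 10L,
                                pool_max_size = 1L) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj) || is.null(rownames(adj))) {
    stop("'adj' must be a square matrix with transcript IDs as dimnames",
         call. = FALSE)
  }
  if (!(edge_threshold >= -1 && edge_threshold < 1)) {
    stop("edge_threshold must lie in [-1, 1)", call. = FALSE)
  }
  ids <- rownames(adj)
  w <- adj
  w[w <= edge_threshold] <- 0
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  iso <- igraph::degree(g) == 0
  if (all(iso)) {
    warning("no edges above threshold; all transcripts pooled into the null community",
            call. = FALSE)
    labels <- stats::setNames(rep(0L, length(ids)), ids)
    return(structure(list(labels = labels, null_label = 0L,
                          sizes = stats::setNames(length(ids), "0"),
                          modularity = NA_real_, graph = g),
                     class = "community_assignment"))
  }
  sub <- igraph::induced_subgraph(g, which(!iso))
  best <- NULL
  for (i in seq_len(restarts)) {
    cl <- with_seed(seed + i - 1L,
                    igraph::cluster_louvain(sub, resolution = resolution))
    m <- igraph::modularity(cl)
    if (is.null(best) || m > best$modularity + 1e-12) {
      best <- list(modularity = m, membership = igraph::membership(cl))
    }
  }
  mem <- best$membership  # named by vertex id
  raw_sizes <- table(mem)
  placed <- names(raw_sizes)[raw_sizes > pool_max_size]
  # size-descending, ties by first appearance for determinism
  placed <- placed[order(-raw_sizes[placed], as.integer(placed))]
  labels <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (j in seq_along(placed)) {
    labels[names(mem)[mem == placed[j]]] <- j - 1L
  }
  null_members <- ids[is.na(labels)]
  null_label <- NA_integer_
  if (length(null_members) > 0L) {
    null_label <- length(placed)
    labels[null_members] <- null_label
  }
  sizes <- table(labels)
  structure(list(labels = labels, null_label = null_label,
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 modularity = best$modularity, graph = g),
            class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  n_comm <- length(x$sizes)
  cat(sprintf("Community assignment: %d transcripts in %d communit%s\n",
              length(x$labels), n_comm, if (n_comm == 1L) "y" else "ies"))
  for (lab in names(x$sizes)) {
    tag <- if (!is.na(x$null_label) && lab == as.character(x$null_label))
      " (null: unplaced)" else ""
    cat(sprintf("  community %s: %d transcript(s)%s\n", lab, x$sizes[[lab]], tag))
  }
  if (!is.na(x$modularity)) {
    cat(sprintf("  modularity of placed partition: %.4f\n", x$modularity))
  }
  invisible(x)
}

#' Community label vector -> member list
#'
#' @param assignment A `community_assignment` from [louvain_communities()].
#' @return Named list: label (as character) -> character vector of
#'   transcript IDs.
#' @export
community_members <- function(assignment) {
  stopifnot(inherits(assignment, "community_assignment"))
  split(names(assignment$labels), assignment$labels)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table. 1 means identical partitions, 0 is
#' the expectation under random labeling.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  comb_a <- sum(choose(rowSums(tab), 2))
  comb_b <- sum(choose(colSums(tab), 2))
  expected <- comb_a * comb_b / choose(n, 2)
  maximum <- (comb_a + comb_b) / 2
  if (maximum == expected) return(1)
  (sum_comb - expected) / (maximum - expected)
}
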