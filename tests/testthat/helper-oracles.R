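# Independent oracles used across the suite. These deliberately use naive
# direct implementations (loops, textbook formulas) rather than the
# package's code paths.

# All 4^k k-mers in lexicographic order over A < C < G < T.
all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  grids <- expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)
  # expand.grid varies the FIRST factor fastest; reverse columns so the
  # LAST position varies fastest, giving lexicographic order.
  sort(apply(grids, 1L, function(r) paste(rev(r), collapse = "")))
}

# Sliding-window k-mer counter: walks every window, skips windows with
# any non-ACGT character.
naive_kmer_counts <- function(seq, k) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  kmers <- all_kmers(k)
  counts <- setNames(integer(length(kmers)), kmers)
  n <- nchar(seq)
  if (n >= k) {
    for (s in seq_len(n - k + 1L)) {
      w <- substr(seq, s, s + k - 1L)
      if (grepl("^[ACGT]+$", w)) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# Textbook Pearson correlation: covariance over the product of standard
# deviations, computed from first principles.
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Pair-counting adjusted Rand index: loops over all item pairs and counts
# agreements/disagreements directly.
pair_counting_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) n11 <- n11 + 1
      else if (!same_a && !same_b) n00 <- n00 + 1
      else if (same_a) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / total
  maximum <- ((n11 + n10) + (n11 + n01)) / 2
  if (maximum == expected) return(1)
  (n11 - expected) / (maximum - expected)
}

# O(n^3) brute-force triad enumeration: loops over every candidate
# (lncRNA, miRNA, RBP) triple and tests the three supporting edges by
# membership.
brute_force_triads <- function(rbp_lnc, mi_lnc, mi_rbp) {
  lncs <- unique(c(rbp_lnc$source, mi_lnc$target))
  mirs <- unique(c(mi_lnc$source, mi_rbp$source))
  rbps <- unique(c(rbp_lnc$target, mi_rbp$target))
  has <- function(df, s, t) any(df$source == s & df$target == t)
  rows <- list()
  for (L in lncs) for (M in mirs) for (P in rbps) {
    if (has(rbp_lnc, L, P) && has(mi_lnc, M, L) && has(mi_rbp, M, P)) {
      rows[[length(rows) + 1L]] <- data.frame(
        lncRNA_id = L, miRNA_id = M, rbp_id = P, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(lncRNA_id = character(0), miRNA_id = character(0),
                      rbp_id = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$lncRNA_id, out$miRNA_id, out$rbp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random helpers ------------------------------------------------------------

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_edge_df <- function(sources, targets, n, edge_class) {
  data.frame(source = sample(sources, n, replace = TRUE),
             target = sample(targets, n, replace = TRUE),
             edge_class = edge_class,
             evidence = "test",
             stringsAsFactors = FALSE)
}

# Planted-partition weighted adjacency matrix: blocks of nodes, dense
# high-weight within, sparse low-weight between.
planted_partition_adjacency <- function(n_blocks = 4L, block_size = 30L,
                                        p_within = 0.8, p_between = 0.05,
                                        w_within = c(0.5, 1),
                                        w_between = c(0, 0.2)) {
  n <- n_blocks * block_size
  labels <- rep(seq_len(n_blocks), each = block_size)
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (labels[i] == labels[j]) {
        if (runif(1) < p_within) adj[i, j] <- runif(1, w_within[1], w_within[2])
      } else {
        if (runif(1) < p_between) adj[i, j] <- runif(1, w_between[1], w_between[2])
      }
      adj[j, i] <- adj[i, j]
    }
  }
  diag(adj) <- 1
  ids <- sprintf("node%03d", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  list(adj = adj, labels = setNames(labels, ids))
}
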