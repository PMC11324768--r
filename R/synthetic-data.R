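# Synthetic-input generators with planted structure. Every generator is a
# pure function of (configuration, seed): identical calls yield identical
# outputs, and the planted truth is returned alongside so recovery can be
# scored exactly.

#' Generate transcript sequences with block-specific hexamer enrichment
#'
#' Emulates the premise that functionally related lncRNAs share k-mer
#' profiles: background bases are drawn i.i.d. at the configured GC
#' content, and each block of transcripts receives its own set of
#' designated k-mer motifs planted at `enrichment` times their background
#' expectation. Motif copies overwrite background bases (length is
#' unchanged), so downstream per-kilobase density normalization is
#' exercised honestly.
#'
#' @param block_sizes Integer vector of transcripts per block (each >= 2).
#' @param length_range Length 2 vector, min/max transcript length in nt.
#' @param motifs_per_block Distinct planted motifs per block.
#' @param enrichment Target motif abundance as a multiple of background
#'   expectation (>= 1; 1 plants nothing).
#' @param gc Background GC content in (0, 1).
#' @param k Motif length (matches the profiling k).
#' @param seed Integer seed; same configuration + seed reproduces the
#'   output exactly.
#' @return List with `sequences` (named [Biostrings::DNAStringSet]),
#'   `truth` (data frame `transcript_id`, `block`), and `motifs` (list of
#'   per-block motif vectors).
#' @export
generate_sequences <- function(block_sizes = c(30L, 30L, 30L, 30L),
                               length_range = c(1000L, 3000L),
                               motifs_per_block = 25L,
                               enrichment = 8,
                               gc = 0.5,
                               k = 6L,
                               seed = 1L) {
  stopifnot(length(block_sizes) >= 1L, all(block_sizes >= 2L),
            length(length_range) == 2L, gc > 0, gc < 1, enrichment >= 1)
  if (length_range[1L] < k) {
    stop("minimum sequence length must be at least k", call. = FALSE)
  }
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    n_blocks <- length(block_sizes)
    all_motifs <- replicate(n_blocks * motifs_per_block,
                            paste(sample(bases, k, replace = TRUE,
                                         prob = p), collapse = ""))
    while (anyDuplicated(all_motifs)) {
      all_motifs[duplicated(all_motifs)] <-
        replicate(sum(duplicated(all_motifs)),
                  paste(sample(bases, k, replace = TRUE, prob = p),
                        collapse = ""))
    }
    motifs <- split(all_motifs, rep(seq_len(n_blocks), each = motifs_per_block))
    names(motifs) <- as.character(seq_len(n_blocks) - 1L)
    n_total <- sum(block_sizes)
    ids <- sprintf("SYNLNC%04d", seq_len(n_total))
    blocks <- rep(seq_len(n_blocks) - 1L, times = block_sizes)
    seqs <- character(n_total)
    for (i in seq_len(n_total)) {
      L <- sample(seq(length_range[1L], length_range[2L]), 1L)
      chars <- sample(bases, L, replace = TRUE, prob = p)
      # planted copies are kept disjoint across ALL of the block's motifs,
      # so one planted copy never overwrites another and the realized
      # motif frequency stays close to the enrichment target
      candidates <- sample(seq_len(L - k + 1L))
      used <- integer(0)
      for (motif in motifs[[as.character(blocks[i])]]) {
        pm <- prod(p[strsplit(motif, "")[[1L]]])
        n_extra <- stats::rpois(1L, (enrichment - 1) * (L - k + 1) * pm)
        if (n_extra == 0L) next
        planted <- 0L
        for (s in candidates) {
          if (planted >= n_extra) break
          if (any(abs(s - used) < k)) next
          chars[s:(s + k - 1L)] <- strsplit(motif, "")[[1L]]
          used <- c(used, s)
          planted <- planted + 1L
        }
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- ids
    list(sequences = sequences,
         truth = data.frame(transcript_id = ids, block = blocks,
                            stringsAsFactors = FALSE),
         motifs = motifs)
  })
}

#' Generate differential-expression tables with planted shared effects
#'
#' Emulates the inputs of cross-dataset consensus filtering: a fixed gene
#' universe measured in `n_datasets` independent datasets. Genes in
#' `shared_effect_ids` receive |log2FC| >= `effect_size` with p < 0.001 in
#' every dataset, with the sign drawn independently per dataset (modeling
#' discordant directions between cohorts). All other genes are null:
#' log2FC ~ Normal(0, 0.03) and p ~ Uniform(0, 1).
#'
#' @param gene_ids Character vector: the gene universe.
#' @param n_datasets Number of datasets/tables to simulate.
#' @param shared_effect_ids Subset of `gene_ids` with a planted shared
#'   effect.
#' @param effect_size Minimum |log2FC| of planted effects (keep it above
#'   the filter threshold the tables are meant to exercise).
#' @param biotype Single biotype or vector along `gene_ids`.
#' @param seed Integer seed.
#' @return List of data frames (one per dataset) with columns `gene_id`,
#'   `symbol`, `biotype`, `log2fc`, `pvalue`, `dataset_id`.
#' @export
generate_dge_tables <- function(gene_ids, n_datasets = 2L,
                                shared_effect_ids = character(0),
                                effect_size = 1,
                                biotype = "lncRNA",
                                seed = 1L) {
  stopifnot(n_datasets >= 1L, all(shared_effect_ids %in% gene_ids),
            effect_size > 0)
  biotype <- rep_len(biotype, length(gene_ids))
  with_seed(seed, {
    lapply(seq_len(n_datasets), function(d) {
      n <- length(gene_ids)
      planted <- gene_ids %in% shared_effect_ids
      sign <- sample(c(-1, 1), n, replace = TRUE)
      log2fc <- stats::rnorm(n, 0, 0.03)
      log2fc[planted] <- sign[planted] *
        (effect_size + stats::runif(sum(planted), 0, 1))
      pvalue <- stats::runif(n, 0, 1)
      pvalue[planted] <- stats::runif(sum(planted), 0, 0.001)
      data.frame(gene_id = gene_ids,
                 symbol = NA_character_,
                 biotype = biotype,
                 log2fc = log2fc,
                 pvalue = pvalue,
                 dataset_id = sprintf("synthetic_ds%d", d),
                 stringsAsFactors = FALSE)
    })
  })
}

#' Generate bipartite interaction tables with planted hubs and triads
#'
#' Produces the three edge classes the triad stage consumes. Background
#' edges are i.i.d. Bernoulli at the configured per-class rates. For a
#' fraction `triad_rate` of each community's lncRNAs, one complete
#' (lncRNA, miRNA, RBP) edge triple is planted, drawing the miRNA/RBP from
#' `mirna_pool`/`rbp_pool` (pass the dysregulated subsets so planted
#' triads survive AD-mode filtering). Optional hubs are planted by wiring
#' a named node to a fixed number of community lncRNAs.
#'
#' Incidental triads — triples completed by background edges rather than
#' planting — are enumerated by brute force at truth-writing time so tests
#' can assert exact totals.
#'
#' @param members Named list: community label -> lncRNA ID vector.
#' @param n_rbps,n_mirnas Interactor universe sizes (IDs `RBP01`... and
#'   `mir-1`...).
#' @param hub_spec Optional data frame with columns `node`, `class`
#'   (`"rbp"` or `"mirna"`), `degree`, and optionally `community`; each
#'   row wires `node` to `degree` distinct lncRNAs of that community (or
#'   of the full set).
#' @param triad_rate Fraction of each community's lncRNAs given a planted
#'   triad, in \[0, 1\].
#' @param background_rates Named numeric vector of per-class edge
#'   probabilities (`rbp_lnc`, `mi_lnc`, `mi_rbp`).
#' @param rbp_pool,mirna_pool Candidate interactors for planted triads;
#'   default the full universe.
#' @param seed Integer seed.
#' @return List with the three edge data frames (`rbp_lnc`, `mi_lnc`,
#'   `mi_rbp`), `planted_triads`, `incidental_triads`, and `all_triads`.
#' @export
generate_interaction_tables <- function(members,
                                        n_rbps = 20L, n_mirnas = 30L,
                                        hub_spec = NULL,
                                        triad_rate = 0.5,
                                        background_rates = c(rbp_lnc = 0.02,
                                                             mi_lnc = 0.02,
                                                             mi_rbp = 0.05),
                                        rbp_pool = NULL,
                                        mirna_pool = NULL,
                                        seed = 1L) {
  stopifnot(is.list(members), triad_rate >= 0, triad_rate <= 1)
  rbps <- sprintf("RBP%02d", seq_len(n_rbps))
  mirnas <- sprintf("mir-%d", seq_len(n_mirnas))
  rbp_pool <- rbp_pool %||% rbps
  mirna_pool <- mirna_pool %||% mirnas
  stopifnot(all(rbp_pool %in% rbps), all(mirna_pool %in% mirnas))
  lncs <- unique(unlist(members, use.names = FALSE))
  with_seed(seed, {
    bern_pairs <- function(a, b, rate) {
      if (rate <= 0) {
        return(data.frame(source = character(0), target = character(0),
                          stringsAsFactors = FALSE))
      }
      hits <- which(matrix(stats::runif(length(a) * length(b)) < rate,
                           nrow = length(a)), arr.ind = TRUE)
      data.frame(source = a[hits[, 1L]], target = b[hits[, 2L]],
                 stringsAsFactors = FALSE)
    }
    rbp_lnc <- bern_pairs(lncs, rbps, background_rates[["rbp_lnc"]])
    mi_lnc <- bern_pairs(mirnas, lncs, background_rates[["mi_lnc"]])
    mi_rbp <- bern_pairs(mirnas, rbps, background_rates[["mi_rbp"]])
    if (!is.null(hub_spec)) {
      for (i in seq_len(nrow(hub_spec))) {
        pool <- if (!is.null(hub_spec$community) &&
                    !is.na(hub_spec$community[i])) {
          members[[as.character(hub_spec$community[i])]]
        } else lncs
        chosen <- sample(pool, min(hub_spec$degree[i], length(pool)))
        if (hub_spec$class[i] == "rbp") {
          rbp_lnc <- rbind(rbp_lnc, data.frame(source = chosen,
                                               target = hub_spec$node[i],
                                               stringsAsFactors = FALSE))
        } else {
          mi_lnc <- rbind(mi_lnc, data.frame(source = hub_spec$node[i],
                                             target = chosen,
                                             stringsAsFactors = FALSE))
        }
      }
    }
    planted <- list()
    for (lab in names(members)) {
      ids <- members[[lab]]
      n_pick <- round(triad_rate * length(ids))
      if (n_pick == 0L) next
      chosen <- sample(ids, n_pick)
      for (L in chosen) {
        M <- sample(mirna_pool, 1L)
        P <- sample(rbp_pool, 1L)
        rbp_lnc <- rbind(rbp_lnc, data.frame(source = L, target = P,
                                             stringsAsFactors = FALSE))
        mi_lnc <- rbind(mi_lnc, data.frame(source = M, target = L,
                                           stringsAsFactors = FALSE))
        mi_rbp <- rbind(mi_rbp, data.frame(source = M, target = P,
                                           stringsAsFactors = FALSE))
        planted[[length(planted) + 1L]] <-
          data.frame(lncRNA_id = L, miRNA_id = M, rbp_id = P,
                     stringsAsFactors = FALSE)
      }
    }
    finish <- function(df, cls) {
      df <- unique(df)
      df <- df[order(df$source, df$target), , drop = FALSE]
      rownames(df) <- NULL
      df$edge_class <- rep(cls, nrow(df))
      df$evidence <- rep("synthetic", nrow(df))
      df
    }
    rbp_lnc <- finish(rbp_lnc, "rbp_lnc")
    mi_lnc <- finish(mi_lnc, "mi_lnc")
    mi_rbp <- finish(mi_rbp, "mi_rbp")
    planted_triads <- if (length(planted) > 0L) {
      unique(do.call(rbind, planted))
    } else {
      data.frame(lncRNA_id = character(0), miRNA_id = character(0),
                 rbp_id = character(0), stringsAsFactors = FALSE)
    }
    all_triads <- enumerate_triads_dense(rbp_lnc, mi_lnc, mi_rbp)
    key <- function(t) paste(t$lncRNA_id, t$miRNA_id, t$rbp_id, sep = "\r")
    incidental <- all_triads[!key(all_triads) %in% key(planted_triads), ,
                             drop = FALSE]
    rownames(incidental) <- NULL
    list(rbp_lnc = rbp_lnc, mi_lnc = mi_lnc, mi_rbp = mi_rbp,
         planted_triads = planted_triads,
         incidental_triads = incidental,
         all_triads = all_triads)
  })
}

# Plain dense triple-loop triad enumeration over the node universes of the
# supplied tables. Quadratic-in-pairs and deliberately simple; used at
# truth-writing time, small inputs only.
enumerate_triads_dense <- function(rbp_lnc, mi_lnc, mi_rbp) {
  out <- list()
  lp <- paste(rbp_lnc$source, rbp_lnc$target, sep = "\r")
  for (m in sort(unique(c(mi_lnc$source, mi_rbp$source)))) {
    for (l in sort(unique(mi_lnc$target[mi_lnc$source == m]))) {
      for (p in sort(unique(mi_rbp$target[mi_rbp$source == m]))) {
        if (paste(l, p, sep = "\r") %in% lp) {
          out[[length(out) + 1L]] <- c(l, m, p)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(lncRNA_id = character(0), miRNA_id = character(0),
                      rbp_id = character(0), stringsAsFactors = FALSE))
  }
  mat <- do.call(rbind, out)
  df <- data.frame(lncRNA_id = mat[, 1L], miRNA_id = mat[, 2L],
                   rbp_id = mat[, 3L], stringsAsFactors = FALSE)
  df <- unique(df[order(df$lncRNA_id, df$miRNA_id, df$rbp_id), , drop = FALSE])
  rownames(df) <- NULL
  df
}

#' Generate per-tool subcellular localization predictions
#'
#' Draws a latent true compartment for each transcript from
#' `compartment_probs`, then lets each transcript be "concordant" with
#' probability `agreement_rate` (all tools report the true compartment) or
#' discordant (one randomly chosen tool reports a different compartment).
#'
#' @param transcript_ids Character vector of transcripts.
#' @param tools Character vector of tool names.
#' @param agreement_rate Probability that all tools agree on a transcript.
#' @param compartment_probs Named probability vector over compartments;
#'   the default is cytoplasm-heavy, as lncRNA localization predictors
#'   typically report.
#' @param seed Integer seed.
#' @return List with `predictions` (data frame `transcript_id`, `tool`,
#'   `compartment`) and `truth` (data frame `transcript_id`,
#'   `compartment`, `concordant`).
#' @export
generate_localization_predictions <- function(transcript_ids,
                                              tools = c("iLoc-LncRNA",
                                                        "lncLocator",
                                                        "Locate-R"),
                                              agreement_rate = 0.6,
                                              compartment_probs = c(
                                                cytoplasm = 0.6,
                                                nucleus = 0.25,
                                                ribosome = 0.05,
                                                exosome = 0.10),
                                              seed = 1L) {
  stopifnot(agreement_rate >= 0, agreement_rate <= 1, length(tools) >= 1L)
  comps <- names(compartment_probs)
  with_seed(seed, {
    true_comp <- sample(comps, length(transcript_ids), replace = TRUE,
                        prob = compartment_probs)
    concordant <- stats::runif(length(transcript_ids)) < agreement_rate
    rows <- lapply(seq_along(transcript_ids), function(i) {
      comp <- rep(true_comp[i], length(tools))
      if (!concordant[i]) {
        off_tool <- sample(seq_along(tools), 1L)
        comp[off_tool] <- sample(setdiff(comps, true_comp[i]), 1L)
      }
      data.frame(transcript_id = transcript_ids[i], tool = tools,
                 compartment = comp, stringsAsFactors = FALSE)
    })
    list(predictions = do.call(rbind, rows),
         truth = data.frame(transcript_id = transcript_ids,
                            compartment = true_comp,
                            concordant = concordant,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Control dCt values are centred on `base_dct`; treated replicates are
#' shifted by the gene's true ddCt (so the expected fold change is
#' `2^-ddct`), with Gaussian replicate noise.
#'
#' @param ddct_effects Named numeric vector: gene -> true ddCt.
#' @param n_replicates Replicates per group.
#' @param base_ct Reference-gene Ct level.
#' @param base_dct Control-group dCt level.
#' @param noise_sd Replicate noise SD in cycles.
#' @param seed Integer seed.
#' @return Ct measurement data frame accepted by [ddct_fold_change()].
#' @export
generate_ct_table <- function(ddct_effects, n_replicates = 3L,
                              base_ct = 15, base_dct = 8,
                              noise_sd = 0.15, seed = 1L) {
  with_seed(seed, {
    rows <- lapply(names(ddct_effects), function(g) {
      dct_c <- base_dct + stats::rnorm(n_replicates, 0, noise_sd)
      dct_t <- base_dct + ddct_effects[[g]] +
        stats::rnorm(n_replicates, 0, noise_sd)
      data.frame(
        sample_group = rep(c("control", "treated"), each = n_replicates),
        gene = g,
        reference_gene = "REF",
        ct_target = base_ct + c(dct_c, dct_t),
        ct_reference = base_ct,
        replicate = rep(seq_len(n_replicates), 2L),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
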