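# End-to-end orchestration: consensus filtering -> k-mer community
# segregation -> bipartite network construction and degree ranking ->
# regulatory triad enumeration -> localization consensus, with a
# deterministic on-disk report bundle.

#' Assemble and validate a pipeline configuration
#'
#' @param de_tables Character vector of paths to the RNA-seq
#'   differential-expression TSVs (one per dataset; the consensus is the
#'   intersection across all of them).
#' @param mirna_de_table Path to the small-RNA DE TSV used for the
#'   dysregulated miRNA set.
#' @param fasta Path to the FASTA of canonical lncRNA transcripts.
#' @param rbp_lnc,mi_lnc,mi_rbp Paths to the three interaction edge TSVs.
#' @param localization Path to the per-tool localization prediction TSV.
#' @param out_dir Output directory for the report bundle.
#' @param criteria A [filter_criteria()] object.
#' @param k,pseudocount k-mer profiling parameters (see
#'   [seekr_profile()]).
#' @param edge_threshold,resolution,louvain_seed,restarts,pool_max_size
#'   Community detection parameters (see [louvain_communities()]).
#' @param required_tools Tools whose agreement defines the localization
#'   consensus; defaults to every tool found in the prediction table.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(de_tables, mirna_de_table, fasta,
                            rbp_lnc, mi_lnc, mi_rbp, localization,
                            out_dir,
                            criteria = filter_criteria(),
                            k = 6L, pseudocount = 1.0,
                            edge_threshold = 0, resolution = 1,
                            louvain_seed = 0L, restarts = 10L,
                            pool_max_size = 1L,
                            required_tools = NULL) {
  paths <- c(de_tables, mirna_de_table, fasta, rbp_lnc, mi_lnc, mi_rbp,
             localization)
  missing_paths <- paths[!file.exists(paths)]
  if (length(missing_paths) > 0L) {
    stop("configured input path(s) do not exist: ",
         paste(missing_paths, collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(criteria, "filter_criteria"))
  structure(list(de_tables = de_tables, mirna_de_table = mirna_de_table,
                 fasta = fasta, rbp_lnc = rbp_lnc, mi_lnc = mi_lnc,
                 mi_rbp = mi_rbp, localization = localization,
                 out_dir = out_dir, criteria = criteria,
                 k = as.integer(k), pseudocount = pseudocount,
                 edge_threshold = edge_threshold, resolution = resolution,
                 louvain_seed = as.integer(louvain_seed),
                 restarts = as.integer(restarts),
                 pool_max_size = as.integer(pool_max_size),
                 required_tools = required_tools),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Relative paths in the file are resolved against the file's directory.
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [pipeline_config()] (criteria as a `fc_up`/`fc_down`/`alpha` block).
#' @return A `pipeline_config` object.
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  crit <- cfg$criteria %||% list()
  pipeline_config(
    de_tables = resolve(unlist(cfg$de_tables)),
    mirna_de_table = resolve(cfg$mirna_de_table),
    fasta = resolve(cfg$fasta),
    rbp_lnc = resolve(cfg$rbp_lnc),
    mi_lnc = resolve(cfg$mi_lnc),
    mi_rbp = resolve(cfg$mi_rbp),
    localization = resolve(cfg$localization),
    out_dir = resolve(cfg$out_dir %||% "lnctriad_out"),
    criteria = filter_criteria(fc_up = crit$fc_up %||% 0.1,
                               fc_down = crit$fc_down %||% -0.1,
                               alpha = crit$alpha %||% 0.05),
    k = cfg$k %||% 6L,
    pseudocount = cfg$pseudocount %||% 1.0,
    edge_threshold = cfg$edge_threshold %||% 0,
    resolution = cfg$resolution %||% 1,
    louvain_seed = cfg$louvain_seed %||% 0L,
    restarts = cfg$restarts %||% 10L,
    pool_max_size = cfg$pool_max_size %||% 1L,
    required_tools = cfg$required_tools)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes consensus differential-expression filtering, k-mer community
#' segregation, AD/comprehensive bipartite network construction with
#' degree rankings for both edge classes, regulatory triad enumeration
#' with per-community participation, and localization consensus voting.
#' All report tables, GML networks and a run log are written under
#' `config$out_dir`; with a fixed configuration the bundle is
#' byte-identical across runs.
#'
#' @param config A `pipeline_config` (or path to a YAML config file).
#' @return An object of class `lnctriad_report` (list of all intermediate
#'   and final results), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  ## 1. consensus differential-expression filtering
  filt <- run_stage("dge_filter", {
    tables <- lapply(config$de_tables, read_dge_table)
    lnc <- consensus_dysregulated_set(tables, "lncRNA", config$criteria)
    pc <- consensus_dysregulated_set(tables, "protein_coding", config$criteria)
    mir_tab <- read_dge_table(config$mirna_de_table)
    mir_status <- classify_regulation(mir_tab$log2fc, mir_tab$pvalue,
                                      config$criteria)
    mir_ids <- normalize_mirna_ids(
      mir_tab$gene_id[mir_tab$biotype == "miRNA" &
                        mir_status != "not_significant"])
    list(lnc = lnc, pc = pc, mirna_ids = sort(unique(mir_ids)),
         tables = tables)
  })
  write_tsv(filt$lnc$evidence, out("consensus_lncRNAs.tsv"))
  write_tsv(filt$pc$evidence, out("consensus_protein_coding.tsv"))
  write_tsv(data.frame(mirna_id = filt$mirna_ids), out("dysregulated_miRNAs.tsv"))

  ## 2. k-mer community segregation of the consensus lncRNAs
  comm <- run_stage("kmer_community", {
    seqs <- read_fasta(config$fasta)
    keep <- intersect(names(seqs), filt$lnc$ids)
    if (length(keep) < 2L) {
      stop("fewer than 2 consensus lncRNAs with sequence information")
    }
    if (length(keep) < length(filt$lnc$ids)) {
      message(sprintf("%d consensus lncRNA(s) lack a sequence and are skipped",
                      length(filt$lnc$ids) - length(keep)))
    }
    seqs <- seqs[keep]
    profiles <- seekr_profile(seqs, k = config$k,
                              pseudocount = config$pseudocount)
    adj <- pearson_adjacency(profiles)
    assignment <- louvain_communities(adj,
                                      edge_threshold = config$edge_threshold,
                                      resolution = config$resolution,
                                      seed = config$louvain_seed,
                                      restarts = config$restarts,
                                      pool_max_size = config$pool_max_size)
    list(seqs = seqs, profiles = profiles, adj = adj,
         assignment = assignment)
  })
  write_tsv(data.frame(transcript_id = names(comm$assignment$labels),
                       community = unname(comm$assignment$labels)),
            out("communities.tsv"))
  write_tsv(data.frame(transcript_id = rownames(comm$adj),
                       round(as.data.frame(comm$adj), 6)),
            out("adjacency.tsv"))

  ## 3. per-community bipartite networks and degree rankings
  nets <- run_stage("interaction_networks", {
    rbp_edges <- read_edge_table(config$rbp_lnc, "rbp_lnc")
    mi_edges <- read_edge_table(config$mi_lnc, "mi_lnc")
    mi_edges$source <- normalize_mirna_ids(mi_edges$source)
    members <- community_members(comm$assignment)
    ev1 <- filt$lnc$evidence[filt$lnc$evidence$dataset_id ==
                               filt$lnc$datasets[1L], , drop = FALSE]
    lnc_fc <- stats::setNames(ev1$log2fc, ev1$gene_id)
    res <- list()
    for (lab in names(members)) {
      for (cls in c("rbp_lnc", "mi_lnc")) {
        edges <- if (cls == "rbp_lnc") rbp_edges else mi_edges
        dys <- if (cls == "rbp_lnc") filt$pc$ids else filt$mirna_ids
        for (mode in c("AD", "comprehensive")) {
          net <- build_network(edges, members[[lab]], mode = mode,
                               dysregulated_interactors = dys,
                               lnc_log2fc = lnc_fc,
                               community_label = as.integer(lab))
          key <- sprintf("%s_%s_community%s", cls, mode, lab)
          res[[key]] <- list(
            network = net,
            ranking_lnc = degree_ranking(net, "lncRNA"),
            ranking_inter = degree_ranking(net, "interactor"))
        }
      }
    }
    res
  })
  for (key in names(nets)) {
    write_gml(nets[[key]]$network, out(paste0("network_", key, ".gml")))
    write_network_edge_tsv(nets[[key]]$network, out(paste0("edges_", key, ".tsv")))
    write_tsv(nets[[key]]$ranking_inter,
              out(paste0("ranking_interactor_", key, ".tsv")))
    write_tsv(nets[[key]]$ranking_lnc,
              out(paste0("ranking_lncRNA_", key, ".tsv")))
  }
  top_nodes <- do.call(rbind, lapply(names(nets), function(key) {
    info <- nets[[key]]
    top <- function(r) {
      if (nrow(r) == 0L || max(r$degree) == 0L) {
        return(data.frame(nodes = NA_character_, degree = NA_integer_))
      }
      data.frame(nodes = paste(r$node_id[r$rank == 1L], collapse = ","),
                 degree = r$degree[1L])
    }
    ti <- top(info$ranking_inter); tl <- top(info$ranking_lnc)
    data.frame(community = info$network$community_label,
               edge_class = info$network$edge_class,
               mode = info$network$mode,
               top_interactors = ti$nodes, interactor_degree = ti$degree,
               top_lncRNAs = tl$nodes, lncRNA_degree = tl$degree,
               stringsAsFactors = FALSE)
  }))
  top_nodes <- top_nodes[order(top_nodes$community, top_nodes$edge_class,
                               top_nodes$mode), , drop = FALSE]
  write_tsv(top_nodes, out("top_nodes.tsv"))

  ## 4. regulatory triads from each community's AD networks
  triads <- run_stage("triad_finder", {
    mi_rbp <- read_edge_table(config$mi_rbp, "mi_rbp")
    mi_rbp$source <- normalize_mirna_ids(mi_rbp$source)
    members <- community_members(comm$assignment)
    per_comm <- lapply(names(members), function(lab) {
      rl <- nets[[sprintf("rbp_lnc_AD_community%s", lab)]]$network$edges
      ml <- nets[[sprintf("mi_lnc_AD_community%s", lab)]]$network$edges
      tr <- find_triads(
        data.frame(source = rl$lncRNA_id, target = rl$interactor_id,
                   stringsAsFactors = FALSE),
        data.frame(source = ml$interactor_id, target = ml$lncRNA_id,
                   stringsAsFactors = FALSE),
        mi_rbp)
      if (nrow(tr) > 0L) tr$community <- lab else tr$community <- character(0)
      tr
    })
    all_triads <- do.call(rbind, per_comm)
    summary <- triad_participation(all_triads, members)
    list(triads = all_triads, summary = summary)
  })
  write_tsv(triads$triads, out("triads.tsv"))
  write_tsv(triads$summary, out("triad_summary.tsv"))
  if (nrow(triads$triads) > 0L) {
    write_gml(triads_as_igraph(triads$triads), out("triad_network.gml"))
  }

  ## 5. subcellular localization consensus
  loc <- run_stage("localization_consensus", {
    pred <- read_tsv(config$localization)
    # appearance order, not sort(): collation is locale-dependent and the
    # report must serialize identically everywhere
    tools <- config$required_tools %||% unique(pred$tool)
    cons <- consensus_localization(pred, tools)
    members <- community_members(comm$assignment)
    dist <- do.call(rbind, lapply(names(members), function(lab) {
      do.call(rbind, lapply(tools, function(tl) {
        pct <- compartment_distribution(pred, tl, members[[lab]])
        data.frame(community = lab, tool = tl,
                   compartment = names(pct), pct = round(unname(pct), 4),
                   stringsAsFactors = FALSE)
      }))
    }))
    list(consensus = cons, distribution = dist, predictions = pred)
  })
  cons_df <- do.call(rbind, lapply(names(loc$consensus$assignments), function(cp) {
    ids <- loc$consensus$assignments[[cp]]
    if (length(ids) == 0L) return(NULL)
    data.frame(transcript_id = ids, compartment = cp, stringsAsFactors = FALSE)
  }))
  write_tsv(cons_df %||% data.frame(transcript_id = character(0),
                                    compartment = character(0)),
            out("localization_consensus.tsv"))
  write_tsv(loc$distribution, out("localization_distribution.tsv"))

  ## 6. run log
  writeLines(c(
    sprintf("lnctriad version: %s",
            as.character(utils::packageVersion("lnctriad"))),
    sprintf("igraph version: %s",
            as.character(utils::packageVersion("igraph"))),
    sprintf("Biostrings version: %s",
            as.character(utils::packageVersion("Biostrings"))),
    sprintf("louvain seed: %d (restarts: %d)", config$louvain_seed,
            config$restarts),
    sprintf("k: %d, pseudocount: %g, edge threshold: %g, resolution: %g",
            config$k, config$pseudocount, config$edge_threshold,
            config$resolution),
    sprintf("criteria: log2FC > %g / < %g, p < %g", config$criteria$fc_up,
            config$criteria$fc_down, config$criteria$alpha),
    sprintf("datasets: %s", paste(basename(config$de_tables), collapse = ", "))),
    out("run_log.txt"))

  report <- structure(list(config = config, consensus = filt,
                           communities = comm, networks = nets,
                           top_nodes = top_nodes, triads = triads,
                           localization = loc),
                      class = "lnctriad_report")
  invisible(report)
}

#' @export
print.lnctriad_report <- function(x, ...) {
  cat("lnctriad pipeline report\n")
  cat(sprintf("  consensus lncRNAs: %d; protein-coding: %d; miRNAs: %d\n",
              length(x$consensus$lnc$ids), length(x$consensus$pc$ids),
              length(x$consensus$mirna_ids)))
  print(x$communities$assignment)
  cat(sprintf("  triads: %d across %d communit%s\n",
              nrow(x$triads$triads), nrow(x$triads$summary),
              if (nrow(x$triads$summary) == 1L) "y" else "ies"))
  for (i in seq_len(nrow(x$triads$summary))) {
    s <- x$triads$summary[i, ]
    cat(sprintf("    community %s: %d/%d lncRNAs in triads (%.1f%%)\n",
                s$community_label, s$n_participating, s$n_lncRNAs,
                s$participation_pct))
  }
  counts <- vapply(x$localization$consensus$assignments, length, integer(1))
  cat(sprintf("  localization consensus: %s\n",
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  cat(sprintf("  report written to: %s\n", x$config$out_dir))
  invisible(x)
}

#' Simulate a complete set of pipeline inputs
#'
#' Writes every input the pipeline consumes — FASTA with planted
#' community-specific hexamer enrichment, DE tables with planted shared
#' effects for lncRNA and protein-coding genes, a small-RNA DE table, the
#' three interaction edge tables with planted hubs and triads, and
#' per-tool localization predictions — plus a ground-truth JSON sidecar
#' and a ready-to-run YAML configuration.
#'
#' Planted triads draw their miRNA/RBP from the dysregulated subsets so
#' they survive AD-mode filtering; an RBP hub is wired to a fixed fraction
#' of the first block's lncRNAs, emulating a dominant community RBP.
#'
#' @param dir Directory to write inputs into (created if needed).
#' @param seed Master seed; per-generator seeds are derived by small
#'   offsets.
#' @param block_sizes Community block sizes for the sequence generator.
#' @param enrichment Motif enrichment multiple for block motifs.
#' @param n_null_lnc Null (non-dysregulated) lncRNA genes added to the DE
#'   tables.
#' @param n_rbps,n_dys_rbps RBP universe size and dysregulated subset size.
#' @param n_mirnas,n_dys_mirnas miRNA universe and dysregulated subset.
#' @param triad_rate Fraction of each community's lncRNAs with a planted
#'   triad.
#' @param hub_coverage Fraction of block-0 lncRNAs wired to the planted
#'   hub RBP.
#' @param agreement_rate Localization tool agreement rate.
#' @return List with `config` (a `pipeline_config`), `config_path`, and
#'   `truth` (planted structure).
#' @export
simulate_pipeline_inputs <- function(dir, seed = 1L,
                                     block_sizes = c(30L, 30L, 30L, 30L),
                                     enrichment = 8,
                                     n_null_lnc = 200L,
                                     n_rbps = 20L, n_dys_rbps = 12L,
                                     n_mirnas = 30L, n_dys_mirnas = 18L,
                                     triad_rate = 0.65,
                                     hub_coverage = 0.86,
                                     agreement_rate = 0.6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_sequences(block_sizes = block_sizes,
                            enrichment = enrichment, seed = seed)
  fasta <- file.path(dir, "lncRNA_sequences.fa")
  write_fasta(gen$sequences, fasta)

  lnc_ids <- gen$truth$transcript_id
  null_lnc <- sprintf("NULLLNC%04d", seq_len(n_null_lnc))
  rbps <- sprintf("RBP%02d", seq_len(n_rbps))
  dys_rbps <- rbps[seq_len(n_dys_rbps)]
  null_pc <- sprintf("PCG%04d", seq_len(100L))
  universe <- c(lnc_ids, null_lnc, rbps, null_pc)
  biotypes <- c(rep("lncRNA", length(lnc_ids) + length(null_lnc)),
                rep("protein_coding", length(rbps) + length(null_pc)))
  de <- generate_dge_tables(universe, n_datasets = 2L,
                            shared_effect_ids = c(lnc_ids, dys_rbps),
                            effect_size = 1, biotype = biotypes,
                            seed = seed + 1L)
  de_paths <- vapply(seq_along(de), function(i) {
    p <- file.path(dir, sprintf("de_dataset%d.tsv", i))
    write_tsv(de[[i]], p)
    p
  }, character(1))

  mirnas <- sprintf("mir-%d", seq_len(n_mirnas))
  dys_mirnas <- mirnas[seq_len(n_dys_mirnas)]
  mir_de <- generate_dge_tables(mirnas, n_datasets = 1L,
                                shared_effect_ids = dys_mirnas,
                                effect_size = 1, biotype = "miRNA",
                                seed = seed + 2L)[[1L]]
  mir_de$dataset_id <- "synthetic_smallrna"
  mir_path <- file.path(dir, "de_mirna.tsv")
  write_tsv(mir_de, mir_path)

  members <- split(gen$truth$transcript_id, gen$truth$block)
  hub <- data.frame(node = dys_rbps[1L], class = "rbp",
                    degree = as.integer(round(hub_coverage * block_sizes[1L])),
                    community = "0", stringsAsFactors = FALSE)
  inter <- generate_interaction_tables(members, n_rbps = n_rbps,
                                       n_mirnas = n_mirnas,
                                       hub_spec = hub,
                                       triad_rate = triad_rate,
                                       rbp_pool = dys_rbps,
                                       mirna_pool = dys_mirnas,
                                       seed = seed + 3L)
  edge_paths <- list()
  for (cls in c("rbp_lnc", "mi_lnc", "mi_rbp")) {
    p <- file.path(dir, paste0("edges_", cls, ".tsv"))
    write_edge_table(inter[[cls]], p)
    edge_paths[[cls]] <- p
  }

  loc <- generate_localization_predictions(lnc_ids,
                                           agreement_rate = agreement_rate,
                                           seed = seed + 4L)
  loc_path <- file.path(dir, "localization_predictions.tsv")
  write_tsv(loc$predictions, loc_path)

  truth <- list(seed = seed,
                blocks = stats::setNames(as.list(gen$truth$block),
                                         gen$truth$transcript_id),
                motifs = gen$motifs,
                planted_shared_de = c(lnc_ids, dys_rbps),
                dysregulated_rbps = dys_rbps,
                dysregulated_mirnas = dys_mirnas,
                hub = as.list(hub[1L, ]),
                planted_triads = inter$planted_triads,
                incidental_triads = inter$incidental_triads,
                localization = loc$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  config <- pipeline_config(de_tables = de_paths, mirna_de_table = mir_path,
                            fasta = fasta,
                            rbp_lnc = edge_paths$rbp_lnc,
                            mi_lnc = edge_paths$mi_lnc,
                            mi_rbp = edge_paths$mi_rbp,
                            localization = loc_path,
                            out_dir = file.path(dir, "report"))
  cfg_yaml <- list(de_tables = basename(de_paths),
                   mirna_de_table = basename(mir_path),
                   fasta = basename(fasta),
                   rbp_lnc = basename(edge_paths$rbp_lnc),
                   mi_lnc = basename(edge_paths$mi_lnc),
                   mi_rbp = basename(edge_paths$mi_rbp),
                   localization = basename(loc_path),
                   out_dir = "report",
                   criteria = list(fc_up = 0.1, fc_down = -0.1, alpha = 0.05),
                   k = 6L, pseudocount = 1.0, edge_threshold = 0,
                   resolution = 1, louvain_seed = 0L, restarts = 10L,
                   pool_max_size = 1L)
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg_yaml, config_path)
  list(config = config, config_path = config_path, truth = truth)
}
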