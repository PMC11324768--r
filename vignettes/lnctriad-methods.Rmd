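---
title: "Methods: k-mer communities and regulatory triads of dysregulated lncRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer communities and regulatory triads of dysregulated lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnctriad)
```

## The analysis in one paragraph

Long non-coding RNAs (lncRNAs) rarely share linear sequence homology, so
alignment cannot group them by function. The working assumption of this
package is the k-mer-profile view: transcripts with correlated 6-mer
usage tend to share localization and protein/miRNA interaction partners.
Starting from per-dataset differential-expression (DE) tables, the
pipeline (i) builds a consensus set of dysregulated lncRNAs, (ii)
segregates them into communities by Louvain modularity optimization on
the Pearson correlation of standardized 6-mer profiles, (iii) builds
per-community bipartite networks against RBPs and miRNAs in a
disease-restricted ("AD") and an unrestricted ("comprehensive") mode and
ranks nodes by degree, (iv) enumerates (lncRNA, miRNA, RBP) regulatory
triads — the competing-endogenous-RNA motif in which the lncRNA sponges a
miRNA that also targets the mRNA of the lncRNA's own RBP partner — and
reports the fraction of each community participating in at least one
triad, and (v) votes a consensus subcellular localization across
prediction tools. A 2^-ddCt module summarizes qPCR validation
experiments.

## Consensus differential-expression filtering

A gene is called dysregulated in one dataset when `log2FC > fc_up` or
`log2FC < fc_down` with `p < alpha`; all inequalities strict, so boundary
values are not called. Defaults are `fc_up = 0.1`, `fc_down = -0.1`,
`alpha = 0.05` (unadjusted p). These are deliberately permissive: a
holistic screen wants inclusion, and several lncRNAs with well-replicated
disease roles show |log2FC| well below conventional cut-offs. An optional
`padj` column supports FDR-based screening for users who want stringency.

Three choices deserve emphasis because they change the answer:

* **Intersection semantics.** The consensus set contains genes
  significant in *every* dataset; a gene absent from one dataset's output
  is treated as not significant there, hence excluded. The data do not
  distinguish "measured null" from "not measured", and we prefer the
  conservative reading.
* **Discordant directions are retained.** Expression of the same
  transcript can move in opposite directions in different case cohorts;
  direction is judged independently per dataset and disagreement does not
  exclude a gene.
* **Sex-biased subset.** Genes sex-biased in the disease cohort are
  reduced by those sex-biased in controls, isolating disease-specific sex
  bias by set subtraction, not by interaction modeling.

## k-mer profiles and community segregation

For each transcript, overlapping 6-mers are counted (windows containing
any non-ACGT character are skipped; `U` and case are normalized at
parse time). Counts become densities per kilobase of *full* transcript
length, are log2-transformed after adding a pseudocount (default 1,
keeping absent k-mers finite at 0), and each of the 4096 k-mer columns is
z-scored across the transcript set. Zero-variance columns (and the
single-transcript degenerate case) are set to 0. The order —
density, log, z-score — follows the published SEEKR convention; both the
pseudocount and `k` are exposed.

Pearson correlation of profile vectors gives the adjacency. Since a
correlation is almost never exactly zero, the literal "non-zero elements
are edges" rule would produce a complete graph; sparsity comes from the
`edge_threshold` parameter. The default keeps edges with `r > 0`,
weighted by `r`: positive profile similarity is the meaningful signal,
and negative correlations are not interpretable as positive modularity
weights.

Louvain is order-dependent, so `louvain_communities()` runs `restarts`
(default 10) optimizations from consecutive seeds and keeps the
max-modularity partition, ties broken by the earliest seed — identical
inputs always return identical partitions. Communities are relabeled
0, 1, 2, ... by non-increasing size. Transcripts the procedure fails to
place — isolated nodes under the threshold, or members of communities of
at most `pool_max_size` members (default: singletons) — are pooled into a
trailing *null community* with the largest label. A resolution parameter
is exposed but defaults to classic modularity (1).

## Networks, degree ranking, triads

Bipartite networks are built per community and edge class. "AD" mode
keeps only interactors that are themselves in the dysregulated set
(consensus protein-coding genes for RBPs; the significant small-RNA set
for miRNAs); "comprehensive" mode keeps every supported interactor, so
the AD edge set is always a subset of the comprehensive one. Multiple
evidence rows collapse to one edge: degree counts distinct partners, not
citations. Community lncRNAs with no retained edges stay as isolated
nodes because they belong in participation denominators. Where
interaction databases disagree on miRNA spelling, identifiers are
normalized by stripping the species prefix and case-folding while
preserving the mature-arm suffix. When two predicted/validated sources
supply the same class of edges they are merged by union: the network
stage tests co-occurrence of support, not its provenance.

Degree rankings sort by degree descending with alphabetical
tie-breaking; tied degrees share a dense rank, so "rank 1" can be a
cluster of nodes, matching how network viewers group equal-degree nodes.

A triad (L, M, P) exists iff the three supporting edges exist:
(L, P) in the RBP–lncRNA set, (M, L) in the miRNA–lncRNA set, and
(M, P) in the miRNA–RBP set. The implementation indexes by miRNA and
joins lncRNA and RBP target lists, but the result is defined purely
set-theoretically and is checked in the test suite against an O(n^3)
brute-force enumerator. Triads are computed from the AD-mode networks
(the comprehensive variant is a flag away), and participation
percentages use *all* community members as the denominator, retained at
full precision until reporting. All network members are eligible for
triads, not just top-ranked nodes.

## Localization consensus and qPCR summaries

Tool vocabularies are normalized onto
{cytoplasm, nucleus, ribosome, exosome, other}; unknown labels map to
`other` with a message. A transcript gets a consensus compartment only
when every required tool has a top-ranked prediction for it and all
agree; anything less leaves it unassigned. Consensus sets are therefore
pairwise disjoint, and dropping a tool from the requirement can only
grow them. Per-compartment probability vectors are out of scope — only
each tool's top compartment is consumed.

The qPCR module computes dCt per replicate, ddCt against the control
mean, and per-replicate fold changes `2^-ddCt` reported as mean ± SEM.
Significance is an unpaired two-sided Welch t-test on the dCt values,
not on fold changes: dCt is the approximately normal log-scale quantity.
With fewer than two replicates per group (or degenerate constant data)
the p-value is reported as not computable rather than guessed.

## What the synthetic data emulate — and what they do not

`simulate_pipeline_inputs()` generates every input format the pipeline
reads, with planted truth serialized alongside:

* **Sequences.** Four blocks of 30 transcripts, 1–3 kb, i.i.d. background
  at 50% GC, with 25 block-specific hexamer motifs planted at 8 times
  their background expectation. Twenty-five motifs may sound like many,
  but it mirrors how real k-mer communities arise from broad
  compositional signatures rather than one or two motifs; a design
  calculation (and the planted-recovery test) shows that with ~4096
  z-scored features, a handful of enriched hexamers is statistically
  invisible to profile correlation — the planted signal must span tens of
  k-mers for between-transcript correlation to rise above counting
  noise, exactly as compositional biology does. Planted copies overwrite
  background (length unchanged) and are kept mutually disjoint within a
  sequence so the realized enrichment tracks the target.
* **DE tables.** Planted shared-effect genes get |log2FC| ≥ 1 with
  p < 0.001 in every dataset, with per-dataset random sign to model
  discordant cohorts; nulls get log2FC ~ N(0, 0.03), p ~ U(0, 1).
* **Interactions.** Background Bernoulli edges per class, one planted
  RBP hub wired to 86% of block 0, and one complete planted triad for
  65% of each community's lncRNAs, drawn from the dysregulated pools so
  AD filtering keeps them. Incidental triads completed by background
  edges are enumerated by brute force at generation time so tests can
  assert exact totals.
* **Localization.** A latent cytoplasm-heavy compartment per transcript;
  all tools agree with probability 0.6, otherwise one random tool
  dissents.

The defaults (120 transcripts, two RNA-seq-like datasets plus one
small-RNA table, a hub covering 86% of its community, 65% planted triad
rate, 60% tool agreement) are chosen once to mirror the scale of a real
hippocampal lncRNA screen; those problem sizes are what the test suite
and the acceptance script run.

What passing on synthetic data does *not* show: real transcripts are not
i.i.d. background with inserted motifs (no repeats, no GC gradients, no
shared ancestry), real interaction tables have heavy-tailed degree
distributions and correlated evidence, and real localization predictors
err systematically rather than uniformly. Recovery on this generator
validates the machinery — filtering logic, profile arithmetic, graph
construction, enumeration — not biological performance.

## Numerical and degenerate-input choices

* Strict inequalities everywhere a threshold is stated; boundary values
  are not significant and threshold-equal correlations are not edges.
* Zero-variance profiles correlate 0 with everything (with a warning),
  keeping the adjacency finite; zero-variance k-mer columns z-score to 0.
* An all-isolated graph returns a single null community with a warning
  rather than failing.
* AD mode with an empty dysregulated set returns a valid edgeless
  network with a warning — empty is an answer, not an error.
* Report tables are written with fixed separators and no row names;
  the GML creator line is pinned and tool order follows file appearance
  (not locale-dependent sorting), so identical seeds yield byte-identical
  bundles on any machine.
* All generator randomness flows through a seed-restoring wrapper, so
  package calls never disturb the caller's RNG stream.

## A worked micro-example

```{r example}
members <- list(`0` = sprintf("L%02d", 1:20))
inter <- generate_interaction_tables(members, triad_rate = 0.65,
                                     background_rates = c(rbp_lnc = 0,
                                                          mi_lnc = 0,
                                                          mi_rbp = 0),
                                     seed = 1)
triads <- find_triads(inter$rbp_lnc, inter$mi_lnc, inter$mi_rbp)
triad_participation(triads, members)
```

## Known limitations

* Louvain restarts make results reproducible, not optimal; very flat
  modularity landscapes can still change partitions under a different
  seed policy.
* The null-community rule (isolates plus pooled sub-minimum communities)
  is one reasonable formalization of "the algorithm failed to place";
  alternatives (e.g. modularity-contribution thresholds) are not
  implemented.
* Degree is the only centrality computed; betweenness or eigenvector
  rankings may disagree about "top" nodes.
* The miRNA–RBP edge class is stored as unordered co-occurrence; the
  direction of regulation is an interpretation, not a tested property.
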