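Package: lnctriad
Title: Community Segregation and Regulatory Triad Analysis of Dysregulated lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for holistic functional analysis of dysregulated long
    non-coding RNAs (lncRNAs). Builds cross-dataset consensus sets of
    dysregulated genes from differential-expression tables, segregates
    lncRNAs into functionally similar communities from standardized 6-mer
    (SEEKR-style) sequence profiles via Pearson correlation and Louvain
    modularity optimization, constructs disease-restricted and
    comprehensive bipartite lncRNA interaction networks with degree
    rankings, enumerates lncRNA-miRNA-RBP regulatory triads with
    per-community participation statistics, performs subcellular
    localization consensus voting across prediction tools, and computes
    2^-ddCt qPCR fold changes. Includes generators for synthetic inputs
    with planted structure so the whole pipeline can be exercised and
    benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
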