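Package: varnet
Title: Gene Co-Expression Networks from Inter-Individual Expression Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gene co-expression networks from expression variability
    among genetically identical individuals sampled at fixed timepoints,
    without genetic or environmental perturbation. At each timepoint,
    Spearman rank correlations are computed between all gene pairs across
    individuals, significant pairs are selected by Benjamini-Hochberg
    false-discovery-rate control, and edges are retained only when
    significant in a run of consecutive timepoints (a temporal persistence
    filter). A conventional averaged time-course network (Spearman on
    mean-over-individuals profiles with Bonferroni correction) is provided
    for contrast. Downstream tools include Louvain community detection,
    partition robustness comparison, per-module edge-timing distributions,
    night-edge percentages, Fisher gene-set enrichment, module-graph
    assortativity, and a synthetic diurnal transcriptome generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    mclust,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
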