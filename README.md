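# varnet

Gene co-expression networks from **inter-individual expression
variability** — without genetic or environmental perturbation.

## The problem

Standard co-expression networks compare transcriptomes across
perturbations (genotypes, treatments, conditions) and connect genes whose
expression co-varies between them. But genetically identical individuals
grown in one environment still differ in expression, and that variability
carries regulatory signal: if two genes co-vary *across individuals
sampled at the same moment*, they are candidates for common regulation at
that moment. `varnet` implements this inference for diurnal single-individual
designs — the reference layout being single plant seedlings, 14 individuals
per timepoint, 12 timepoints at Zeitgeber times ZT0, 2, ..., 22 across one
24-h light/dark cycle — and contrasts it with the conventional analysis of
the same data.

## The method

**Variability network.** For each timepoint *t* and gene pair (*g*, *h*),
compute Spearman's ρ across the individuals of *t*; select pairs within
each timepoint by Benjamini–Hochberg step-up control at FDR 10%; keep as
edges the pairs significant in at least *k* = 4 consecutive timepoints
allowing ≤ 1 gap inside the run (significance at ZT 8, 10, 14, 16
qualifies; ZT12 is the allowed gap). Each edge records at which timepoints
it was detected, so edge timing (day vs night, transitions) is itself an
observable.

**Averaged time-course network.** Reduce each gene to its
mean-over-individuals 12-point profile, correlate profiles (Spearman), and
keep pairs with *p* ≤ α/m (Bonferroni, α = 0.05, *m* = tested pairs). This
is what pooling individuals would have given.

Downstream: Louvain modularity maximization for modules; per-module
edge-timing distributions and night-edge percentages; Fisher-exact
enrichment against gene sets (highly variable genes, TF target lists, GMT
files); a module meta-graph with attribute assortativity (do night-wired
modules connect to night-wired modules?); and a synthetic diurnal
transcriptome generator with ground truth (latent-factor coupling per
module per timepoint) for end-to-end validation.

## Worked example

```r
library(varnet)
dir <- "demo_run"
res <- run_pipeline(default_config(synthetic = TRUE, seed = 1), dir)
report(dir)
```

```
== variability-network pipeline report ==
variability network : 358 edges, 60 genes
averaged network    : 6793 edges, 324 genes
shared genes/edges  : 43 / 37
modules             : 3 total, 3 with >= min size (modularity 0.6213)
module summary (size / %HVG / %night edges):
  module 0: 20 genes, 100.0% HVG, 0.1% night
  module 1: 20 genes, 0.0% HVG, 100.0% night
  module 2: 20 genes, 0.0% HVG, 48.1% night
```

Reading this: the synthetic study plants three 20-gene modules (one
HVG-tiered, coupled during the day; one coupled at night; one across the
day/night transition) among 400 background genes. The variability route
recovers exactly the 60 planted genes as a 3-module network whose
edge-timing matches the planted coupling windows — module 0's detections
fall in the day (0.1% night), module 1's at night (100%), module 2's
straddle the transition (48.1%). The averaged route, blind to
inter-individual signal, instead links hundreds of background genes whose
*mean* diurnal profiles happen to be similar — the two networks share only
a few dozen genes and edges, which is the methodological point: the two
routes see different biology.

Individual stages are available as plain functions
(`build_variability_network()`, `build_averaged_network()`,
`louvain_partition()`, `module_summary()`, `set_enrichment()`,
`assortativity_pearson()`, `generate_expression()`, ...); see the vignette
`vignettes/variability-networks.Rmd` for the statistical conventions and
the synthetic model.

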