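Package: wormassays
Title: Quantitative Analyses for C. elegans Host-Defence Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the quantitative assays used to dissect
    antimicrobial-peptide gene regulation in Caenorhabditis elegans.  Calls
    specific bait interactors from label-free quantification (LFQ)
    affinity-purification mass-spectrometry tables via replicate filtering,
    down-shifted normal imputation of missing-not-at-random values, pooled
    t statistics and a SAM-style hyperbolic combined significance threshold;
    quantifies candidate-list overlap with the hypergeometric upper tail;
    computes delta-delta-Ct fold induction and ChIP-qPCR percent-input fold
    enrichment from cycling-threshold tables; summarises per-worm sorter
    fluorescence with Kruskal-Wallis and Dunn's post-hoc comparisons; and
    compares censored survival cohorts with Kaplan-Meier estimates and
    one-sided log-rank tests.  Synthetic-data generators with the statistical
    structure of each assay make the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
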