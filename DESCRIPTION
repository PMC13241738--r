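Package: ProteoNT
Title: Integrative Proteome-Neurotransmitter Signaling-Module Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates label-free quantitative proteomics with monoamine
    neurochemistry to discover region-specific neurotransmitter signaling
    modules in mouse brain. Implements per-protein differential abundance
    with a signed ranking statistic, preranked gene-set enrichment with
    permutation-based normalized enrichment scores and FDR q-values,
    direction-aware pathway-activation z-scores, two-way ANOVA with Sidak
    simple-effect contrasts for HPLC-ECD neurotransmitter panels including
    left-censored (below-LOD) handling, and a concordance rule that selects
    signaling modules whose proteomic activation direction agrees with the
    measured neurotransmitter change. A synthetic-data generator with known
    ground truth emulates the factorial study design (WT/TG genotypes, 4
    and 7 months, seven brain regions) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, Metabolomics, GeneSetEnrichment, Pathways, Software
RoxygenNote: 7.3.3
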