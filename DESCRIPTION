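Package: stochbeta
Title: Ecological Drivers of Microbiome Cohorts: Beta-Diversity
    Partitioning, Null-Model Stochasticity and Core Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect the ecological structure of amplicon-derived
    microbiome cohorts. Implements incidence-based multiple-site Sorensen
    dissimilarity partitioned into turnover (Simpson-based) and nestedness
    components, a null-model estimator of community assembly stochasticity
    built on Bray-Curtis similarity with proportional occurrence-frequency
    and richness constraints, prevalence-based core-microbiome sets with
    Venn-region decomposition, a Kruskal-Wallis plus linear-discriminant
    effect-size screen for signature features, and a linear trait-matrix
    projection from taxa to pathway profiles. A synthetic cohort generator
    with tunable assembly (neutral versus environmentally filtered),
    turnover/nestedness structure, planted core taxa and functional
    redundancy makes every stage testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
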