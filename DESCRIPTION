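Package: compherit
Title: Heritability of Microbiome Taxa from Compositional Abundance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how the use of relative (compositional) microbial
    abundance data distorts heritability estimates of microbiome taxa. Provides
    the second-order delta-method approximation of the heritability obtained
    from relative abundances (phi-squared) under a quantitative-genetic model
    of absolute abundances, a multivariate-normal community simulator with
    genetic and environmental correlation structure, variance-component
    estimation with likelihood-ratio testing on host-by-taxon abundance
    tables, Monte-Carlo power and false-discovery experiments, compositional
    normalizations (TSS, ALR, CLR, CSS, log) with recovery experiments, and a
    packaged compilation of published microbiome-heritability studies with
    summary statistics and regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
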