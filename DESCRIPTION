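Package: rilqtl
Title: Constitutive and Water-Deficit-Responsive QTL Mapping in Biparental RIL Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetics pipeline for multi-environment trials of a
    biparental recombinant inbred line (RIL) population evaluated under
    irrigated and non-irrigated scenarios across years. Provides a synthetic
    trial generator (genetic map, selfing-RIL genotypes, augmented-bloc
    phenotypes with planted QTL effects), mixed-model bloc-BLUP correction,
    REML variance components and broad-sense heritability, least-square means,
    percent response and PCA trait descriptives, Van Soest derived traits, and
    a per-marker mixed-model genome scan that classifies QTLs as constitutive
    (marker main effect) or responsive (marker-by-scenario interaction), with
    run-based confidence intervals, r-squared attribution, normalized allele
    effects, and cross-trait cluster detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
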