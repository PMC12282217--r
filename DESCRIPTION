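Package: condaba
Title: Consensus Differential-Abundance Analysis for Metagenomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Consensus-based differential-abundance (DA) analysis for
    shotgun metagenomic taxonomic and pathway profiles. Implements six DA
    engine families (arcsine-square-root and CLR linear models, a
    bias-corrected CLR linear model, an iterative log-linear model with
    sample-specific offsets, Dirichlet Monte-Carlo instances with rank-sum
    tests, a negative-binomial Wald test, and a reference-ratio permutation
    test), majority-vote consensus across engines per taxonomic level,
    proportion versus approximate-count input variants, Aitchison beta
    diversity with PERMANOVA gated by dispersion homogeneity, rarefaction
    based alpha diversity, tool-concordance metrics, depth-confound
    controls, and a synthetic paired-cohort generator with implanted
    ground-truth signals for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
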