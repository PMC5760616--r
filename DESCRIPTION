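Package: murat
Title: Multivariate Rare-Variant Region-Based Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Region-based association tests between sets of rare genetic
    variants and one or several correlated continuous phenotypes. Implements
    the univariate variance-component score test (SKAT) and its multivariate
    extension MURAT, in which variant effects carry a common cross-trait
    correlation (a Kronecker-structured random effect) searched over a grid
    with a min-p omnibus combination. Includes minor-allele-frequency based
    variant weighting, gene-piece / variant-window / single-variant region
    construction, permutation-based estimation of genome-wide significance
    thresholds, a generative simulator for calibration and power studies, and
    a scan pipeline with principal-component adjustment for population
    structure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
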