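Package: camix
Title: Continuous Admixture Dating from Weighted Linkage Disequilibrium Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the timing and mode of two-way population admixture from
    the exponential decay of admixture-induced weighted linkage
    disequilibrium (ALD). Supports one-pulse hybrid isolation (HI), gradual
    admixture (GA), continuous gene flow (CGF) and their isolation-truncated
    extensions (GA-I, CGF-I); fits each model to observed ALD decay curves
    by ordinary least squares over an exponential basis, selects the
    best-fit model by pairwise Wilcoxon signed-rank tests on jackknife
    pseudo log mean squared errors with Holm-Bonferroni correction, and
    reports msE and quasi-F diagnostics. Includes a forward-time
    ancestry-tract simulator with haplotype painting for validation, and
    readers for VCF, EIGENSTRAT-style and plain haplotype panels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'models.R'
    'fit.R'
    'weighted-ld.R'
    'simulator.R'
    'selection.R'
    'study.R'
    'io.R'
    'pipeline.R'
    'camix-package.R'
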