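Package: splitself
Title: Coalescent Demographic Inference for Range-Expansion Speciation
    with Selfing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying parapatric speciation driven by
    post-glacial range expansion and shifts to self-fertilization: a
    structured-coalescent simulator with population splits, migration and
    partial selfing; joint unfolded site-frequency-spectrum (SFS)
    construction with standard variant filters; Monte-Carlo
    composite-likelihood demographic fitting with expectation conditional
    maximization, AIC model comparison, hierarchical scenario selection
    and parametric-bootstrap confidence intervals; Patterson's D with
    block jackknife; inbreeding-coefficient and progeny-array
    outcrossing-rate estimation; individual-level linkage disequilibrium
    by the correlation of zygosity; and mutational-load counting with
    geodesic expansion-distance regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml,
    geosphere
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
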