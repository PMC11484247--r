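Package: panelmr
Title: Two-Sample Mendelian Randomization Across Panels of Outcome Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: genome-wide-significance and instrument-strength filtering,
    greedy linkage-disequilibrium clumping, secondary-phenotype screening,
    allele harmonization with palindromic-SNP removal, inverse-variance
    weighted estimation with Cochran's Q-driven fixed/random model choice,
    MR-Egger regression, the weighted-median estimator with parametric
    bootstrap, and the MR-PRESSO global, outlier and distortion tests.
    A panel driver orchestrates the full chain over many outcome traits,
    and a synthetic summary-statistics generator with known ground truth
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
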