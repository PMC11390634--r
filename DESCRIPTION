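Package: drugtargetmr
Title: Drug-Target Mendelian Randomization Scans from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for drug-target Mendelian randomization (MR)
    from GWAS summary statistics. Builds cis genetic instruments for
    antihypertensive drug classes from systolic blood pressure associations
    (genome-wide significance, +/-100 kb gene windows, LD clumping at
    r-squared < 0.1, proxy lookup at r-squared > 0.80, palindrome exclusion,
    allele harmonization), gates them through a positive-control outcome
    (coronary artery disease), estimates causal odds ratios per 1 mmHg
    decline in systolic blood pressure with Wald-ratio and inverse-variance
    weighted estimators (fixed and multiplicative random effects), and runs
    a full sensitivity battery: Cochran's Q, MR-Egger regression, MR-PRESSO
    global/outlier/distortion tests, Steiger directionality, and
    leave-one-out analysis. A summary-statistic simulator with known ground
    truth (gene windows, LD blocks, palindromic variants, injected
    pleiotropic outliers) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
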