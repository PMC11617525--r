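Package: mrmediate
Title: Two-Sample Mendelian Randomization and Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with
    genome-wide association study (GWAS) summary statistics: instrument
    selection (genome-wide significance, greedy LD clumping,
    outcome-association exclusion, R2/F instrument strength), allele
    harmonization with palindromic-variant handling, the inverse-variance
    weighted, MR-Egger and weighted-median causal estimators, sensitivity
    diagnostics (Cochran's Q, Egger intercept pleiotropy test, leave-one-out,
    MR-PRESSO outlier detection), family-wise multiple-testing adjustment,
    and two-step MR mediation with the product-of-coefficients statistic and
    a delta-method Z test. Includes an end-to-end mediator-screening
    pipeline and a generator of synthetic GWAS summary statistics from an
    explicit exposure-mediator-outcome structural model for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
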