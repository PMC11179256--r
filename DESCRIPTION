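Package: prsblend
Title: Heterogeneity-Aware Blending of GWAS Summary Statistics for Polygenic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Blends two genome-wide association study (GWAS) summary-statistic
    datasets -- a proximal study matching the target trait and population and a
    related adjunct study -- into a complete new set of per-SNP summary
    statistics ready for any downstream polygenic risk score (PRS) tool.
    Heterogeneity of effects is assessed per SNP with a Cochran's Q test
    adjusted for shared controls, converted to local false discovery rates
    (the blending weights) by a two-groups empirical-Bayes estimator, and used
    to interpolate between the proximal estimate and the inverse-variance
    meta-analysis estimate. A matching blended linkage-disequilibrium (LD)
    block reference is derived for LD-aware PRS methods. Includes a paired-GWAS
    simulator (shared/non-shared causal architectures, high-penetrance
    variants, shared control pools, block-structured genotypes) and PRS
    scoring/evaluation utilities for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
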