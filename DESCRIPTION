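Package: triomr
Title: Within-Family Mendelian Randomization for Parent-Offspring Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating effects of parental exposures (such as
    educational attainment) on child outcomes in genotyped mother-father-child
    trios. Implements polygenic-index construction from GWAS summary
    statistics with allele harmonization and greedy LD clumping, multiple
    imputation by chained equations with predictive-mean-matching and
    Rubin's-rules pooling, one-sample Mendelian randomization by two-stage
    least squares with cluster-robust inference and instrument-strength
    diagnostics (including the within-family variant that conditions on the
    child's own polygenic index), and summary-data MR estimators (IVW,
    MR-Egger, weighted median, mode-based) on mutually adjusted per-variant
    associations. Ships a synthetic trio-cohort generator with Mendelian
    transmission, tunable linkage disequilibrium, assortative mating, family
    confounding, genetic nurture and direct genetic effects, so the whole
    pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
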