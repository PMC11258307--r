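# triomr

Within-family Mendelian randomization for genotyped mother–father–child
trios: does parental educational attainment causally affect children's
depressive, anxiety and ADHD traits, or do the familiar observational
associations reflect confounding and direct genetic transmission?

`triomr` is aimed at genetic epidemiologists and biostatisticians working
with trio cohorts (or planning analyses of them). It implements the full
analysis ladder from GWAS summary statistics to pooled causal estimates,
together with a synthetic trio-cohort generator with known causal structure
so that every stage can be validated against planted truth — important
because the real cohorts this design needs are access-restricted.

## The design

An ordinary regression of a child outcome on parental education is
confounded by everything families share. Instrumenting each parent's years
of education $E_m, E_f$ with their own education polygenic index (PGI)
$G_m, G_f$ removes environmental confounding, but parents transmit half
their alleles to the child, so the instrument is correlated with the
child's own genetic liability — a violation of the exclusion restriction.
The within-family model adds the child's PGI $G_c$ as a covariate, which
blocks the transmission path and isolates *genetic nurture* (effects of
parental education on the child's environment) from *direct genetic
effects*:

$$Y = \beta_m E_m + \beta_f E_f + \eta\, G_c + X'\delta + \varepsilon,
\qquad E_m, E_f \text{ instrumented by } G_m, G_f .$$

Estimation is two-stage least squares with cluster-robust (genetic family
ID) standard errors; $X$ holds child sex, birth year, genotyping batch and
60 ancestry PCs. Without the $G_c$ adjustment, the naive MR estimate of
$\beta$ has probability limit $\beta + \eta_{\mathrm{raw}}/(2\gamma)$, where
$\gamma$ is the effect of the raw PGI on education — the package
demonstrates this bias law by simulation and its removal by conditioning.

What the package covers:

* **simulate** — trio cohorts with Mendelian transmission, block-LD
  haplotypes, assortative mating by rank-matched education, a shared family
  confounder, genetic nurture ($\beta_m,\beta_f$), direct effects ($\eta$),
  per-variant pleiotropy, bounded questionnaire outcomes, and MCAR/MAR
  outcome missingness.
* **pgi** — allele harmonization, greedy LD clumping ($p < 5\times10^{-8}$,
  $r^2 = 0.01$, 10,000 kb window; strict $r^2 = 0.001$ subset), weighted
  scoring, within-role standardization.
* **impute** — chained-equation multiple imputation with type-1 predictive
  mean matching (knn 10), passive ADHD totals, prorated questionnaire
  scores, and Rubin pooling with Barnard–Rubin degrees of freedom.
* **onesample** — the four model specifications (minimally adjusted OLS,
  confounder-adjusted OLS, MR, within-family MR), cluster-robust sandwich
  variances, first-stage and conditional F, partial $R^2$.
* **twosample** — per-variant child-outcome associations mutually adjusted
  for mother, father and child genotype, and IVW, MR-Egger, weighted-median
  and mode-based summary estimators with heterogeneity diagnostics.
* **pipeline** — `run_analysis()` orchestrates all stages reproducibly;
  `run_simulation_study()` drives scenario grids with bias and coverage
  summaries.

## Worked example

Simulate 5,000 trios with a small maternal nurture effect
(−0.02 outcome SD per year of education) and a protective direct genetic
effect (−0.06 SD per PGI SD), build the PGI from simulated GWAS summary
statistics, and fit the within-family model:

```r
library(triomr)

cfg <- sim_config(n_families = 5000, n_snps = 100, seed = 42,
                  beta_mother = -0.02, eta = -0.06,
                  ld_adjacent_corr = 0, discretize = FALSE,
                  missing_rate_outcome = 0)
cohort <- simulate_trio_cohort(cfg)

sumstats <- simulate_gwas_sumstats(cohort$panel, cfg, gamma = cohort$truth$gamma)
harm     <- harmonize_alleles(sumstats, cohort$panel)
ld       <- ld_from_dosages(rbind(cohort$dosages$mother, cohort$dosages$father))
clump    <- clump_variants(harm$sumstats, ld)
scores   <- score_cohort(cohort, harm$sumstats, clump$retained)

pheno <- cohort$phenotypes
pheno$smfq <- cohort$truth$latent_outcomes[, "smfq"]
run_spec(pheno, scores, spec = "wfmr", outcome = "smfq")
```

```
2SLS (cluster-robust) fit: n = 5000, clusters = 5000
            term  estimate       se     ci_low  ci_high         p
      edu_mother -0.035738 0.075298  -0.183320  0.11184 6.351e-01
      edu_father -0.015740 0.070702  -0.154313  0.12283 8.238e-01
     (Intercept) -5.619426 9.818406 -24.863149 13.62430 5.671e-01
       pgi_child -0.023436 0.021866  -0.066292  0.01942 2.838e-01
  ... and 65 more covariate terms
Instrument diagnostics:
       term     F F_conditional partial_r2
 edu_mother 21.22         23.78   0.008302
 edu_father 24.22         25.55   0.009705
```

Estimates are in outcome SD units per year of parental education (the
`pgi_child` term is per PGI SD). The planted truths on that scale are
−0.0196 (maternal effect) and −0.0587 (direct effect); both 95% intervals
cover them, and at this deliberately modest sample size the intervals are
wide — the same qualitative picture the design produces on real cohorts of
tens of thousands of trios, where first-stage F statistics run into the
hundreds. A cohort with missing outcomes goes through
`chained_impute()`/`pool_rubin()` instead of a single `run_spec()` call, or
simply through `run_analysis(run_config(...))`, which wires every stage
together.

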