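---
title: "Within-family Mendelian randomization in trios: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-family Mendelian randomization in trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomr)
```

## The estimation problem

Children of more educated parents tend to report fewer emotional and
behavioural difficulties, but that association mixes at least four causal
structures: a genuine effect of the rearing environment parents with more
education provide (*genetic nurture* when indexed through parental
genotype), direct transmission of education-associated alleles that also
influence the child's traits, environmental confounding shared within
families, and assortative mating, which correlates the two parental
genomes. `triomr` implements the trio design that separates these: each
parent's years of education is instrumented by that parent's own polygenic
index (PGI) for education, and the child's own PGI is conditioned on.

The structural model for a standardized child outcome $Y$ is

$$Y = \beta_m E_m + \beta_f E_f + \eta G_c + X'\delta + \varepsilon,$$

with $E_m, E_f$ parental years of education, $G_c$ the child's standardized
PGI, and $X$ the exogenous covariates (child sex, birth year, genotyping
batch dummies, 20 ancestry principal components for each trio member).
Two-stage least squares with instruments $(G_m, G_f)$ identifies
$(\beta_m, \beta_f)$ under the usual IV assumptions; conditioning on $G_c$
is what makes the exclusion restriction defensible, because an untransmitted
parental allele cannot affect the child through the child's genome.

Four specifications form the reporting ladder (`run_spec()`): minimally
adjusted OLS of the outcome on both parents' education; OLS additionally
adjusted for measured confounders (parental depressive/anxiety and ADHD
trait scores, parental smoking, parity); MR without the child-PGI
adjustment; and within-family MR with it. Comparing the third and fourth
isolates the transmission path empirically.

### The transmission bias law

Under random mating, no pleiotropy and no confounder–instrument
correlation, the naive MR estimate (no child-PGI adjustment) has
probability limit

$$\mathrm{plim}\;\hat\beta_p = \beta_p + \frac{\eta_{\mathrm{raw}}}{2\gamma},
\qquad p \in \{m, f\},$$

where $\eta_{\mathrm{raw}}$ is the direct effect per raw PGI unit and
$\gamma$ the effect of the raw PGI on years of education. The factor 2
comes from each parent transmitting half their alleles:
$\mathrm{cov}(G_p, G_c) = \tfrac12\mathrm{var}(G_p)$. The acceptance suite
verifies this closed form by simulation at $n = 100{,}000$ and verifies
that the within-family specification removes it. Because the check runs as
a single replicate, the simulation plants a large direct effect
($\eta = 0.3$ SD per PGI SD) so the predicted bias (about 0.5 SD) is
dozens of Monte-Carlo standard errors wide of zero and the 10% relative
comparison is well powered.

## Inference

All variances are clustered sandwich estimators with the finite-sample
factor $\frac{G}{G-1}\cdot\frac{N-1}{N-k}$; with every observation its own
cluster this reproduces HC1, which the tests exploit as an oracle identity
against the `sandwich` package. For 2SLS the sandwich is evaluated with
*structural* residuals $y - X\hat\beta$ (not second-stage residuals), the
variance that is consistent for IV; a brute-force dense-algebra
implementation in the test helpers checks both coefficients and the full
covariance to $10^{-10}$. Confidence intervals use normal critical values,
matching the large-sample setting the design targets; pooled fits use $t$
intervals on Barnard–Rubin degrees of freedom.

Instrument strength is reported three ways (`first_stage_diagnostics()`):
the classical excluded-instrument F from each exposure's first stage,
computed from the $R^2$ increment formula; a Sanderson–Windmeijer-style
conditional F that first partials the other endogenous regressor out by
IV and rescales by $q/(q - m + 1)$; and the partial $R^2$ of the
exposure's own instrument given the covariates, defined as the squared
partial correlation $(R^2_{\mathrm{own}} - R^2_{\mathrm{red}})/(1 -
R^2_{\mathrm{red}})$. Which of the first two a given software package
prints is rarely stated, so both are always reported.

## The synthetic cohort generator

The generator (`simulate_trio_cohort()`) is a first-class, tested module,
not a fixture. Its causal graph contains exactly the paths the design is
about: parental genotype → parental education (strength $\gamma$),
parental education → child outcome ($\beta_m, \beta_f$), child genotype →
outcome ($\eta$, plus optional per-variant pleiotropy), a family-level
standard-normal confounder $C$ loading on both education and outcome, and
phenotypic assortative mating.

Defaults describe the study regime the package targets: 20,000 trios and
200 variants (a desk-scale profile; `run_config(full_scale = TRUE)`
switches to 40,879 trios, 1,729 variants and 50 imputations), a PGI
calibrated to explain 1.4% of education variance, education means/SDs of
about 15.4/2.3 (mothers) and 14.8/2.6 (fathers) years, questionnaire
outcomes bounded on their published ranges (0–26 depressive, 0–10 anxiety,
0–27 per ADHD subscale with the 0–54 total formed passively), a small male
excess in difficulties, and 54% outcome missingness. Unless a fixed
`gamma` is supplied, $\gamma$ is calibrated on the realized parental raw
scores so that $\gamma^2\mathrm{var}(G_{\mathrm{raw}})$ is 1.4% of total
education variance — matching the instrument-strength regime in which
first-stage F statistics at $n \approx 40{,}000$ run into the hundreds.

Specific constructions, and why:

* **Haplotypes and LD.** Each haplotype is a within-block Markov chain:
  an allele is copied from the previous in-block locus with probability
  `ld_adjacent_corr`, else drawn fresh from the locus frequency. This
  gives tunable $r^2$ decay, exact haplotypes for Mendelian transmission
  (one uniformly chosen allele per parent per locus, independent across
  loci), and trivial vectorized code. No recombination maps or demography
  are attempted.
* **Assortative mating.** Couples are rank-matched on the pre-confounder
  education signal plus matching noise. The noise SD starts from the
  analytic value $\tau^2 = v_0(1-\rho_0)/\rho_0$ and is refined by a few
  secant steps against the realized spousal correlation, which includes
  the shared-confounder contribution (the family confounder is assigned
  per couple, after matching, since it is a family-level quantity). With
  `am_rho = 0` pairing is random.
* **Outcomes.** A single latent structural equation per outcome, with
  independent noise per scale; reported scores are optionally discretized
  by rounding and clipping onto the questionnaire range. Discretization is
  off in estimator-recovery tests so planted coefficients stay exact, and
  on by default because bounded integer scores are what real
  questionnaires deliver. The latent construction is an artifact choice —
  nothing in the target literature specifies a generating distribution for
  these scores.
* **Measured confounders.** Parental trait scores, smoking (3-level) and
  parity (5-level) are thresholded/discretized latent normals loading
  positively on $C$, so "adjusting for likely confounders" has something
  real to remove. Ancestry PCs and batch labels are pure noise covariates:
  the generator plants no population structure, so they only exercise the
  covariate plumbing (and the collinearity drop-and-warn path).
* **Missingness.** MCAR, or MAR with missingness probability logistic in
  mid-parental education with a calibrated intercept that hits the target
  marginal rate. Genotypes are never made missing, matching the design's
  complete-genetic-data sampling frame.
* **Simulated GWAS.** Published effects are the true per-allele effects on
  years of education ($\gamma w_j$) plus noise with
  $se_j = \sigma/\sqrt{2f_j(1-f_j)N}$; the noiseless flag gives the
  infinite-discovery-sample limit used when a test needs the scored PGI to
  equal the true genetic value. The summary-level generator
  `simulate_snp_assocs()` additionally orients effects to the
  exposure-increasing allele (half-normal) because that is the orientation
  on which *directional* pleiotropy is defined; with symmetric effects a
  planted mean pleiotropy would cancel out of the Egger intercept by
  construction.

What passing tests on this generator do **not** show about real data:
there is no population stratification, no genotyping error, no item-level
questionnaire structure, no dynastic effects beyond the education path,
and LD is block-wise artificial. The generator demonstrates estimator
correctness under the stated causal model, not robustness to every
violation real cohorts can present.

## Polygenic index construction

Harmonization drops variants absent from the genotype panel, flips signs
where the coded allele is the published other allele, resolves strand
flips via complements, and drops strand-ambiguous (A/T, C/G) variants with
effect-allele frequency in [0.4, 0.6]; irreconcilable allele pairs are
logged, never fatal. Clumping is greedy: the smallest-p unclaimed variant
below $5\times10^{-8}$ (strict `<`) becomes an index and claims all
unclaimed same-chromosome variants within a symmetric, boundary-inclusive
10,000 kb window with $r^2 \ge 0.01$ (0.001 for the strict subset used by
the summary-data estimators). Ties on p break by (chromosome, position)
ascending — a declared convention, since published clumping
implementations rarely document theirs. Missing LD entries default to
$r^2 = 0$ with a warning (configurable to error), a permissive choice for
sparse references that is logged for audit. Raw scores are
$\sum_j \hat\beta_j d_{ij}$; standardization is within role
(mother/father/child separately), because effect sizes are interpreted per
within-role SD.

## Multiple imputation

`chained_impute()` visits variables in increasing-missingness order,
imputing each by type-1 predictive mean matching: a linear model on the
current completed predictors, a posterior draw of $(\sigma^2, \beta)$
(scaled inverse-$\chi^2$, then normal), predictions for observed rows from
$\hat\beta$ and for missing rows from the draw, and a uniformly chosen
donor among the `knn = 10` observed rows with nearest predictions. Donor
copying guarantees imputed values live on the observed support — bounded
questionnaire scores stay bounded with no extra machinery. Ordinal
covariates go through the same PMM path on their integer codes rather than
an ordered-logistic model; this preserves the observed support and avoids
a proportional-odds fitter at the cost of ignoring the latent-scale
likelihood, a documented divergence from analyses that impute such
variables by ordered logit. ADHD subscales are imputed and the total formed
passively afterwards; passive totals never serve as predictors. Ten cycles
is the default sweep count and five datasets the desk default (`m = 50`
at full scale); neither value has a stated counterpart in the target
analyses, so common chained-equation defaults are used.

Pooling follows Rubin's rules with the Barnard–Rubin small-sample degrees
of freedom (reducing to the classical value as the complete-data df grows).
Type-1 PMM is known to understate between-imputation variance slightly in
strongly linear problems; the acceptance suite measures exactly this
(pooled-CI coverage of a planted slope across 100 seeded replicates) rather
than asserting more than the algorithm delivers.

The MAR acceptance property deserves a note. When outcome missingness
depends only on parental education and education is in the analysis model,
complete-case regression is unbiased for the slope — imputation cannot
"beat" it there. Selection on education distorts estimands that do *not*
condition on education, the outcome mean being the cleanest; that is the
estimand the MAR check uses, with education and an auxiliary in the
imputation model and the full-data sample mean as per-replicate truth.

## Summary-data estimators

Per-variant outcome associations come from one linear model per variant:
outcome on mother, father and child dosage plus the standard covariates —
the mutual adjustment that makes these within-family summary statistics.
The covariates are residualized out once (Frisch–Waugh), so each variant
costs a $3\times3$ solve; coefficients are exactly those of the full
regression (the oracle tests check this against dense normal-equations
solves), and the clustered sandwich is evaluated in the residualized frame
with the full-model df correction, an equivalence that is exact for the
coefficients and asymptotically standard for the variances.

IVW is the origin-constrained WLS slope with weights $1/se_{y_j}^2$, with
a multiplicative random-effects SE scaled by $\max(1, \sqrt{Q/(J-1)})$;
MR-Egger adds the intercept after orienting exposure effects non-negative
(with `intercept = FALSE` it reproduces IVW exactly, which is tested by
refit). The weighted median interpolates the weighted ratio CDF at one
half with delta-method ratio weights $b_{x_j}^2/se_{y_j}^2$; the
mode-based estimator maximizes a weighted Gaussian kernel density over the
Wald ratios with Silverman bandwidth times `phi` (default 1) on a 512-point
grid spanning the ratio mean ±5 SD, polished by golden-section search
within one grid step; degenerate spreads (single variant, identical
ratios) return the ratio directly. Median and mode SEs come from a
parametric bootstrap of both effect columns under a caller-supplied seed,
so they are bit-reproducible. Exposure effects stay on the GWAS reporting
scale; because the simulated GWAS reports years-of-education units, the
suite's estimates are directly comparable to the 2SLS education effects,
and a consistency test confirms IVW and within-family 2SLS agree on a
clean cohort.

## Pipeline, problem sizes, and determinism

`run_analysis()` chains the stages under one seed and records a manifest
(config hash, seed, record counts for every filtering step) sufficient to
regenerate every number; the determinism contract — identical results
tables from identical configs — is tested byte-for-byte. The test and
acceptance workloads use deliberately scaled problem sizes chosen as the
smallest that leave the checked properties comfortably identified: the
bias law at $n = 100{,}000 \times 50$ variants (single replicate),
coverage at 500 replicates of $5{,}000 \times 100$, instrument calibration
at $40{,}000 \times 200$, pleiotropy properties at the summary level with
200 variants × 100 replicates, and imputation properties at
$n = 2{,}000$–$5{,}000$ × 100 seeds.

## Known limitations

Inference offers no weak-instrument-robust intervals (Anderson–Rubin) and
no LIML/GMM alternatives; imputation has no multilevel or ordered-logistic
models; the two-sample module implements no outlier-removal (MR-PRESSO),
multivariable MR or Steiger filtering; the generator's LD and ancestry
structure are intentionally artificial. The education-category-to-years
table shipped in `inst/extdata/education_years.tsv` is a synthetic
ISCED-style placeholder for `map_education()` and should be replaced by a
study's own mapping.
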