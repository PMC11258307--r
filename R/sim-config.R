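#' Simulation configuration for a synthetic trio cohort
#'
#' Collects every knob of the trio-cohort generator: panel size and allele
#' frequencies, linkage disequilibrium, instrument strength (either a fixed
#' `gamma` or a target share of education variance explained by the polygenic
#' index), genetic-nurture and direct genetic effects, family-level
#' confounding, assortative mating, per-variant horizontal pleiotropy,
#' outcome missingness, and the bounded questionnaire scales the reported
#' outcomes are mapped onto.
#'
#' The default values describe the study regime the package targets: a
#' cohort of 20,000 trios scored on a 200-variant panel whose polygenic index
#' explains about 1.4\% of the variance in parental years of education,
#' child outcomes on bounded questionnaire ranges with roughly 54\% of child
#' outcome values missing, and a small protective direct genetic effect.
#'
#' @param n_families number of mother-father-child trios.
#' @param n_snps number of variants on the panel.
#' @param allele_freq_range length-2 vector, lower/upper bound of the uniform
#'   distribution allele frequencies are drawn from (degenerate width-0 range
#'   allowed; inverted range rejected).
#' @param ld_block_size number of adjacent variants per LD block; blocks are
#'   mutually independent.
#' @param ld_adjacent_corr probability that a haplotype allele is copied from
#'   the previous in-block locus rather than drawn fresh; 0 gives independent
#'   loci.
#' @param gamma effect of the raw polygenic index on years of education
#'   (years per raw-score unit). `NULL` (the default) calibrates gamma
#'   empirically so the raw index explains `pgi_r2` of education variance.
#' @param pgi_r2 target share of education variance explained by the index
#'   when `gamma` is calibrated; default 0.014.
#' @param beta_mother,beta_father genetic-nurture effects: change in the
#'   latent child outcome (outcome SD units) per year of parental education.
#' @param eta direct genetic effect: latent outcome change per SD of the
#'   child's standardized polygenic index.
#' @param conf_edu,conf_outcome loadings of the shared standard-normal
#'   family confounder on parental education (years per SD) and on the
#'   latent child outcome (SD per SD).
#' @param am_rho target spousal correlation of years of education, in
#'   `[0, 1)`; 0 means random mating.
#' @param pleiotropy_mean,pleiotropy_sd per-variant direct effects of the
#'   child's allele count on the latent outcome, drawn once per cohort from
#'   `N(pleiotropy_mean, pleiotropy_sd^2)`.
#' @param missing_rate_outcome marginal missingness proportion for each child
#'   outcome score.
#' @param missing_mechanism `"MCAR"` or `"MAR-on-education"`.
#' @param mar_edu_coef log-odds change in outcome missingness per year of
#'   mid-parental education under the MAR mechanism (the intercept is
#'   calibrated to hit `missing_rate_outcome` marginally).
#' @param discovery_n effective sample size of the simulated discovery GWAS
#'   (drives the standard errors of published variant effects).
#' @param outcome_ranges named list of `c(min, max)` questionnaire bounds for
#'   each simulated outcome.
#' @param outcome_scale named list of `c(mean, sd)` used to place the latent
#'   outcome on each questionnaire scale when discretizing.
#' @param discretize logical; if `TRUE` reported outcomes are rounded and
#'   clipped to `outcome_ranges`, if `FALSE` the latent continuous outcome is
#'   reported (used for estimator-recovery work where the planted
#'   coefficients must stay exact).
#' @param edu_intercept named vector `c(mother=, father=)` of mean years of
#'   education.
#' @param edu_noise_sd SD of the idiosyncratic education noise (years).
#' @param sex_effect latent-outcome shift for male children (SD units).
#' @param outcome_noise_sd SD of the latent outcome noise.
#' @param weight_sd SD of the zero-mean normal the true per-allele variant
#'   weights are drawn from.
#' @param smoking_thresholds,parity_thresholds cut points on the latent
#'   normal scales behind the ordinal smoking (3-level) and parity (5-level)
#'   covariates.
#' @param seed integer seed; a fixed seed makes the whole cohort
#'   bit-identical across calls.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_trio_cohort()]
#' @export
sim_config <- function(n_families = 20000L,
                       n_snps = 200L,
                       allele_freq_range = c(0.1, 0.9),
                       ld_block_size = 5L,
                       ld_adjacent_corr = 0.8,
                       gamma = NULL,
                       pgi_r2 = 0.014,
                       beta_mother = 0,
                       beta_father = 0,
                       eta = -0.04,
                       conf_edu = 0.5,
                       conf_outcome = 0.2,
                       am_rho = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       missing_rate_outcome = 0.54,
                       missing_mechanism = c("MCAR", "MAR-on-education"),
                       mar_edu_coef = -0.3,
                       discovery_n = 750000,
                       outcome_ranges = list(smfq = c(0, 26), scared = c(0, 10),
                                             adhd_inatt = c(0, 27), adhd_hyper = c(0, 27)),
                       outcome_scale = list(smfq = c(1.9, 2.5), scared = c(1.0, 1.2),
                                            adhd_inatt = c(5.0, 4.1), adhd_hyper = c(3.6, 3.9)),
                       discretize = TRUE,
                       edu_intercept = c(mother = 15.4, father = 14.8),
                       edu_noise_sd = 2.4,
                       sex_effect = 0.1,
                       outcome_noise_sd = 1,
                       weight_sd = 0.01,
                       smoking_thresholds = c(0.0, 1.2),
                       parity_thresholds = c(-0.1, 0.9, 1.6, 2.5),
                       seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(n_families = as.integer(n_families), n_snps = as.integer(n_snps),
              allele_freq_range = allele_freq_range,
              ld_block_size = as.integer(ld_block_size),
              ld_adjacent_corr = ld_adjacent_corr,
              gamma = gamma, pgi_r2 = pgi_r2,
              beta_mother = beta_mother, beta_father = beta_father, eta = eta,
              conf_edu = conf_edu, conf_outcome = conf_outcome, am_rho = am_rho,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              missing_rate_outcome = missing_rate_outcome,
              missing_mechanism = missing_mechanism, mar_edu_coef = mar_edu_coef,
              discovery_n = discovery_n,
              outcome_ranges = outcome_ranges, outcome_scale = outcome_scale,
              discretize = isTRUE(discretize),
              edu_intercept = edu_intercept, edu_noise_sd = edu_noise_sd,
              sex_effect = sex_effect, outcome_noise_sd = outcome_noise_sd,
              weight_sd = weight_sd,
              smoking_thresholds = smoking_thresholds,
              parity_thresholds = parity_thresholds,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_families < 1L) stop("n_families must be >= 1")
  if (cfg$n_snps < 1L) stop("n_snps must be >= 1")
  fr <- cfg$allele_freq_range
  if (length(fr) != 2L || any(!is.finite(fr))) stop("allele_freq_range must be two finite numbers")
  if (fr[1] > fr[2]) stop("inverted allele_freq_range")
  if (fr[1] <= 0 || fr[2] >= 1) stop("allele_freq_range must lie strictly inside (0, 1)")
  for (nm in c("ld_adjacent_corr", "missing_rate_outcome", "pgi_r2")) {
    v <- cfg[[nm]]
    if (v < 0 || v > 1) stop(sprintf("%s must be a probability in [0, 1]", nm))
  }
  if (cfg$am_rho < 0 || cfg$am_rho >= 1) stop("am_rho must lie in [0, 1)")
  if (cfg$ld_block_size < 1L) stop("ld_block_size must be >= 1")
  if (cfg$discovery_n <= 0) stop("discovery_n must be positive")
  if (cfg$pleiotropy_sd < 0) stop("pleiotropy_sd must be non-negative")
  if (!is.list(cfg$outcome_ranges) || is.null(names(cfg$outcome_ranges)))
    stop("outcome_ranges must be a named list of c(min, max)")
  for (nm in names(cfg$outcome_ranges)) {
    r <- cfg$outcome_ranges[[nm]]
    if (length(r) != 2L || r[1] >= r[2])
      stop(sprintf("outcome range for '%s' must satisfy min < max", nm))
    if (is.null(cfg$outcome_scale[[nm]]))
      stop(sprintf("no outcome_scale entry for outcome '%s'", nm))
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Trio cohort simulation configuration\n")
  cat(sprintf("  families: %d, variants: %d (blocks of %d, within-block copy prob %.2f)\n",
              x$n_families, x$n_snps, x$ld_block_size, x$ld_adjacent_corr))
  g <- if (is.null(x$gamma)) sprintf("calibrated to R2 = %.3f", x$pgi_r2)
       else sprintf("%.4f years per raw-score unit", x$gamma)
  cat(sprintf("  instrument strength: gamma %s\n", g))
  cat(sprintf("  nurture beta (m/f): %.3f / %.3f, direct eta: %.3f\n",
              x$beta_mother, x$beta_father, x$eta))
  cat(sprintf("  confounder loadings (edu/outcome): %.2f / %.2f, spousal rho: %.2f\n",
              x$conf_edu, x$conf_outcome, x$am_rho))
  cat(sprintf("  outcomes: %s (%s)\n", paste(names(x$outcome_ranges), collapse = ", "),
              if (x$discretize) "discretized" else "latent"))
  cat(sprintf("  missingness: %.0f%% %s\n", 100 * x$missing_rate_outcome, x$missing_mechanism))
  invisible(x)
}

# Override selected fields of a sim_config (used by scenario grids).
modify_sim_config <- function(cfg, overrides) {
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) stop(sprintf("unknown sim_config field '%s'", nm))
    cfg[[nm]] <- overrides[[nm]]
  }
  validate_sim_config(cfg)
}
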