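mr_result <- function(estimator, estimate, se, se_fixed = se, ci = NULL,
                      Q = NA_real_, n_snps, extra = list()) {
  if (is.null(ci)) ci <- estimate + c(-1, 1) * 1.96 * se
  structure(c(list(estimator = estimator, estimate = estimate, se = se,
                   se_fixed = se_fixed, ci_low = ci[1], ci_high = ci[2],
                   p = if (is.finite(se) && se > 0)
                     2 * stats::pnorm(-abs(estimate / se)) else NA_real_,
                   Q = Q, n_snps = n_snps), extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s: %.*f (SE %.*f, 95%% CI %.*f to %.*f), %d variants\n",
              x$estimator, digits, x$estimate, digits, x$se,
              digits, x$ci_low, digits, x$ci_high, x$n_snps))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept: %.*f (SE %.*f, p = %.3g)\n", digits, x$intercept,
                digits, x$intercept_se, x$intercept_p))
  if (is.finite(x$Q)) cat(sprintf("  Cochran's Q = %.2f on %d df\n", x$Q,
                                  x$n_snps - if (identical(x$estimator, "egger")) 2L else 1L))
  invisible(x)
}

#' Inverse-variance weighted estimator
#'
#' Weighted least-squares slope of the variant-outcome effects on the
#' variant-exposure effects through the origin, with weights
#' `1/se_outcome^2`. The fixed-effect SE comes from the weighted LS
#' information; the (multiplicative) random-effects SE scales it by
#' `max(1, sqrt(Q/(J-1)))`. With a single variant this reduces exactly to
#' the Wald ratio.
#'
#' @param beta_exp,beta_out per-variant exposure and outcome effects.
#' @param se_out per-variant SE of the outcome effect.
#' @return an `mr_estimate`.
#' @export
mr_ivw <- function(beta_exp, beta_out, se_out) {
  stopifnot(length(beta_exp) >= 1, all(se_out > 0))
  w <- 1 / se_out^2
  est <- sum(w * beta_exp * beta_out) / sum(w * beta_exp^2)
  se_fixed <- sqrt(1 / sum(w * beta_exp^2))
  J <- length(beta_exp)
  Q <- sum(w * (beta_out - est * beta_exp)^2)
  se <- if (J > 1) se_fixed * max(1, sqrt(Q / (J - 1))) else se_fixed
  mr_result("ivw", est, se, se_fixed, ci = est + c(-1, 1) * 1.96 * se,
            Q = Q, n_snps = J)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects *with* an
#' intercept, weights `1/se_outcome^2`, after orienting every variant so its
#' exposure effect is non-negative (flipping the outcome effect in tandem).
#' A non-null intercept indicates directional horizontal pleiotropy; under
#' the InSIDE assumption the slope remains a consistent effect estimate.
#' With `intercept = FALSE` the fit is constrained through the origin and
#' reproduces [mr_ivw()] exactly.
#'
#' @inheritParams mr_ivw
#' @param intercept include the pleiotropy intercept (default `TRUE`).
#' @param min_snps minimum number of variants (default 3: slope, intercept
#'   and at least one residual df); lower it only for degenerate exact-fit
#'   fixtures.
#' @return an `mr_estimate` with `intercept`, `intercept_se`, `intercept_p`
#'   fields.
#' @export
mr_egger <- function(beta_exp, beta_out, se_out, intercept = TRUE,
                     min_snps = 3L) {
  J <- length(beta_exp)
  if (intercept && J < min_snps)
    stop(sprintf("MR-Egger needs at least %d variants", min_snps))
  flip <- sign(beta_exp); flip[flip == 0] <- 1
  bx <- beta_exp * flip; by <- beta_out * flip
  w <- 1 / se_out^2
  if (!intercept) return(mr_ivw(beta_exp, beta_out, se_out))
  X <- cbind(1, bx)
  A <- solve(crossprod(X * sqrt(w)))
  beta <- unname(drop(A %*% crossprod(X * w, by)))
  res <- by - drop(X %*% beta)
  Q <- sum(w * res^2)
  disp <- if (J > 2) max(1, Q / (J - 2)) else 1
  se_fixed <- sqrt(diag(A))
  se <- se_fixed * sqrt(disp)
  mr_result("egger", beta[2], se[2], se_fixed[2],
            ci = beta[2] + c(-1, 1) * 1.96 * se[2], Q = Q, n_snps = J,
            extra = list(intercept = beta[1], intercept_se = se[1],
                         intercept_p = 2 * stats::pnorm(-abs(beta[1] / se[1]))))
}

# Weighted median by cumulative-probability interpolation: order the Wald
# ratios, let S_j be the cumulative normalized weights and p_j = S_j - s_j/2,
# then interpolate linearly at p = 0.5.
weighted_median_interp <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  s <- w[ord] / sum(w)
  p <- cumsum(s) - s / 2
  J <- length(r)
  if (J == 1L || 0.5 <= p[1]) return(r[1])
  if (0.5 >= p[J]) return(r[J])
  i <- max(which(p <= 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
}

#' Weighted median estimator
#'
#' Inverse-variance weighted median of the per-variant Wald ratios
#' `beta_out/beta_exp`, with delta-method ratio weights
#' `beta_exp^2/se_out^2` and linear interpolation of the weighted empirical
#' CDF at probability one half. Consistent when variants carrying at least
#' half the weight are valid instruments. The SE comes from a parametric
#' bootstrap that redraws both effect columns from their sampling
#' distributions.
#'
#' @inheritParams mr_ivw
#' @param se_exp per-variant SE of the exposure effect (0 if omitted).
#' @param n_boot bootstrap draws for the SE (default 1000; 0 skips the
#'   bootstrap and reports `NA` SE).
#' @param seed optional seed so bootstrap SEs are reproducible.
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(beta_exp, beta_out, se_out, se_exp = NULL,
                               n_boot = 1000L, seed = NULL) {
  stopifnot(length(beta_exp) >= 1)
  if (is.null(se_exp)) se_exp <- rep(0, length(beta_exp))
  w <- beta_exp^2 / se_out^2
  est <- weighted_median_interp(beta_out / beta_exp, w)
  se <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    J <- length(beta_exp)
    boots <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, beta_exp, se_exp)
      by <- stats::rnorm(J, beta_out, se_out)
      weighted_median_interp(by / bx, bx^2 / se_out^2)
    }, numeric(1))
    se <- stats::sd(boots)
  }
  mr_result("weighted_median", est, se, n_snps = length(beta_exp))
}

#' Mode-based estimator
#'
#' Weighted Gaussian kernel density over the per-variant Wald ratios, with
#' Silverman's rule-of-thumb bandwidth scaled by `phi`; the estimate is the
#' density argmax on a 512-point grid spanning the ratio mean plus/minus 5
#' SD. Consistent when the largest group of variants sharing a ratio value
#' are valid instruments (zero modal pleiotropy). SE by parametric
#' bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param phi bandwidth multiplier (default 1).
#' @return an `mr_estimate`.
#' @export
mr_mode <- function(beta_exp, beta_out, se_out, se_exp = NULL, phi = 1,
                    n_boot = 1000L, seed = NULL) {
  stopifnot(length(beta_exp) >= 1, phi > 0)
  if (is.null(se_exp)) se_exp <- rep(0, length(beta_exp))
  point <- function(bx, by) {
    ratio <- by / bx
    w <- bx^2 / se_out^2
    J <- length(ratio)
    s <- stats::sd(ratio)
    if (J == 1L || !is.finite(s) || s == 0) return(ratio[1])
    h0 <- 0.9 * min(s, stats::IQR(ratio) / 1.34) * J^(-1 / 5)
    if (h0 <= 0) h0 <- 0.9 * s * J^(-1 / 5)
    h <- phi * h0
    grid <- seq(mean(ratio) - 5 * s, mean(ratio) + 5 * s, length.out = 512L)
    dens <- colSums(w * stats::dnorm(outer(ratio, grid, "-") / h))
    peak <- grid[which.max(dens)]
    step <- grid[2] - grid[1]
    # polish the grid argmax within one grid step
    stats::optimize(function(g) sum(w * stats::dnorm((ratio - g) / h)),
                    c(peak - step, peak + step), maximum = TRUE)$maximum
  }
  est <- point(beta_exp, beta_out)
  se <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    J <- length(beta_exp)
    boots <- vapply(seq_len(n_boot), function(b)
      point(stats::rnorm(J, beta_exp, se_exp), stats::rnorm(J, beta_out, se_out)),
      numeric(1))
    se <- stats::sd(boots)
  }
  mr_result("mode", est, se, n_snps = length(beta_exp))
}

#' Per-variant outcome associations mutually adjusted for the trio
#'
#' For each variant fits one linear model of the (possibly imputed) child
#' outcome on the mother's, father's and child's dosages at that variant
#' plus the standard covariates, and records the mother and father dosage
#' coefficients as the parental variant-outcome effects. Conditioning on the
#' child's dosage is what makes these *within-family* summary associations.
#' Coefficients are obtained after residualizing outcome and dosages on the
#' covariates once (Frisch-Waugh), so the per-variant solve is a 3x3 system;
#' standard errors use the clustered sandwich in the residualized frame with
#' the full-model df correction. Monomorphic variants are dropped with a
#' warning.
#'
#' @param cohort a `trio_cohort`.
#' @param outcome numeric outcome vector, one per family (e.g. a completed,
#'   standardized outcome column).
#' @param variants variant ids to use (default: all panel variants).
#' @param covariates covariate matrix; default [spec_covariates()] of the
#'   cohort phenotypes (sex, birth year, batch, ancestry PCs).
#' @param cluster cluster id per family (default the family id).
#' @return data.frame of class `snp_assoc_set` with one row per variant and
#'   parent: `id`, `parent`, `beta_out`, `se_out`.
#' @export
snp_conditional_assocs <- function(cohort, outcome, variants = NULL,
                                   covariates = NULL, cluster = NULL) {
  if (is.null(variants)) variants <- cohort$panel$id
  if (is.null(covariates)) covariates <- spec_covariates(cohort$phenotypes)
  if (is.null(cluster)) cluster <- cohort$phenotypes$family_id
  keep <- !is.na(outcome)
  y <- outcome[keep]
  C <- cbind(1, as.matrix(covariates)[keep, , drop = FALSE])
  cl <- cluster[keep]
  qc <- qr(C)
  ry <- qr.resid(qc, y)
  rg <- lapply(cohort$dosages, function(D)
    qr.resid(qc, D[keep, variants, drop = FALSE]))
  k_full <- qc$rank + 3L
  n <- length(y)
  rows <- vector("list", length(variants))
  mono <- character()
  for (j in seq_along(variants)) {
    X <- cbind(mother = rg$mother[, j], father = rg$father[, j],
               child = rg$child[, j])
    v <- cohort$dosages$child[keep, variants[j]]
    if (stats::var(cohort$dosages$mother[keep, variants[j]]) == 0 ||
        stats::var(cohort$dosages$father[keep, variants[j]]) == 0 ||
        stats::var(v) == 0) {
      mono <- c(mono, variants[j]); next
    }
    XtXi <- solve(crossprod(X))
    beta <- drop(XtXi %*% crossprod(X, ry))
    u <- ry - drop(X %*% beta)
    sw <- cluster_sandwich(XtXi, X, u, cl, k_full)
    se <- sqrt(diag(sw$vcov))
    rows[[j]] <- data.frame(id = variants[j], parent = c("mother", "father"),
                            beta_out = beta[1:2], se_out = se[1:2],
                            beta_child = beta[3], se_child = se[3],
                            row.names = NULL)
  }
  if (length(mono))
    warning(sprintf("dropped %d monomorphic variant(s): %s", length(mono),
                    paste(utils::head(mono, 3), collapse = ", ")))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  class(out) <- c("snp_assoc_set", class(out))
  out
}

#' Simulate summary-level variant association sets
#'
#' Generates per-variant exposure effects and outcome effects
#' `beta_out = effect * beta_exp_true + alpha_j + noise`, where the direct
#' (pleiotropic) effects `alpha_j` are zero for valid instruments and drawn
#' from `N(pleiotropy_mean, pleiotropy_sd^2)` (independently of instrument
#' strength, so InSIDE holds) for the invalid fraction. Used to exercise
#' the summary-data estimators against planted truth without building a
#' cohort.
#'
#' @param n_snps number of variants.
#' @param effect true causal effect of the exposure on the outcome.
#' @param pleiotropy_mean,pleiotropy_sd distribution of the direct effects
#'   of invalid instruments.
#' @param prop_invalid fraction of variants given a direct effect.
#' @param se_exp,se_out sampling SEs of the published effects (scalars or
#'   per-variant vectors); `se_exp = 0` is the noiseless-exposure limit.
#' @param exp_sd SD of the true exposure effects.
#' @param seed optional seed.
#' @return data.frame with `beta_exp`, `se_exp`, `beta_out`, `se_out`,
#'   `alpha` (the planted direct effects) and a logical `valid`.
#' @export
simulate_snp_assocs <- function(n_snps, effect = 0, pleiotropy_mean = 0,
                                pleiotropy_sd = 0, prop_invalid = 1,
                                se_exp = 0, se_out = 0.02, exp_sd = 0.02,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # effects oriented to the exposure-increasing allele (half-normal), the
  # orientation on which directional pleiotropy is defined
  bx_true <- abs(stats::rnorm(n_snps, 0, exp_sd))
  se_exp <- rep_len(se_exp, n_snps)
  se_out <- rep_len(se_out, n_snps)
  invalid <- seq_len(n_snps) <= round(prop_invalid * n_snps)
  alpha <- ifelse(invalid,
                  stats::rnorm(n_snps, pleiotropy_mean, pleiotropy_sd), 0)
  bx <- bx_true + stats::rnorm(n_snps, 0, se_exp)
  by <- effect * bx_true + alpha + stats::rnorm(n_snps, 0, se_out)
  data.frame(beta_exp = bx, se_exp = se_exp, beta_out = by, se_out = se_out,
             alpha = alpha, valid = !invalid)
}

#' Run the full grid of summary-data MR estimators on a cohort
#'
#' Clumps the harmonized summary statistics (at `r2 = 0.01`, or the stricter
#' `0.001` subset with `strict = TRUE`), estimates mutually adjusted
#' per-variant outcome associations for each requested outcome, and applies
#' IVW, MR-Egger, weighted median and the mode-based estimator for each
#' parent. Exposure effects stay on the GWAS reporting scale, so estimates
#' inherit that per-unit scale.
#'
#' @param cohort a `trio_cohort`.
#' @param sumstats harmonized summary statistics (see
#'   [harmonize_alleles()]).
#' @param outcomes named list of outcome vectors (one value per family), or
#'   character vector of phenotype column names.
#' @param strict use the r2 = 0.001 clump (default `FALSE`).
#' @param ld LD matrix; default computed from the pooled parental dosages.
#' @param n_boot bootstrap draws behind the median/mode SEs.
#' @param seed seed for the bootstrap.
#' @return data.frame with one row per (outcome, parent, estimator):
#'   estimate, SE, CI, p, Q, number of variants, plus the Egger intercept
#'   columns on the Egger rows.
#' @export
run_twosample_suite <- function(cohort, sumstats, outcomes = "smfq",
                                strict = FALSE, ld = NULL, n_boot = 500L,
                                seed = 1L) {
  if (is.character(outcomes)) {
    nm <- outcomes
    outcomes <- lapply(nm, function(o) cohort$phenotypes[[o]])
    names(outcomes) <- nm
  }
  if (is.null(ld))
    ld <- ld_from_dosages(rbind(cohort$dosages$mother, cohort$dosages$father))
  cl <- if (strict) clump_strict(sumstats, ld)
        else clump_variants(sumstats, ld)
  ids <- cl$retained
  ss <- sumstats[match(ids, sumstats$id), ]
  rows <- list()
  for (onm in names(outcomes)) {
    assoc <- snp_conditional_assocs(cohort, outcomes[[onm]], variants = ids)
    for (parent in c("mother", "father")) {
      a <- assoc[assoc$parent == parent, ]
      a <- a[match(ids, a$id), ]
      ok <- !is.na(a$beta_out)
      bx <- ss$beta[ok]; sx <- ss$se[ok]
      by <- a$beta_out[ok]; sy <- a$se_out[ok]
      ests <- list(mr_ivw(bx, by, sy),
                   mr_egger(bx, by, sy),
                   mr_weighted_median(bx, by, sy, sx, n_boot = n_boot, seed = seed),
                   mr_mode(bx, by, sy, sx, n_boot = n_boot, seed = seed))
      for (e in ests) {
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = onm, parent = parent, estimator = e$estimator,
          estimate = e$estimate, se = e$se, ci_low = e$ci_low,
          ci_high = e$ci_high, p = e$p, Q = e$Q, n_snps = e$n_snps,
          egger_intercept = if (!is.null(e$intercept)) e$intercept else NA_real_,
          egger_intercept_p = if (!is.null(e$intercept_p)) e$intercept_p else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "clump") <- cl
  attr(out, "scale") <- "outcome SD per GWAS exposure unit"
  out
}
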