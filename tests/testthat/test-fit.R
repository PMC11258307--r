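test_that("outcome standardization is exact, idempotent, and rejects constants", {
  z <- standardize_outcome(c(0, 2))
  expect_equal(as.numeric(z), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  z2 <- standardize_outcome(as.numeric(z))
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-12)
  expect_error(standardize_outcome(rep(3, 10)), "constant")
  # fixed center/scale applied to new data
  s <- standardize_outcome(c(5, NA, 7), center = 5, scale = 2)
  expect_equal(as.numeric(s), c(0, NA, 1))
})

test_that("cluster-robust OLS: zero SEs under perfect fit, HC1 with singleton clusters", {
  x <- c(1, 2, 3, 4)
  y <- 2 + 3 * x
  f <- fit_ols_cluster(y, cbind(x = x), cluster = c(1, 1, 2, 2))
  expect_equal(f$coefficients$estimate, c(2, 3), tolerance = 1e-10)
  expect_equal(f$coefficients$se, c(0, 0), tolerance = 1e-10)

  skip_if_not_installed("sandwich")
  set.seed(61)
  n <- 80
  X <- cbind(a = rnorm(n), b = runif(n))
  yy <- 1 + X %*% c(0.5, -1) + rnorm(n) * (1 + X[, "b"])
  fo <- fit_ols_cluster(drop(yy), X, cluster = seq_len(n))
  lmf <- lm(yy ~ X)
  se_hc1 <- sqrt(diag(sandwich::vcovHC(lmf, type = "HC1")))
  expect_equal(fo$coefficients$se, unname(se_hc1), tolerance = 1e-10)

  expect_error(fit_ols_cluster(yy, X, cluster = rep(1, n)), "2 clusters")
})

test_that("cluster-robust OLS matches the brute-force sandwich oracle", {
  set.seed(62)
  n <- 30
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + X %*% c(1, -0.5) + rnorm(n)
  cl <- rep(1:10, each = 3)
  f <- fit_ols_cluster(drop(y), X, cl)
  o <- brute_ols_cluster(drop(y), X, cl)
  expect_equal(f$coefficients$estimate, unname(o$beta), tolerance = 1e-10)
  expect_equal(unname(f$vcov), unname(o$vcov), tolerance = 1e-10)
})

test_that("cluster-robust OLS recovers a planted slope with paired clusters", {
  set.seed(63)
  n <- 10000
  cl <- rep(1:5000, each = 2)
  u_cl <- rnorm(5000)[cl]
  x <- rnorm(n)
  y <- 0.5 * x + u_cl + rnorm(n)
  f <- fit_ols_cluster(y, cbind(x = x), cl)
  i <- f$coefficients$term == "x"
  expect_lt(abs(f$coefficients$estimate[i] - 0.5), 3 * f$coefficients$se[i])
})

test_that("2SLS reduces to OLS when instruments equal regressors, and to the Wald ratio", {
  set.seed(64)
  n <- 60
  x <- rnorm(n); y <- 1 + 2 * x + rnorm(n)
  cl <- rep(1:30, each = 2)
  f2 <- fit_2sls_cluster(y, cbind(x = x), cbind(x = x), cluster = cl)
  fo <- fit_ols_cluster(y, cbind(x = x), cl)
  expect_equal(sort(f2$coefficients$estimate), sort(fo$coefficients$estimate),
               tolerance = 1e-10)
  expect_equal(sort(f2$coefficients$se), sort(fo$coefficients$se),
               tolerance = 1e-10)

  # hand-computed Wald ratio: cov(z, y)/cov(z, x) = 1
  fw <- fit_2sls_cluster(c(0, 0, 1, 1), cbind(x = c(0, 1, 1, 2)),
                         cbind(z = c(0, 0, 1, 1)), cluster = 1:4)
  expect_equal(fw$coefficients$estimate[fw$coefficients$term == "x"], 1,
               tolerance = 1e-10)

  expect_error(fit_2sls_cluster(y, cbind(x, x2 = rnorm(n)), cbind(z = x),
                                cluster = cl),
               "under-identified")
})

test_that("2SLS uses structural residuals: coefficients and vcov match the oracle", {
  set.seed(65)
  n <- 30
  z <- cbind(z1 = rnorm(n), z2 = rnorm(n))
  w <- cbind(w1 = rnorm(n))
  x <- cbind(x1 = 0.8 * z[, 1] + rnorm(n), x2 = 0.7 * z[, 2] + rnorm(n))
  y <- drop(1 + x %*% c(1, -1) + w + rnorm(n))
  cl <- rep(1:10, each = 3)
  f <- fit_2sls_cluster(y, x, z, w, cluster = cl)
  o <- brute_2sls_cluster(y, x, z, w, cl)
  expect_equal(f$coefficients$estimate, unname(o$beta), tolerance = 1e-10)
  expect_equal(unname(f$vcov), unname(o$vcov), tolerance = 1e-10)
})

test_that("first-stage F follows the R-squared formula and flags weak instruments", {
  # construct R2_full = 0.5, R2_reduced = 0 exactly at n = 12:
  # x = z + e with z and e orthogonal, equal norms, both orthogonal to w
  z <- rep(c(1, -1), 6)
  e <- rep(c(1, 1, -1, -1), 3)
  w0 <- rnorm(12)
  w <- drop(residuals(lm(w0 ~ z + e)))  # orthogonal to 1, z, e
  x <- z + e
  d <- first_stage_diagnostics(cbind(x = x), cbind(z = z), cbind(w = w))
  expect_equal(d$F, 9, tolerance = 1e-8)
  expect_equal(d$F_conditional, d$F)
  expect_equal(d$partial_r2, 0.5, tolerance = 1e-8)

  # population-orthogonal instrument: F rarely above 10
  set.seed(66)
  fs <- replicate(40, {
    n <- 500
    first_stage_diagnostics(cbind(x = rnorm(n)), cbind(z = rnorm(n)), NULL)$F
  })
  expect_lte(mean(fs > 10), 0.05)
})

test_that("within-family MR recovers planted effects in one simulated cohort", {
  cfg <- recovery_config(10000, 60, seed = 67, beta_mother = 0, beta_father = 0,
                         eta = -0.08)
  co <- simulate_trio_cohort(cfg)
  ss <- simulate_gwas_sumstats(co$panel, cfg, noiseless = TRUE,
                               gamma = co$truth$gamma)
  sc <- score_cohort(co, ss)
  df <- co$phenotypes
  y <- co$truth$latent_outcomes[, "smfq"]
  df$smfq <- y
  f <- run_spec(df, sc, spec = "wfmr", outcome = "smfq")
  cf <- f$coefficients
  for (tm in c("edu_mother", "edu_father")) {
    i <- cf$term == tm
    expect_true(cf$ci_low[i] <= 0 && 0 <= cf$ci_high[i], info = tm)
  }
  i <- cf$term == "pgi_child"
  eta_std <- cfg$eta / sd(y)
  expect_lt(abs(cf$estimate[i] - eta_std), 3 * cf$se[i])
  # diagnostics present and coherent
  expect_true(all(f$diagnostics$F >= 0))
  expect_true(all(f$diagnostics$partial_r2 >= 0 & f$diagnostics$partial_r2 <= 1))
})

test_that("MR estimates agree with and without the child index under pure nurture", {
  cfg <- recovery_config(10000, 60, seed = 68, beta_mother = -0.02,
                         beta_father = 0, eta = 0)
  co <- simulate_trio_cohort(cfg)
  ss <- simulate_gwas_sumstats(co$panel, cfg, noiseless = TRUE,
                               gamma = co$truth$gamma)
  sc <- score_cohort(co, ss)
  df <- co$phenotypes
  df$smfq <- co$truth$latent_outcomes[, "smfq"]
  f_mr <- run_spec(df, sc, spec = "mr", outcome = "smfq", diagnostics = FALSE)
  f_wf <- run_spec(df, sc, spec = "wfmr", outcome = "smfq", diagnostics = FALSE)
  for (tm in c("edu_mother", "edu_father")) {
    a <- f_mr$coefficients[f_mr$coefficients$term == tm, ]
    b <- f_wf$coefficients[f_wf$coefficients$term == tm, ]
    expect_lt(abs(a$estimate - b$estimate), 3 * sqrt(a$se^2 + b$se^2))
  }
})

test_that("per-parent MR mode and sensitivity toggles run and stay consistent", {
  cfg <- recovery_config(4000, 40, seed = 69, beta_mother = 0, eta = -0.05,
                         discretize = TRUE)
  co <- simulate_trio_cohort(cfg)
  ss <- simulate_gwas_sumstats(co$panel, cfg, noiseless = TRUE,
                               gamma = co$truth$gamma)
  sc <- score_cohort(co, ss)
  df <- co$phenotypes # discretized outcomes, non-negative
  f_joint <- run_spec(df, sc, spec = "wfmr", outcome = "smfq", diagnostics = FALSE)
  f_pp <- run_spec(df, sc, spec = "wfmr", outcome = "smfq", per_parent = TRUE,
                   diagnostics = FALSE)
  a <- f_joint$coefficients[f_joint$coefficients$term == "edu_mother", ]
  b <- f_pp$coefficients[f_pp$coefficients$term == "edu_mother", ]
  expect_lt(abs(a$estimate - b$estimate), 3 * sqrt(a$se^2 + b$se^2))

  f_sqrt <- run_spec(df, sc, spec = "ols_minimal", outcome = "smfq",
                     sqrt_transform = TRUE)
  expect_s3_class(f_sqrt, "fit_result")
  f_m <- run_spec(df, sc, spec = "ols_minimal", outcome = "smfq", subset_sex = 1)
  f_f <- run_spec(df, sc, spec = "ols_minimal", outcome = "smfq", subset_sex = 0)
  expect_equal(f_m$n + f_f$n, nrow(df))
})

test_that("pooled fits across imputations carry Rubin variance components", {
  cfg <- sim_config(n_families = 1500, n_snps = 30, seed = 70,
                    ld_adjacent_corr = 0, missing_rate_outcome = 0.4)
  co <- simulate_trio_cohort(cfg)
  ss <- simulate_gwas_sumstats(co$panel, cfg, noiseless = TRUE,
                               gamma = co$truth$gamma)
  sc <- score_cohort(co, ss)
  imp_data <- cbind(co$phenotypes, pgi_mother = sc$pgi_mother,
                    pgi_father = sc$pgi_father, pgi_child = sc$pgi_child)
  keep <- c("family_id", "smfq", "edu_mother", "edu_father", "child_sex",
            "birth_year", "batch_centre", "batch_chip", "pgi_mother",
            "pgi_father", "pgi_child")
  cc <- chained_impute(imp_data[keep],
                       imputation_config(m = 3, n_cycles = 2, seed = 71,
                                         variables = "smfq"))
  merged <- lapply(cc$datasets, function(dd)
    cbind(dd, co$phenotypes[setdiff(names(co$phenotypes), names(dd))]))
  f <- run_spec(merged, sc, spec = "ols_minimal", outcome = "smfq",
                outcome_ref = co$phenotypes$smfq)
  expect_s3_class(f, "pooled_fit")
  cf <- f$coefficients
  expect_true(all(cf$T >= cf$W - 1e-12))
  expect_equal(f$m, 3)
})
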