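test_that("variant panel respects the frequency range and is reproducible", {
  cfg <- sim_config(n_families = 10, n_snps = 1, allele_freq_range = c(0.5, 0.5),
                    seed = 1)
  panel <- simulate_snp_panel(cfg)
  expect_equal(panel$frequency, 0.5)

  cfg2 <- sim_config(n_families = 10, n_snps = 100, seed = 42)
  expect_identical(simulate_snp_panel(cfg2), simulate_snp_panel(cfg2))

  expect_error(sim_config(allele_freq_range = c(0.9, 0.1)), "inverted")

  # uniform(0.1, 0.9) mean within 3 SE of 0.5 at 10,000 draws
  cfg3 <- sim_config(n_families = 10, n_snps = 10000, seed = 7)
  p3 <- simulate_snp_panel(cfg3)
  se <- 0.8 / sqrt(12 * 10000)
  expect_lt(abs(mean(p3$frequency) - 0.5), 3 * se)

  # positions strictly increasing within chromosome, 1-based
  for (ch in unique(p3$chromosome)) {
    pos <- p3$position[p3$chromosome == ch]
    expect_true(all(diff(pos) > 0) && all(pos >= 1))
  }
})

test_that("Mendelian transmission is exact for homozygote parents and fair for heterozygotes", {
  set.seed(1)
  n <- 10000
  both2 <- transmit_child(homozygote_parent(n, 2), homozygote_parent(n, 2))
  expect_true(all(both2$dosage == 2))
  both0 <- transmit_child(homozygote_parent(n, 0), homozygote_parent(n, 0))
  expect_true(all(both0$dosage == 0))

  # het x het: dosage (0,1,2) with probability (1/4, 1/2, 1/4)
  het <- transmit_child(homozygote_parent(n, 1), homozygote_parent(n, 1))
  tab <- tabulate(het$dosage + 1L, nbins = 3L)
  chi <- suppressWarnings(chisq.test(tab, p = c(0.25, 0.5, 0.25)))
  expect_gt(chi$p.value, 0.001)

  expect_error(transmit_child(homozygote_parent(5, 1), homozygote_parent(6, 1)),
               "locus mismatch")
})

test_that("simulated children are Mendelian-consistent with their parents", {
  cfg <- recovery_config(5000, 40, seed = 3)
  co <- simulate_trio_cohort(cfg)
  dm <- co$dosages$mother; df <- co$dosages$father; dc <- co$dosages$child
  # child allele count bounded by what each parent can transmit
  expect_true(all(dc >= (dm == 2) + (df == 2)))
  expect_true(all(dc <= 2 - (dm == 0) - (df == 0)))
  # transmitted haplotypes reconstruct the dosage exactly
  expect_identical(unname(dc), co$child_haplotypes$h_m + co$child_haplotypes$h_f)
  # mean child-minus-midparent dosage near 0
  dev <- rowMeans(dc - (dm + df) / 2)
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(length(dev)))
})

test_that("parent-child polygenic score covariance is half the parental variance", {
  cfg <- recovery_config(8000, 80, seed = 13)
  co <- simulate_trio_cohort(cfg)
  cm <- cov(co$truth$raw_pgi$mother, co$truth$raw_pgi$child)
  vm <- var(co$truth$raw_pgi$mother)
  # Monte-Carlo tolerance: SE of the covariance estimate
  se <- sqrt((vm * var(co$truth$raw_pgi$child) + cm^2) / 8000)
  expect_lt(abs(cm - vm / 2), 3 * se)
})

test_that("assortative mating calibration hits the target spousal correlation", {
  co <- simulate_trio_cohort(recovery_config(5000, 50, seed = 21, am_rho = 0.4))
  r <- cor(co$phenotypes$edu_mother, co$phenotypes$edu_father)
  expect_gt(r, 0.3); expect_lt(r, 0.5)

  co0 <- simulate_trio_cohort(recovery_config(5000, 50, seed = 22))
  r0 <- cor(co0$truth$raw_pgi$mother, co0$truth$raw_pgi$father)
  expect_lt(abs(r0), 3 / sqrt(5000))

  expect_error(sim_config(am_rho = 1), "am_rho")
})

test_that("education variance reduces to the noise variance when all signal is off", {
  cfg <- recovery_config(5000, 30, seed = 5, gamma = 0, conf_edu = 0)
  panel <- simulate_snp_panel(cfg)
  parents <- simulate_parents(panel, cfg)
  v <- var(parents$mother$edu)
  tgt <- cfg$edu_noise_sd^2
  se <- tgt * sqrt(2 / 5000)
  expect_lt(abs(v - tgt), 3 * se)
})

test_that("outcomes are pure noise when every structural path is off", {
  cfg <- recovery_config(5000, 30, seed = 9, beta_mother = 0, beta_father = 0,
                         eta = 0, conf_outcome = 0, sex_effect = 0)
  co <- simulate_trio_cohort(cfg)
  fit <- lm(co$truth$latent_outcomes[, "smfq"] ~ co$phenotypes$edu_mother +
              co$phenotypes$edu_father)
  cf <- summary(fit)$coefficients
  expect_lt(abs(cf[2, 1]), 3 * cf[2, 2])
  expect_lt(abs(cf[3, 1]), 3 * cf[3, 2])
})

test_that("a planted direct genetic effect is recovered from the latent outcome", {
  cfg <- recovery_config(10000, 60, seed = 17, eta = -0.08)
  co <- simulate_trio_cohort(cfg)
  std <- function(x) (x - mean(x)) / sd(x)
  fit <- lm(co$truth$latent_outcomes[, "smfq"] ~ co$truth$std_pgi_child +
              std(co$truth$raw_pgi$mother) + std(co$truth$raw_pgi$father))
  cf <- summary(fit)$coefficients
  expect_lt(abs(cf[2, 1] - (-0.08)), 3 * cf[2, 2])
})

test_that("discretized outcomes stay on their questionnaire ranges", {
  cfg <- sim_config(n_families = 2000, n_snps = 30, seed = 4, discretize = TRUE,
                    missing_rate_outcome = 0)
  co <- simulate_trio_cohort(cfg)
  for (nm in names(cfg$outcome_ranges)) {
    r <- cfg$outcome_ranges[[nm]]
    v <- co$phenotypes[[nm]]
    expect_true(all(v >= r[1] & v <= r[2]), info = nm)
    expect_true(all(v == round(v)), info = nm)
  }
  expect_identical(co$phenotypes$adhd_total,
                   co$phenotypes$adhd_inatt + co$phenotypes$adhd_hyper)
})

test_that("missingness mechanisms behave at the extremes and under MAR", {
  cfg0 <- recovery_config(2000, 20, seed = 6)
  co <- simulate_trio_cohort(cfg0)
  expect_false(anyNA(co$phenotypes$smfq))

  cfg1 <- modify_sim_config(cfg0, list(missing_rate_outcome = 1))
  co1 <- apply_missingness(co, cfg1)
  expect_true(all(is.na(co1$phenotypes$smfq)))

  # MAR on education with a negative coefficient: observed trios have
  # more educated parents
  cfgm <- recovery_config(20000, 20, seed = 8,
                          missing_rate_outcome = 0.5,
                          missing_mechanism = "MAR-on-education",
                          mar_edu_coef = -0.3)
  com <- simulate_trio_cohort(cfgm)
  ph <- com$phenotypes
  tt <- t.test(ph$edu_mother[!is.na(ph$smfq)], ph$edu_mother[is.na(ph$smfq)])
  expect_gt(tt$estimate[1], tt$estimate[2])
  expect_lt(tt$p.value, 0.001)
  # marginal rate close to the target
  expect_lt(abs(mean(is.na(ph$smfq)) - 0.5), 0.02)

  cfg_bad <- cfg0; cfg_bad$missing_mechanism <- "nonsense"
  expect_error(apply_missingness(co, cfg_bad), "unknown")
})

test_that("simulated GWAS effects collapse to the truth in the noiseless limit", {
  cfg <- recovery_config(10, 50, seed = 12, gamma = 2)
  panel <- simulate_snp_panel(cfg)
  ss <- simulate_gwas_sumstats(panel, cfg, noiseless = TRUE)
  expect_equal(ss$beta, 2 * panel$true_weight)
  set.seed(1); a <- simulate_gwas_sumstats(panel, cfg)
  set.seed(1); b <- simulate_gwas_sumstats(panel, cfg)
  expect_identical(a, b)
})

test_that("null GWAS p-values are uniform", {
  cfg <- sim_config(n_families = 10, n_snps = 2000, weight_sd = 0, gamma = 1,
                    seed = 19, missing_rate_outcome = 0)
  panel <- simulate_snp_panel(cfg)
  set.seed(23)
  ss <- simulate_gwas_sumstats(panel, cfg)
  frac <- mean(ss$pvalue < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- sim_config(n_families = 300, n_snps = 25, seed = 99)
  expect_identical(simulate_trio_cohort(cfg), simulate_trio_cohort(cfg))
})
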