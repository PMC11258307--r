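make_sumstats <- function(id, chr, pos, p, beta = 0.01,
                          ea = "A", oa = "C") {
  data.frame(id = id, chromosome = chr, position = pos,
             effect_allele = rep_len(ea, length(id)),
             other_allele = rep_len(oa, length(id)),
             beta = rep_len(beta, length(id)),
             se = rep_len(0.001, length(id)),
             pvalue = p, eaf = rep_len(0.3, length(id)),
             stringsAsFactors = FALSE)
}

test_that("allele harmonization matches, flips, and drops correctly", {
  panel <- data.frame(id = c("v1", "v2", "v3", "v4", "v5"),
                      allele_coded = c("A", "C", "A", "G", "A"),
                      allele_other = c("C", "A", "T", "C", "T"),
                      stringsAsFactors = FALSE)
  ss <- data.frame(id = c("v1", "v2", "v3", "v4", "v5", "v6"),
                   effect_allele = c("A", "A", "A", "G", "A", "A"),
                   other_allele = c("C", "C", "T", "T", "T", "C"),
                   beta = c(0.05, 0.02, 0.01, 0.03, 0.01, 0.1),
                   se = 0.01, pvalue = 1e-9,
                   eaf = c(0.3, 0.3, 0.5, 0.3, 0.2, 0.3),
                   stringsAsFactors = FALSE)
  h <- harmonize_alleles(ss, panel)
  # v1: identity
  expect_equal(h$sumstats$beta[h$sumstats$id == "v1"], 0.05)
  # v2: coded allele is the sumstats other allele -> sign flip
  expect_equal(h$sumstats$beta[h$sumstats$id == "v2"], -0.02)
  expect_equal(h$sumstats$eaf[h$sumstats$id == "v2"], 0.7)
  # v3: A/T with EAF 0.5 -> strand-ambiguous, dropped
  expect_false("v3" %in% h$sumstats$id)
  expect_true(any(h$log$id == "v3" & h$log$reason == "strand_ambiguous"))
  # v4: G/T vs G/C -> irreconcilable, dropped but not fatal
  expect_false("v4" %in% h$sumstats$id)
  expect_true(any(h$log$id == "v4" & h$log$reason == "allele_mismatch"))
  # v5: A/T ambiguous pair but EAF 0.2 outside the band -> kept
  expect_true("v5" %in% h$sumstats$id)
  # v6: absent from the genotype panel
  expect_true(any(h$log$id == "v6" & h$log$reason == "absent_from_panel"))
})

test_that("greedy clumping reproduces the hand-traced example", {
  # A (p=1e-10) claims B (r2=0.5, 50 kb away); C is independent
  ss <- make_sumstats(c("A", "B", "C"), 1, c(1e6, 1e6 + 5e4, 5e7),
                      c(1e-10, 1e-9, 1e-8))
  ld <- diag(3); dimnames(ld) <- list(ss$id, ss$id)
  ld["A", "B"] <- ld["B", "A"] <- 0.5
  cl <- clump_variants(ss, ld, r2_threshold = 0.01, window_kb = 10000)
  expect_identical(cl$retained, c("A", "C"))
  expect_identical(cl$dropped$id, "B")
  expect_identical(cl$dropped$index, "A")
})

test_that("clumping respects the p threshold and the no-LD case", {
  ss1 <- make_sumstats("X", 1, 100, 1e-7)
  expect_length(clump_variants(ss1, NULL, p_threshold = 5e-8)$retained, 0)

  ss <- make_sumstats(paste0("s", 1:5), 1, (1:5) * 1e5, rep(1e-9, 5))
  ld0 <- diag(5); dimnames(ld0) <- list(ss$id, ss$id)
  cl <- clump_variants(ss, ld0)
  expect_setequal(cl$retained, ss$id)
  # retention order nondecreasing in p (ties broken by chromosome, position)
  expect_identical(cl$retained, paste0("s", 1:5))
})

test_that("clumping matches the reference implementation on random panels", {
  set.seed(101)
  for (rep in 1:5) {
    p <- 20
    ss <- data.frame(id = paste0("r", 1:p), chromosome = sample(1:2, p, TRUE),
                     position = sample(1:2e7, p),
                     effect_allele = "A", other_allele = "C",
                     beta = rnorm(p, 0, 0.02), se = 0.005,
                     pvalue = 10^runif(p, -12, -4), eaf = runif(p, 0.1, 0.9),
                     stringsAsFactors = FALSE)
    ld <- matrix(runif(p * p), p); ld <- (ld + t(ld)) / 2; diag(ld) <- 1
    dimnames(ld) <- list(ss$id, ss$id)
    cl <- clump_variants(ss, ld, r2_threshold = 0.3, window_kb = 5000)
    ref <- reference_clump(ss, ld, 5e-8, 0.3, 5000)
    expect_identical(cl$retained, ref)
    # postcondition: no retained in-window pair with r2 >= threshold
    kept <- ss[match(cl$retained, ss$id), ]
    if (nrow(kept) > 1) for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
      same <- kept$chromosome[i] == kept$chromosome[j] &&
        abs(kept$position[i] - kept$position[j]) <= 5e6
      if (same) expect_lt(ld[kept$id[i], kept$id[j]], 0.3)
    }
  }
})

test_that("the strict clump is a subset of the standard clump", {
  set.seed(55)
  p <- 30
  ss <- data.frame(id = paste0("q", 1:p), chromosome = 1,
                   position = sort(sample(1:5e6, p)),
                   effect_allele = "A", other_allele = "C",
                   beta = rnorm(p, 0, 0.02), se = 0.005,
                   pvalue = 10^runif(p, -12, -8), eaf = 0.4,
                   stringsAsFactors = FALSE)
  ld <- outer(1:p, 1:p, function(i, j) 0.9^abs(i - j))^2
  dimnames(ld) <- list(ss$id, ss$id)
  std <- clump_variants(ss, ld)
  strict <- clump_strict(ss[ss$id %in% std$retained, ], ld)
  expect_true(all(strict$retained %in% std$retained))

  # threshold boundary: a pair with r2 = 0.005 survives at 0.01 but not 0.001
  ss2 <- make_sumstats(c("a", "b"), 1, c(100, 200), c(1e-10, 1e-9))
  ld2 <- matrix(c(1, 0.005, 0.005, 1), 2, dimnames = list(ss2$id, ss2$id))
  expect_length(clump_variants(ss2, ld2, r2_threshold = 0.01)$retained, 2L)
  expect_length(clump_strict(ss2, ld2)$retained, 1L)

  # empty input gives an empty result
  empty <- clump_strict(make_sumstats(character(), integer(), integer(),
                                      numeric()), NULL)
  expect_length(empty$retained, 0)
})

test_that("scoring is the weighted dosage sum, linear, and standardizes cleanly", {
  dos <- matrix(c(2, 1, 0, 0, 1, 2), 3, 2, byrow = TRUE,
                dimnames = list(NULL, c("v1", "v2")))
  ss <- data.frame(id = c("v1", "v2"), beta = c(0.1, -0.2))
  raw <- pgi_score(dos, ss)
  expect_equal(raw[1], 0.1 * 2 + (-0.2) * 1)
  expect_equal(raw[1], 0)
  expect_equal(pgi_score(matrix(0, 2, 2, dimnames = list(NULL, c("v1", "v2"))), ss),
               c(0, 0))
  # linearity in dosages
  expect_equal(pgi_score(3 * dos, ss), 3 * raw)
  # missing dosage for a retained variant is an error
  expect_error(pgi_score(dos[, 1, drop = FALSE], ss), "missing dosages")

  z <- standardize_score(c(raw, 0.5))
  expect_lt(abs(mean(z)), 1e-8)
  expect_lt(abs(sd(z) - 1), 1e-8)
  expect_error(standardize_score(c(1, 1, 1)), "distinct")
})

test_that("cohort scores are standardized within role and track the true genetic value", {
  cfg <- recovery_config(3000, 60, seed = 14)
  co <- simulate_trio_cohort(cfg)
  ss <- simulate_gwas_sumstats(co$panel, cfg, noiseless = TRUE,
                               gamma = co$truth$gamma)
  sc <- score_cohort(co, ss)
  for (role in c("mother", "father", "child")) {
    v <- sc[[paste0("pgi_", role)]]
    expect_lt(abs(mean(v)), 1e-8)
    expect_lt(abs(sd(v) - 1), 1e-8)
  }
  # noiseless weights: the scored index is collinear with the true raw score
  expect_gt(cor(sc$raw_child, co$truth$raw_pgi$child), 0.999999)
})
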