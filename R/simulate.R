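#' Simulate a variant panel
#'
#' Draws a panel of biallelic variants with uniform allele frequencies in the
#' configured range, strictly increasing 1-based positions spread over
#' chromosomes, distinct coded/other alleles, and a true per-allele weight on
#' education drawn from a zero-mean normal. The true weights are the ground
#' truth behind the simulated GWAS and the polygenic index.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `id`, `chromosome`, `position`,
#'   `allele_coded`, `allele_other`, `frequency`, `true_weight`, `block`.
#' @export
simulate_snp_panel <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  p <- config$n_snps
  fr <- config$allele_freq_range
  freq <- if (fr[1] == fr[2]) rep(fr[1], p) else stats::runif(p, fr[1], fr[2])
  block <- ((seq_len(p) - 1L) %/% config$ld_block_size) + 1L
  n_chr <- min(22L, max(1L, ceiling(p / 50)))
  chromosome <- sort(rep_len(seq_len(n_chr), p))
  # strictly increasing positions within each chromosome, 1-based
  position <- integer(p)
  for (ch in unique(chromosome)) {
    idx <- which(chromosome == ch)
    position[idx] <- cumsum(sample(1000:50000, length(idx), replace = TRUE))
  }
  bases <- c("A", "C", "G", "T")
  allele_coded <- sample(bases, p, replace = TRUE)
  allele_other <- vapply(allele_coded, function(a) sample(setdiff(bases, a), 1L), "")
  data.frame(id = sprintf("rs%06d", seq_len(p)),
             chromosome = chromosome, position = position,
             allele_coded = allele_coded, allele_other = unname(allele_other),
             frequency = freq,
             true_weight = stats::rnorm(p, 0, config$weight_sd),
             block = block,
             stringsAsFactors = FALSE)
}

# Draw n haplotypes for the panel: fresh Bernoulli(freq) per locus, except
# that within an LD block an allele is copied from the previous locus with
# probability ld_adjacent_corr. Returns an n x p 0/1 integer matrix.
draw_haplotypes <- function(n, panel, rho) {
  p <- nrow(panel)
  H <- matrix(stats::rbinom(n * p, 1L, rep(panel$frequency, each = n)), n, p)
  if (rho > 0 && p > 1L) {
    for (j in 2:p) {
      if (panel$block[j] == panel$block[j - 1L]) {
        copy <- stats::runif(n) < rho
        H[copy, j] <- H[copy, j - 1L]
      }
    }
  }
  H
}

#' Simulate matched parental couples
#'
#' Draws maternal and paternal haplotype pairs under the block-LD model,
#' builds years of education as intercept + gamma x raw polygenic index +
#' shared family confounder + noise, and pairs couples by rank-matching on
#' the pre-confounder education signal with additive matching noise whose SD
#' is calibrated (by a short secant refinement on the realized correlation)
#' so that the spousal correlation of education approximates `am_rho`.
#' With `am_rho = 0`, couples are paired at random.
#'
#' If `config$gamma` is `NULL`, gamma is calibrated on the realized parental
#' raw scores so the index explains `config$pgi_r2` of education variance.
#'
#' @param panel variant table from [simulate_snp_panel()].
#' @param config a [sim_config()].
#' @return list with elements `mother` and `father` (each holding haplotype
#'   matrices `h1`, `h2`, `raw_pgi`, `edu`), the shared family `confounder`,
#'   and the realized `gamma`.
#' @export
simulate_parents <- function(panel, config) {
  config <- validate_sim_config(config)
  if (nrow(panel) == 0L) stop("empty variant panel")
  n <- config$n_families
  w <- panel$true_weight
  rho <- config$ld_adjacent_corr

  hap <- function() draw_haplotypes(n, panel, rho)
  mh1 <- hap(); mh2 <- hap(); fh1 <- hap(); fh2 <- hap()
  raw_m <- drop((mh1 + mh2) %*% w)
  raw_f <- drop((fh1 + fh2) %*% w)

  gamma <- config$gamma
  if (is.null(gamma)) {
    # calibrate so the raw index explains pgi_r2 of total education variance:
    # gamma^2 var(raw) = pgi_r2 / (1 - pgi_r2) * (conf_edu^2 + noise^2)
    s_raw <- stats::sd(c(raw_m, raw_f))
    if (s_raw == 0) stop("raw polygenic index is constant; cannot calibrate gamma")
    gamma <- sqrt(config$pgi_r2 / (1 - config$pgi_r2) *
                    (config$conf_edu^2 + config$edu_noise_sd^2)) / s_raw
  }

  edu0_m <- config$edu_intercept[["mother"]] + gamma * raw_m +
    stats::rnorm(n, 0, config$edu_noise_sd)
  edu0_f <- config$edu_intercept[["father"]] + gamma * raw_f +
    stats::rnorm(n, 0, config$edu_noise_sd)

  if (config$am_rho == 0) {
    ord_f <- sample.int(n)
  } else {
    ord_f <- match_couples(edu0_m, edu0_f, config$am_rho, config$conf_edu)
  }
  fh1 <- fh1[ord_f, , drop = FALSE]; fh2 <- fh2[ord_f, , drop = FALSE]
  raw_f <- raw_f[ord_f]; edu0_f <- edu0_f[ord_f]

  confounder <- stats::rnorm(n)
  edu_m <- edu0_m + config$conf_edu * confounder
  edu_f <- edu0_f + config$conf_edu * confounder

  list(mother = list(h1 = mh1, h2 = mh2, raw_pgi = raw_m, edu = edu_m),
       father = list(h1 = fh1, h2 = fh2, raw_pgi = raw_f, edu = edu_f),
       confounder = confounder, gamma = gamma)
}

# Rank-matching with calibrated noise. Returns the permutation of fathers.
# The matching key is the pre-confounder education plus normal noise; the
# noise SD is set analytically for the target pre-confounder correlation and
# refined by secant steps on the realized total correlation (which includes
# the shared-confounder contribution conf_edu^2).
match_couples <- function(edu0_m, edu0_f, am_rho, conf_edu, max_iter = 6L) {
  n <- length(edu0_m)
  v0 <- (stats::var(edu0_m) + stats::var(edu0_f)) / 2
  vc <- conf_edu^2
  v_tot <- v0 + vc
  target0 <- (am_rho * v_tot - vc) / v0
  if (target0 <= 0) return(sample.int(n)) # shared confounder alone meets/exceeds target
  target0 <- min(target0, 0.999)
  zm <- stats::rnorm(n); zf <- stats::rnorm(n)
  pairing <- function(tgt) {
    tau <- sqrt(v0 * (1 - tgt) / tgt)
    ord_m <- order(edu0_m + tau * zm)
    ord_f <- order(edu0_f + tau * zf)
    perm <- integer(n)
    perm[ord_m] <- ord_f
    perm
  }
  realized <- function(perm) {
    # realized total spousal correlation incl. the shared confounder term
    cv <- stats::cov(edu0_m, edu0_f[perm]) + vc
    cv / v_tot
  }
  tgt <- target0
  perm <- pairing(tgt)
  for (i in seq_len(max_iter)) {
    r <- realized(perm)
    if (abs(r - am_rho) < 0.01) break
    tgt <- min(max(tgt + (am_rho - r) * v_tot / v0, 1e-4), 0.999)
    perm <- pairing(tgt)
  }
  perm
}

#' Mendelian transmission from parents to child
#'
#' At each locus the child receives one uniformly chosen allele from the
#' mother's haplotype pair and one from the father's, independently across
#' loci. Child dosages are therefore always attainable from the parents.
#'
#' @param mother,father lists with 0/1 haplotype matrices `h1` and `h2`
#'   (families x loci), both genotyped at identical loci.
#' @return list with the transmitted haplotypes `h_m`, `h_f` and the child
#'   `dosage` matrix (`h_m + h_f`).
#' @export
transmit_child <- function(mother, father) {
  if (!identical(dim(mother$h1), dim(father$h1)))
    stop("locus mismatch between parents")
  n <- nrow(mother$h1); p <- ncol(mother$h1)
  pick <- matrix(stats::runif(n * p) < 0.5, n, p)
  h_m <- mother$h1; h_m[!pick] <- mother$h2[!pick]
  pick <- matrix(stats::runif(n * p) < 0.5, n, p)
  h_f <- father$h1; h_f[!pick] <- father$h2[!pick]
  list(h_m = h_m, h_f = h_f, dosage = h_m + h_f)
}

# Map a latent N(0,1)-scale score onto a bounded questionnaire scale.
discretize_scale <- function(latent, scale, range) {
  z <- (latent - mean(latent)) / stats::sd(latent)
  pmin(pmax(round(scale[1] + scale[2] * z), range[1]), range[2])
}

#' Build trio phenotypes
#'
#' Constructs the latent child outcome as
#' `beta_m * edu_m + beta_f * edu_f + eta * stdPGI_child + conf_outcome * C +
#' sum_j alpha_j * g_child_j + sex effect + noise`, with per-variant
#' pleiotropic effects `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)`, and
#' optionally maps it onto each bounded questionnaire range by rounding and
#' clipping. Parental trait scores, smoking and parity are generated with a
#' positive loading on the family confounder so they behave as measurable
#' confounder proxies; genotyping batch labels and 20 ancestry principal
#' components per person are pure-noise covariates.
#'
#' @param parents output of [simulate_parents()].
#' @param child output of [transmit_child()].
#' @param panel variant table.
#' @param config a [sim_config()].
#' @return list with the phenotype `data.frame` (one row per trio) and a
#'   `truth` list (pleiotropy draws, latent outcomes, standardized child
#'   index SD, realized gamma inputs).
#' @export
build_phenotypes <- function(parents, child, panel, config) {
  config <- validate_sim_config(config)
  n <- config$n_families
  C <- parents$confounder
  raw_c <- drop(child$dosage %*% panel$true_weight)
  sd_raw_c <- stats::sd(raw_c)
  std_c <- if (sd_raw_c > 0) (raw_c - mean(raw_c)) / sd_raw_c else raw_c * 0

  alpha <- stats::rnorm(config$n_snps, config$pleiotropy_mean, config$pleiotropy_sd)
  pleio <- if (config$pleiotropy_mean != 0 || config$pleiotropy_sd != 0)
    drop(child$dosage %*% alpha) else numeric(n)

  sex <- stats::rbinom(n, 1L, 0.51) # 1 = male
  birth_year <- sample(2000:2009, n, replace = TRUE)

  structural <- config$beta_mother * parents$mother$edu +
    config$beta_father * parents$father$edu +
    config$eta * std_c + config$conf_outcome * C + pleio +
    config$sex_effect * sex

  out_names <- names(config$outcome_ranges)
  latent <- sapply(out_names, function(nm)
    structural + stats::rnorm(n, 0, config$outcome_noise_sd))
  if (is.null(dim(latent))) latent <- matrix(latent, nrow = n, dimnames = list(NULL, out_names))

  reported <- latent
  if (config$discretize) {
    for (nm in out_names)
      reported[, nm] <- discretize_scale(latent[, nm], config$outcome_scale[[nm]],
                                         config$outcome_ranges[[nm]])
  }

  ord_score <- function(loading, thresholds) {
    z <- loading * C + stats::rnorm(n)
    findInterval(z, thresholds)
  }
  trait <- function(loading, scale, range) {
    z <- loading * C + stats::rnorm(n)
    discretize_scale(z, scale, range)
  }

  pheno <- data.frame(family_id = sprintf("fam%06d", seq_len(n)),
                      edu_mother = parents$mother$edu,
                      edu_father = parents$father$edu,
                      child_sex = sex, birth_year = birth_year,
                      stringsAsFactors = FALSE)
  pheno <- cbind(pheno, as.data.frame(reported))
  if (all(c("adhd_inatt", "adhd_hyper") %in% out_names))
    pheno$adhd_total <- pheno$adhd_inatt + pheno$adhd_hyper
  pheno$trait_depanx_mother <- trait(0.4, c(1.2, 1.9), c(0, 15))
  pheno$trait_depanx_father <- trait(0.4, c(1.1, 2.1), c(0, 24))
  pheno$trait_adhd_mother <- trait(0.3, c(6.7, 3.5), c(0, 24))
  pheno$trait_adhd_father <- trait(0.3, c(8.2, 3.1), c(0, 24))
  pheno$smoking_mother <- ord_score(0.3, config$smoking_thresholds)
  pheno$smoking_father <- ord_score(0.3, config$smoking_thresholds)
  pheno$parity <- ord_score(0.2, config$parity_thresholds)
  pheno$batch_centre <- sample(c("C1", "C2", "C3"), n, replace = TRUE,
                               prob = c(0.5, 0.3, 0.2))
  pheno$batch_chip <- sample(c("chipA", "chipB"), n, replace = TRUE,
                             prob = c(0.6, 0.4))
  for (role in c("child", "mother", "father"))
    for (k in 1:20)
      pheno[[sprintf("pc%d_%s", k, role)]] <- stats::rnorm(n)

  list(phenotypes = pheno,
       truth = list(pleiotropy = alpha, latent_outcomes = latent,
                    raw_pgi_child = raw_c, sd_raw_pgi_child = sd_raw_c,
                    std_pgi_child = std_c))
}

#' Apply outcome missingness to a trio cohort
#'
#' Blanks child outcome scores either completely at random (MCAR) or with a
#' missingness probability that is a logistic function of mid-parental years
#' of education (MAR-on-education; the intercept is calibrated so the
#' marginal rate matches `missing_rate_outcome`). Genotypes are never made
#' missing. The ADHD total, when present, is recomputed so it is missing
#' whenever either subscale is.
#'
#' @param cohort a `trio_cohort`.
#' @param config a [sim_config()]; its `missing_rate_outcome`,
#'   `missing_mechanism` and `mar_edu_coef` fields are used.
#' @return the cohort with `NA`s in the outcome columns; the pre-missingness
#'   outcome table is kept in `truth$complete_outcomes`.
#' @export
apply_missingness <- function(cohort, config) {
  rate <- config$missing_rate_outcome
  if (rate < 0 || rate > 1) stop("missing_rate_outcome must lie in [0, 1]")
  mech <- config$missing_mechanism
  if (!mech %in% c("MCAR", "MAR-on-education"))
    stop(sprintf("unknown missingness mechanism '%s'", mech))
  pheno <- cohort$phenotypes
  out_cols <- intersect(names(config$outcome_ranges), names(pheno))
  cohort$truth$complete_outcomes <-
    pheno[, intersect(c(out_cols, "adhd_total"), names(pheno)), drop = FALSE]
  if (rate == 0) return(cohort)
  n <- nrow(pheno)
  for (nm in out_cols) {
    if (rate == 1) {
      miss <- rep(TRUE, n)
    } else if (mech == "MCAR") {
      miss <- stats::runif(n) < rate
    } else {
      mid_edu <- (pheno$edu_mother + pheno$edu_father) / 2
      slope <- config$mar_edu_coef
      a <- stats::uniroot(function(a) mean(stats::plogis(a + slope * mid_edu)) - rate,
                          c(-50, 50), tol = 1e-8)$root
      miss <- stats::runif(n) < stats::plogis(a + slope * mid_edu)
    }
    pheno[[nm]][miss] <- NA_real_
  }
  if ("adhd_total" %in% names(pheno))
    pheno$adhd_total <- pheno$adhd_inatt + pheno$adhd_hyper
  cohort$phenotypes <- pheno
  cohort
}

#' Simulate GWAS summary statistics for the panel
#'
#' Published per-allele effects are the variants' true effects on years of
#' education (`gamma` times the panel's raw true weights) plus estimation
#' noise, `beta = gamma * true_weight + N(0, se^2)`, with the standard error
#' derived from the discovery sample size and allele frequency as
#' `se = trait_sd / sqrt(2 f (1 - f) N)` (the usual per-allele SE). P-values
#' come from the two-sided Wald statistic. Setting `noiseless = TRUE`
#' overrides the effect draw to the infinite-discovery-sample limit
#' (published betas equal the true per-allele effects) while keeping the
#' reported `se` column positive for downstream weighting.
#'
#' @param panel variant table from [simulate_snp_panel()].
#' @param config a [sim_config()].
#' @param noiseless if `TRUE`, the infinite-discovery-sample limit.
#' @param gamma raw-score-to-years scaling; default the config's fixed
#'   `gamma`, or 1 when gamma is calibrated downstream (pass the cohort's
#'   realized `truth$gamma` to put published betas on the years scale).
#' @param trait_sd residual SD of the trait in the discovery sample;
#'   default the education noise implied by the config.
#' @return a summary-statistics data.frame with columns `id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`,
#'   `eaf`.
#' @export
simulate_gwas_sumstats <- function(panel, config, noiseless = FALSE,
                                   gamma = NULL, trait_sd = NULL) {
  if (config$discovery_n <= 0) stop("discovery_n must be positive")
  if (is.null(gamma)) gamma <- if (is.null(config$gamma)) 1 else config$gamma
  if (is.null(trait_sd))
    trait_sd <- sqrt(config$conf_edu^2 + config$edu_noise_sd^2)
  se <- trait_sd / sqrt(2 * panel$frequency * (1 - panel$frequency) *
                          config$discovery_n)
  beta <- if (noiseless) gamma * panel$true_weight
          else gamma * panel$true_weight + stats::rnorm(nrow(panel), 0, se)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  if (noiseless) p[beta != 0] <- pmin(p[beta != 0], .Machine$double.xmin)
  data.frame(id = panel$id, chromosome = panel$chromosome,
             position = panel$position,
             effect_allele = panel$allele_coded,
             other_allele = panel$allele_other,
             beta = beta, se = se, pvalue = p, eaf = panel$frequency,
             stringsAsFactors = FALSE)
}

#' Simulate a full trio cohort
#'
#' One-call driver: variant panel, matched parents, Mendelian transmission,
#' phenotypes, and (if configured) outcome missingness, all under the
#' config's seed (a fixed seed gives a bit-identical cohort).
#'
#' @param config a [sim_config()].
#' @return an object of class `trio_cohort`: a list with the variant `panel`,
#'   per-role `dosages` (list of families x variants matrices for `mother`,
#'   `father`, `child`), the `phenotypes` data.frame, and a `truth` list
#'   holding the config, realized gamma, confounder, raw/standardized
#'   polygenic indexes and latent outcomes.
#' @export
simulate_trio_cohort <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  panel <- simulate_snp_panel(config) # seeds the RNG with config$seed
  parents <- simulate_parents(panel, config)
  child <- transmit_child(parents$mother, parents$father)
  ph <- build_phenotypes(parents, child, panel, config)

  dos <- list(mother = parents$mother$h1 + parents$mother$h2,
              father = parents$father$h1 + parents$father$h2,
              child = child$dosage)
  for (r in names(dos)) dimnames(dos[[r]]) <- list(ph$phenotypes$family_id, panel$id)

  cohort <- structure(list(
    panel = panel,
    dosages = dos,
    child_haplotypes = list(h_m = child$h_m, h_f = child$h_f),
    phenotypes = ph$phenotypes,
    truth = c(list(config = config, gamma = parents$gamma,
                   confounder = parents$confounder,
                   raw_pgi = list(mother = parents$mother$raw_pgi,
                                  father = parents$father$raw_pgi,
                                  child = ph$truth$raw_pgi_child)),
              ph$truth[setdiff(names(ph$truth), "raw_pgi_child")])),
    class = "trio_cohort")
  if (config$missing_rate_outcome > 0) cohort <- apply_missingness(cohort, config)
  cohort
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("Trio cohort: %d families, %d variants\n",
              nrow(x$phenotypes), nrow(x$panel)))
  out_cols <- intersect(names(x$truth$config$outcome_ranges), names(x$phenotypes))
  miss <- vapply(x$phenotypes[out_cols], function(v) mean(is.na(v)), 0)
  cat(sprintf("  outcomes: %s\n",
              paste(sprintf("%s (%.0f%% missing)", out_cols, 100 * miss), collapse = ", ")))
  cat(sprintf("  realized gamma: %.4f years per raw-score unit\n", x$truth$gamma))
  invisible(x)
}
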