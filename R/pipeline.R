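#' Configuration for a full pipeline run
#'
#' Bundles the simulation configuration, the model grid, imputation
#' settings, sensitivity toggles and the seed for one reproducible run of
#' simulate -> polygenic index -> impute -> one-sample models -> two-sample
#' MR. The default desk-scale profile (20,000 trios, 200 variants, m = 5
#' imputations) keeps a full run interactive; `full_scale = TRUE` switches
#' to the full-cohort profile (40,879 trios, 1729 variants, m = 50).
#'
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param outcomes outcome columns to analyse.
#' @param specs model specifications to fit (see [run_spec()]).
#' @param m number of imputed datasets.
#' @param n_cycles chained-equation sweeps.
#' @param knn PMM donor-pool size.
#' @param sqrt_transform,by_sex,complete_case,strict_clump sensitivity
#'   toggles.
#' @param twosample run the summary-data MR stage.
#' @param full_scale use the full-cohort problem sizes (40,879 trios, 1729 variants, 50 imputations).
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL,
                       outcomes = c("smfq", "scared", "adhd_inatt", "adhd_hyper"),
                       specs = c("ols_minimal", "ols_adjusted", "mr", "wfmr"),
                       m = 5L, n_cycles = 5L, knn = 10L,
                       sqrt_transform = FALSE, by_sex = FALSE,
                       complete_case = FALSE, strict_clump = FALSE,
                       twosample = TRUE, full_scale = FALSE, seed = 1L) {
  if (is.null(sim)) {
    sim <- if (full_scale)
      sim_config(n_families = 40879L, n_snps = 1729L, seed = seed)
    else sim_config(seed = seed)
  }
  if (full_scale) m <- 50L
  structure(list(sim = sim, outcomes = outcomes, specs = specs,
                 m = as.integer(m), n_cycles = as.integer(n_cycles),
                 knn = as.integer(knn), sqrt_transform = sqrt_transform,
                 by_sex = by_sex, complete_case = complete_case,
                 strict_clump = strict_clump, twosample = twosample,
                 full_scale = full_scale, seed = as.integer(seed)),
            class = "run_config")
}

# Small deterministic hash of a configuration (djb2 over its deparsed text),
# recorded in the run manifest so outputs can be traced to their config.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full trio-MR analysis pipeline
#'
#' Simulates (or accepts) a trio cohort, simulates GWAS summary statistics,
#' harmonizes and clumps them, scores the polygenic indexes, multiply
#' imputes the phenotypes when outcomes carry missingness, fits the
#' requested model specifications for every outcome with Rubin pooling, and
#' (optionally) runs the summary-data MR estimator grid. Fully deterministic
#' under the config's seed.
#'
#' @param config a [run_config()].
#' @param cohort optionally, a pre-built `trio_cohort` (the simulate stage
#'   is then skipped).
#' @return list of class `triomr_run` with elements `results` (tidy table:
#'   spec x outcome x term with estimate, SE, CI, p, n), `twosample`,
#'   `diagnostics` (first-stage F, conditional F, partial R2, clump counts),
#'   `clump`, `scores`, `cohort`, and `manifest` (config, seed, hash,
#'   record counts for every filtering stage).
#' @export
run_analysis <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) cohort <- simulate_trio_cohort(config$sim)
  sim <- cohort$truth$config
  set.seed(config$seed + 1L)
  sumstats <- simulate_gwas_sumstats(cohort$panel, sim,
                                     gamma = cohort$truth$gamma)
  harm <- harmonize_alleles(sumstats, cohort$panel)
  ld <- ld_from_dosages(rbind(cohort$dosages$mother, cohort$dosages$father))
  cl <- if (config$strict_clump) clump_strict(harm$sumstats, ld)
        else clump_variants(harm$sumstats, ld)
  scores <- score_cohort(cohort, harm$sumstats, cl$retained)

  pheno <- cohort$phenotypes
  outcomes <- intersect(config$outcomes, names(pheno))
  has_missing <- any(vapply(pheno[outcomes], anyNA, TRUE))
  if (has_missing && !config$complete_case) {
    imp_data <- cbind(pheno,
                      pgi_mother = scores$pgi_mother,
                      pgi_father = scores$pgi_father,
                      pgi_child = scores$pgi_child)
    imp_vars <- names(imp_data)[vapply(imp_data, anyNA, TRUE)]
    imp_vars <- setdiff(imp_vars, "adhd_total")
    icfg <- imputation_config(m = config$m, knn = config$knn,
                              n_cycles = config$n_cycles,
                              variables = imp_vars,
                              passive = if ("adhd_total" %in% names(imp_data))
                                list(adhd_total = c("adhd_inatt", "adhd_hyper"))
                              else list(),
                              seed = config$seed + 2L)
    completed <- chained_impute(imp_data, icfg)
    datasets <- completed$datasets
  } else {
    if (config$complete_case) {
      keep <- stats::complete.cases(pheno[, c(outcomes, "edu_mother", "edu_father")])
      pheno <- pheno[keep, , drop = FALSE]
    }
    completed <- NULL
    datasets <- list(pheno)
  }

  sexes <- if (config$by_sex) c(male = 1L, female = 0L) else c(all = NA_integer_)
  rows <- list()
  diags <- list()
  for (onm in outcomes) {
    ref <- cohort$phenotypes[[onm]] # observed values before imputation
    for (sp in config$specs) {
      for (sx in names(sexes)) {
        fit <- run_spec(datasets, scores, spec = sp, outcome = onm,
                        sqrt_transform = config$sqrt_transform,
                        subset_sex = if (is.na(sexes[[sx]])) NULL else sexes[[sx]],
                        outcome_ref = if (config$sqrt_transform) NULL else ref)
        co <- fit$coefficients
        keep_terms <- co$term %in% c("edu_mother", "edu_father", "pgi_child")
        co <- co[keep_terms, c("term", "estimate", "se", "ci_low", "ci_high", "p")]
        co$spec <- sp; co$outcome <- onm; co$sex <- sx
        co$n <- fit$n; co$n_clusters <- fit$n_clusters
        rows[[length(rows) + 1L]] <- co
        if (!is.null(fit$diagnostics)) {
          d <- fit$diagnostics
          d$spec <- sp; d$outcome <- onm; d$sex <- sx
          diags[[length(diags) + 1L]] <- d
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  ts <- NULL
  if (config$twosample) {
    outcome_values <- lapply(outcomes, function(onm) {
      vals <- if (is.null(completed))
        datasets[[1]][[onm]]
      else # imputed outcome with unimputed genotype data: first completed set
        completed$datasets[[1]][[onm]]
      standardize_outcome(vals)
    })
    names(outcome_values) <- outcomes
    ts <- run_twosample_suite(cohort, harm$sumstats, outcome_values,
                              strict = config$strict_clump, ld = ld,
                              seed = config$seed + 3L)
  }

  manifest <- list(
    seed = config$seed, config_hash = config_hash(config),
    n_families = nrow(cohort$phenotypes), n_snps = nrow(cohort$panel),
    n_harmonized = nrow(harm$sumstats),
    n_harmonization_dropped = nrow(harm$log),
    n_clumped = length(cl$retained),
    clump_params = cl$params,
    m = length(datasets),
    outcome_missing = vapply(cohort$phenotypes[outcomes],
                             function(v) mean(is.na(v)), 0),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  structure(list(results = results,
                 twosample = ts,
                 diagnostics = list(first_stage = if (length(diags))
                   do.call(rbind, diags) else NULL,
                   clump = data.frame(retained = length(cl$retained),
                                      dropped = nrow(cl$dropped))),
                 clump = cl, scores = scores, cohort = cohort,
                 manifest = manifest),
            class = "triomr_run")
}

#' @export
print.triomr_run <- function(x, ...) {
  cat(sprintf("triomr run (seed %d, config %s): %d families, %d/%d variants retained\n",
              x$manifest$seed, x$manifest$config_hash, x$manifest$n_families,
              x$manifest$n_clumped, x$manifest$n_snps))
  cat(sprintf("  %d model results across %s\n", nrow(x$results),
              paste(unique(x$results$spec), collapse = ", ")))
  if (!is.null(x$twosample))
    cat(sprintf("  %d summary-MR estimates\n", nrow(x$twosample)))
  invisible(x)
}

#' Simulation study over a scenario grid
#'
#' For each scenario (a named list of [sim_config()] overrides) simulates
#' independent cohorts, fits the requested estimators with noiseless
#' weights, and summarizes bias, empirical SE and 95% CI coverage of the
#' maternal education effect against the scenario's planted truth.
#' Per-replicate seeds are derived from the master seed so replicates are
#' independent and the whole table is reproducible.
#'
#' @param scenarios named list of scenario override lists.
#' @param replicates replicates per scenario (>= 1; with 1, the empirical
#'   SE is reported as `NA`).
#' @param seed master seed.
#' @param estimators subset of `c("mr", "wfmr")`.
#' @param base a base [sim_config()] the overrides are applied to.
#' @return data.frame of class `simulation_study`: one row per scenario x
#'   estimator with `mean_estimate`, `empirical_se`, `bias`, `coverage`,
#'   `replicates`.
#' @export
run_simulation_study <- function(scenarios, replicates = 100L, seed = 1L,
                                 estimators = c("mr", "wfmr"),
                                 base = sim_config(n_families = 5000L,
                                                   n_snps = 100L,
                                                   ld_adjacent_corr = 0,
                                                   discretize = FALSE,
                                                   missing_rate_outcome = 0)) {
  if (replicates < 1L) stop("replicates must be >= 1")
  out <- list()
  for (snm in names(scenarios)) {
    cfg0 <- modify_sim_config(base, scenarios[[snm]])
    ests <- matrix(NA_real_, replicates, length(estimators),
                   dimnames = list(NULL, estimators))
    covers <- ests
    errs <- ests
    for (r in seq_len(replicates)) {
      cfg <- cfg0
      cfg$seed <- as.integer((as.numeric(seed) * 10007 + r * 101) %% 2147483647)
      cohort <- simulate_trio_cohort(cfg)
      ss <- simulate_gwas_sumstats(cohort$panel, cfg, noiseless = TRUE)
      scores <- score_cohort(cohort, ss)
      y <- cohort$truth$latent_outcomes[, 1]
      df <- cohort$phenotypes
      df[[colnames(cohort$truth$latent_outcomes)[1]]] <- y
      for (est in estimators) {
        fit <- run_spec(df, scores, spec = est,
                        outcome = colnames(cohort$truth$latent_outcomes)[1],
                        diagnostics = FALSE)
        co <- fit$coefficients
        i <- match("edu_mother", co$term)
        # planted effect on the standardized-outcome scale
        truth <- cfg$beta_mother / stats::sd(y)
        ests[r, est] <- co$estimate[i]
        errs[r, est] <- co$estimate[i] - truth
        covers[r, est] <- co$ci_low[i] <= truth && truth <= co$ci_high[i]
      }
    }
    for (est in estimators) {
      out[[length(out) + 1L]] <- data.frame(
        scenario = snm, estimator = est,
        mean_estimate = mean(ests[, est]),
        empirical_se = if (replicates > 1L) stats::sd(ests[, est]) else NA_real_,
        bias = mean(errs[, est]),
        coverage = mean(covers[, est]),
        replicates = replicates)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("simulation_study", class(res))
  res
}

#' Map education categories to years of schooling
#'
#' Applies a user-editable category-to-years lookup table. The default
#' table shipped with the package (`inst/extdata/education_years.tsv`) is a
#' synthetic ISCED-style mapping intended as a starting point; studies
#' should substitute their own mapping.
#'
#' @param categories vector of education category labels.
#' @param table data.frame with columns `category` and `years`; default the
#'   shipped table.
#' @return numeric years of education; unmatched categories give `NA` with
#'   a warning.
#' @export
map_education <- function(categories, table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "education_years.tsv", package = "triomr")
    table <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("category", "years") %in% names(table)))
  years <- table$years[match(as.character(categories), table$category)]
  un <- is.na(years) & !is.na(categories)
  if (any(un))
    warning(sprintf("%d category value(s) not in the mapping table", sum(un)))
  years
}
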