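#' Configuration for chained-equation multiple imputation
#'
#' @param m number of imputed datasets (>= 2; the study default is 50, a
#'   lighter desk default of 5 keeps interactive work fast).
#' @param knn donor-pool size for predictive mean matching (default 10).
#' @param n_cycles chained-equation sweeps per dataset (default 10).
#' @param variables character vector of columns to impute; default: every
#'   column with missing values that is not a passive total.
#' @param ordinal character vector naming variables treated as ordinal;
#'   they are imputed by PMM on their integer codes, which preserves the
#'   observed support.
#' @param predictors columns used on the right-hand side of every
#'   imputation equation; default: all columns except identifiers and
#'   passive totals. Factors enter as dummies.
#' @param passive named list of passive totals, each a character vector of
#'   component columns summed after imputation (e.g. the ADHD full scale
#'   from its inattention and hyperactivity subscales).
#' @param id_cols identifier columns excluded from modelling.
#' @param seed integer seed for reproducibility.
#' @return object of class `imputation_config`.
#' @export
imputation_config <- function(m = 5L, knn = 10L, n_cycles = 10L,
                              variables = NULL, ordinal = character(),
                              predictors = NULL, passive = list(),
                              id_cols = "family_id", seed = NULL) {
  if (m < 2L) stop("m must be >= 2")
  if (knn < 1L) stop("knn must be >= 1")
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  structure(list(m = as.integer(m), knn = as.integer(knn),
                 n_cycles = as.integer(n_cycles), variables = variables,
                 ordinal = ordinal, predictors = predictors,
                 passive = passive, id_cols = id_cols, seed = seed),
            class = "imputation_config")
}

#' Predictive-mean-matching imputation of one column
#'
#' Fits a linear model of the observed target values on the predictors,
#' draws regression parameters from their approximate posterior (sigma^2
#' from the scaled inverse chi-square, coefficients from the corresponding
#' normal), predicts observed rows with the posterior-mean coefficients and
#' missing rows with the drawn coefficients (type-1 matching), finds the
#' `knn` observed rows with the closest predictions for each missing row,
#' and copies the observed value of one uniformly chosen donor. Imputed
#' values are therefore always observed donor values, so they can never
#' leave the observed range.
#'
#' @param y numeric vector with `NA`s to impute.
#' @param X complete numeric predictor matrix (no intercept column; one is
#'   added internally).
#' @param knn donor-pool size.
#' @param ridge small ridge added to the cross-product for numerical
#'   stability with collinear predictors.
#' @return `y` with missing entries replaced by donor values.
#' @export
pmm_impute_column <- function(y, X, knn = 10L, ridge = 1e-10) {
  X <- as.matrix(X)
  obs <- which(!is.na(y)); mis <- which(is.na(y))
  if (!length(mis)) return(y)
  k <- ncol(X) + 1L
  if (length(obs) < k + knn)
    stop(sprintf(paste0("only %d observed values for %d predictors + knn = %d; ",
                        "use fewer predictors or a smaller donor pool"),
                 length(obs), k - 1L, knn))
  Xo <- cbind(1, X[obs, , drop = FALSE])
  yo <- y[obs]
  XtX <- crossprod(Xo) + diag(ridge * max(1, diag(crossprod(Xo))), k)
  XtXi <- solve(XtX)
  beta_hat <- drop(XtXi %*% crossprod(Xo, yo))
  res <- yo - drop(Xo %*% beta_hat)
  df <- max(length(obs) - k, 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1L, df)
  R <- chol((XtXi + t(XtXi)) / 2)
  beta_star <- beta_hat + drop(t(R) %*% stats::rnorm(k)) * sqrt(sigma2)
  yhat_obs <- drop(Xo %*% beta_hat)
  yhat_mis <- drop(cbind(1, X[mis, , drop = FALSE]) %*% beta_star)

  ord <- order(yhat_obs)
  so <- yhat_obs[ord]
  vo <- yo[ord]
  n_obs <- length(so)
  pos <- findInterval(yhat_mis, so)
  donors <- vapply(seq_along(mis), function(i) {
    lo <- pos[i]; hi <- pos[i] + 1L
    cand <- integer(knn)
    for (j in seq_len(knn)) {
      take_lo <- hi > n_obs ||
        (lo >= 1L && (yhat_mis[i] - so[lo]) <= (so[hi] - yhat_mis[i]))
      if (take_lo && lo >= 1L) { cand[j] <- lo; lo <- lo - 1L }
      else { cand[j] <- hi; hi <- hi + 1L }
    }
    vo[cand[sample.int(knn, 1L)]]
  }, numeric(1))
  y[mis] <- donors
  y
}

#' Multiple imputation by chained equations
#'
#' Visits the variables with missingness in order of increasing missingness
#' each cycle, imputing each by predictive mean matching given the current
#' completed values of every predictor, and repeats independently `m` times.
#' Passive totals are formed from their imputed components after each
#' dataset is completed and are never used as predictors. Ordinal variables
#' go through the same PMM path on their integer codes.
#'
#' @param data data.frame with missing values in the variables to impute;
#'   predictor columns (e.g. polygenic indexes, batch dummies) must be
#'   complete.
#' @param config an [imputation_config()].
#' @return object of class `completed_data`: list with `datasets` (list of
#'   `m` completed data.frames), the logical `missing_pattern`, and the
#'   `config`.
#' @export
chained_impute <- function(data, config = imputation_config()) {
  stopifnot(inherits(config, "imputation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  passive_cols <- names(config$passive)
  vars <- config$variables
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, anyNA, TRUE)]
    vars <- setdiff(vars, c(passive_cols, config$id_cols))
  }
  full_miss <- vars[vapply(data[vars], function(v) all(is.na(v)), TRUE)]
  if (length(full_miss))
    stop(sprintf("variable(s) 100%% missing: %s", paste(full_miss, collapse = ", ")))
  preds <- config$predictors
  if (is.null(preds)) preds <- setdiff(names(data), c(config$id_cols, passive_cols))
  miss_frac <- vapply(data[vars], function(v) mean(is.na(v)), 0)
  visit <- vars[order(miss_frac)]
  pattern <- is.na(data[, vars, drop = FALSE])

  # fixed one-hot encoding for factor/character predictors
  encode <- function(df) {
    mats <- lapply(preds, function(nm) {
      v <- df[[nm]]
      if (is.character(v) || is.factor(v)) {
        f <- factor(v)
        if (nlevels(f) < 2L) return(NULL)
        m <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(m) <- paste0(nm, seq_len(ncol(m)))
        m
      } else matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, nm))
    })
    do.call(cbind, mats[!vapply(mats, is.null, TRUE)])
  }

  out <- vector("list", config$m)
  for (d in seq_len(config$m)) {
    cur <- data
    for (v in visit) { # initial fill: random draws from the observed values
      na <- is.na(cur[[v]])
      cur[[v]][na] <- sample(cur[[v]][!na], sum(na), replace = TRUE)
    }
    for (cyc in seq_len(config$n_cycles)) {
      for (v in visit) {
        y <- cur[[v]]
        y[pattern[, v]] <- NA
        Xall <- encode(cur)
        Xall <- Xall[, colnames(Xall) != v, drop = FALSE]
        cur[[v]] <- pmm_impute_column(y, Xall, knn = config$knn)
      }
    }
    for (tot in passive_cols)
      cur[[tot]] <- rowSums(cur[, config$passive[[tot]], drop = FALSE])
    out[[d]] <- cur
  }
  structure(list(datasets = out, missing_pattern = pattern, config = config),
            class = "completed_data")
}

#' @export
print.completed_data <- function(x, ...) {
  cat(sprintf("Multiply imputed data: m = %d datasets, %d rows\n",
              length(x$datasets), nrow(x$datasets[[1]])))
  fr <- colMeans(x$missing_pattern)
  cat(sprintf("  imputed: %s\n",
              paste(sprintf("%s (%.0f%%)", colnames(x$missing_pattern), 100 * fr),
                    collapse = ", ")))
  invisible(x)
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' The pooled estimate is the arithmetic mean of the per-dataset estimates;
#' the total variance is the within-imputation mean plus the
#' between-imputation variance inflated by `(1 + 1/m)`. Degrees of freedom
#' use the Barnard-Rubin small-sample adjustment when a finite complete-data
#' df is supplied (with `dfcom = Inf` they reduce to the classical large-
#' sample value).
#'
#' @param estimates m x k matrix (or length-m vector) of per-dataset
#'   estimates.
#' @param variances m x k matrix (or vector) of their squared standard
#'   errors.
#' @param dfcom complete-data residual degrees of freedom (default `Inf`).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return data.frame with one row per coefficient: `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p`, `df`, within (`W`), between (`B`) and total
#'   (`T`) variance, relative increase in variance (`riv`) and fraction of
#'   missing information (`fmi`).
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf, conf_level = 0.95) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, ncol = 1)
  if (is.null(dim(variances))) variances <- matrix(variances, ncol = 1)
  m <- nrow(estimates)
  if (m < 2L) stop("need estimates from at least 2 imputed datasets")
  stopifnot(identical(dim(estimates), dim(variances)))
  qbar <- colMeans(estimates)
  wbar <- colMeans(variances)
  b <- apply(estimates, 2, stats::var)
  tvar <- wbar + (1 + 1 / m) * b
  riv <- (1 + 1 / m) * b / wbar
  lambda <- (1 + 1 / m) * b / tvar
  df_old <- ifelse(b > 0, (m - 1) * (1 + 1 / riv)^2, Inf)
  if (is.finite(dfcom)) {
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- 1 / (1 / df_old + 1 / df_obs)
  } else df <- df_old
  se <- sqrt(tvar)
  tstat <- ifelse(se > 0, qbar / se, Inf * sign(qbar))
  crit <- stats::qt(1 - (1 - conf_level) / 2, df)
  nm <- colnames(estimates)
  data.frame(term = if (is.null(nm)) paste0("b", seq_along(qbar)) else nm,
             estimate = qbar, se = se,
             ci_low = qbar - crit * se, ci_high = qbar + crit * se,
             p = 2 * stats::pt(-abs(tstat), df),
             df = df, W = wbar, B = b, T = tvar, riv = riv, fmi = lambda,
             row.names = NULL)
}

#' Prorated questionnaire summary score
#'
#' A summary score is computed as `mean(observed items) * n_items` when at
#' least `min_frac` of the items are observed, and is missing otherwise.
#'
#' @param items numeric vector of item responses (with `NA` for unanswered
#'   items) or a matrix with one respondent per row.
#' @param n_items nominal number of items on the scale (default: the length
#'   of `items` / number of columns).
#' @param min_frac minimum observed fraction required (default 0.8).
#' @return the prorated score (or `NA`), one per respondent.
#' @export
prorate_score <- function(items, n_items = NULL, min_frac = 0.8) {
  if (is.matrix(items) || is.data.frame(items)) {
    items <- as.matrix(items)
    if (is.null(n_items)) n_items <- ncol(items)
    return(apply(items, 1, prorate_score, n_items = n_items, min_frac = min_frac))
  }
  if (is.null(n_items)) n_items <- length(items)
  if (n_items < 1L) stop("n_items must be >= 1")
  n_obs <- sum(!is.na(items))
  if (n_obs / n_items >= min_frac) mean(items, na.rm = TRUE) * n_items
  else NA_real_
}
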