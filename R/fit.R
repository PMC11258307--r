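#' Standardize an outcome column
#'
#' Centers and scales to mean zero, SD one over the chosen reference values.
#' In the analysis pipeline the reference is the observed (pre-imputation)
#' outcome values of the analytic sample, and the same center/scale is
#' applied identically across imputed datasets so the estimand does not
#' drift between them.
#'
#' @param x numeric vector to standardize.
#' @param center,scale optional fixed center and scale; by default the mean
#'   and sample SD of the non-missing values of `x`.
#' @return standardized vector with attributes `center` and `scale`.
#' @export
standardize_outcome <- function(x, center = NULL, scale = NULL) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2L) stop("need at least 2 non-missing values")
  if (is.null(center)) center <- mean(obs)
  if (is.null(scale)) scale <- stats::sd(obs)
  if (scale == 0) stop("constant outcome column cannot be standardized")
  structure((x - center) / scale, center = center, scale = scale)
}

# Drop aliased (rank-deficient) columns of a design matrix, with a warning.
# The first column (intercept) is always kept.
drop_aliased <- function(X) {
  q <- qr(X)
  if (q$rank == ncol(X)) return(X)
  keep <- sort(q$pivot[seq_len(q$rank)])
  warning(sprintf("dropping %d collinear column(s): %s", ncol(X) - q$rank,
                  paste(colnames(X)[-keep], collapse = ", ")))
  X[, keep, drop = FALSE]
}

# Cluster-robust sandwich for scores X * u with the finite-sample factor
# (G/(G-1)) * ((N-1)/(N-k)); bread_inv = (A)^{-1} for A = X'X (or Xhat'Xhat).
cluster_sandwich <- function(bread_inv, X, u, cluster, k) {
  S <- rowsum(X * u, cluster)
  G <- nrow(S); n <- nrow(X)
  if (G < 2L) stop("need at least 2 clusters for cluster-robust inference")
  adj <- (G / (G - 1)) * ((n - 1) / (n - k))
  V <- bread_inv %*% crossprod(S) %*% bread_inv * adj
  list(vcov = V, n_clusters = G)
}

make_fit_result <- function(beta, V, n, n_clusters, method,
                            diagnostics = NULL, conf_level = 0.95) {
  se <- sqrt(pmax(diag(V), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(term = names(beta), estimate = unname(beta), se = se,
                      ci_low = unname(beta) - z * se,
                      ci_high = unname(beta) + z * se,
                      p = 2 * stats::pnorm(-abs(unname(beta) / ifelse(se > 0, se, Inf))),
                      row.names = NULL)
  structure(list(coefficients = coefs, vcov = V, n = n,
                 n_clusters = n_clusters, method = method,
                 diagnostics = diagnostics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, digits = 4, max_terms = 8L, ...) {
  cat(sprintf("%s fit: n = %d, clusters = %d\n", x$method, x$n, x$n_clusters))
  co <- x$coefficients
  extra <- nrow(co) - max_terms
  if (extra > 0) co <- co[seq_len(max_terms), , drop = FALSE]
  print(format(co, digits = digits), row.names = FALSE)
  if (extra > 0) cat(sprintf("  ... and %d more covariate terms\n", extra))
  if (!is.null(x$diagnostics)) {
    cat("Instrument diagnostics:\n")
    print(format(x$diagnostics, digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Least squares with cluster-robust standard errors
#'
#' Ordinary least squares with a clustered sandwich variance using the
#' finite-sample factor `(G/(G-1)) * ((N-1)/(N-k))`. With every observation
#' its own cluster this reproduces HC1 heteroskedasticity-robust standard
#' errors. Collinear columns (e.g. redundant batch dummies) are dropped with
#' a warning.
#'
#' @param y outcome vector.
#' @param X design matrix (an intercept column is prepended unless
#'   `add_intercept = FALSE`).
#' @param cluster cluster identifier, one per row (e.g. genetic family id).
#' @param add_intercept prepend an intercept column (default `TRUE`).
#' @return a `fit_result` with the coefficient table, sandwich `vcov`, `n`
#'   and `n_clusters`.
#' @export
fit_ols_cluster <- function(y, X, cluster, add_intercept = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  X <- drop_aliased(X)
  k <- ncol(X)
  qx <- qr(X)
  if (qx$rank < k) stop("design matrix rank-deficient after aliasing pass")
  beta <- qr.coef(qx, y)
  u <- drop(y - X %*% beta)
  Rinv <- backsolve(qr.R(qx), diag(k))
  XtXi <- Rinv %*% t(Rinv)
  XtXi <- XtXi[order(qx$pivot), order(qx$pivot), drop = FALSE]
  sw <- cluster_sandwich(XtXi, X, u, cluster, k)
  make_fit_result(beta, sw$vcov, length(y), sw$n_clusters, "OLS (cluster-robust)")
}

#' Two-stage least squares with cluster-robust standard errors
#'
#' Endogenous regressors are projected on the full instrument set
#' (excluded instruments plus exogenous covariates); the second stage
#' regresses the outcome on the projected endogenous regressors and the
#' exogenous covariates. Standard errors use the clustered sandwich with
#' *structural* residuals `y - X beta` (the original, not projected,
#' endogenous regressors), the variance that is consistent for 2SLS.
#'
#' @param y outcome vector.
#' @param X_endog matrix of endogenous regressors (e.g. mother's and
#'   father's years of education).
#' @param Z matrix of excluded instruments (e.g. the parental polygenic
#'   indexes); at least as many columns as `X_endog`.
#' @param X_exog optional matrix of exogenous covariates (the within-family
#'   variant adds the child's own polygenic index here).
#' @param cluster cluster identifier per row.
#' @param diagnostics if `TRUE`, attach [first_stage_diagnostics()].
#' @return a `fit_result`; endogenous terms come first in the coefficient
#'   table.
#' @export
fit_2sls_cluster <- function(y, X_endog, Z, X_exog = NULL, cluster,
                             diagnostics = FALSE) {
  X_endog <- as.matrix(X_endog)
  Z <- as.matrix(Z)
  if (is.null(colnames(X_endog))) colnames(X_endog) <- paste0("endog", seq_len(ncol(X_endog)))
  if (ncol(Z) < ncol(X_endog))
    stop("under-identified: fewer instruments than endogenous regressors")
  W <- cbind(`(Intercept)` = rep(1, length(y)),
             if (!is.null(X_exog)) as.matrix(X_exog))
  W <- drop_aliased(W)
  Zfull <- cbind(Z, W)
  qz <- qr(Zfull)
  if (qz$rank < ncol(X_endog) + ncol(W)) stop("first-stage rank failure")
  Xhat_end <- qr.fitted(qz, X_endog)
  Xhat <- cbind(Xhat_end, W)
  Xfull <- cbind(X_endog, W)
  qh <- qr(Xhat)
  if (qh$rank < ncol(Xhat)) stop("projected design rank-deficient")
  beta <- qr.coef(qh, y)
  names(beta) <- colnames(Xfull)
  u <- drop(y - Xfull %*% beta) # structural residuals
  k <- ncol(Xhat)
  Rinv <- backsolve(qr.R(qh), diag(k))
  Ainv <- Rinv %*% t(Rinv)
  Ainv <- Ainv[order(qh$pivot), order(qh$pivot), drop = FALSE]
  sw <- cluster_sandwich(Ainv, Xhat, u, cluster, k)
  diag_tab <- if (diagnostics)
    first_stage_diagnostics(X_endog, Z, W[, -1, drop = FALSE], cluster) else NULL
  make_fit_result(beta, sw$vcov, length(y), sw$n_clusters, "2SLS (cluster-robust)",
                  diagnostics = diag_tab)
}

r2_of <- function(y, X) {
  if (is.null(X) || ncol(X) == 0) X <- matrix(1, length(y), 1)
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' First-stage instrument-strength diagnostics
#'
#' For each endogenous regressor reports, from its first-stage regression on
#' all excluded instruments plus exogenous covariates:
#' \itemize{
#'   \item `F`: the classical excluded-instrument F statistic,
#'     `((R2_full - R2_reduced)/q) / ((1 - R2_full)/(n - k))`;
#'   \item `F_conditional`: a Sanderson-Windmeijer-style conditional F that
#'     first partials out the other endogenous regressors via 2SLS, then
#'     tests the instruments on the residual, scaled by `q/(q - m + 1)`;
#'   \item `partial_r2`: the squared partial correlation of the regressor's
#'     own instrument given the exogenous covariates,
#'     `(R2_own - R2_reduced)/(1 - R2_reduced)`.
#' }
#' Own instruments are matched to endogenous regressors by column position.
#'
#' @param X_endog matrix of endogenous regressors.
#' @param Z matrix of excluded instruments.
#' @param X_exog exogenous covariate matrix (may be `NULL`).
#' @param cluster cluster id per row (kept for interface symmetry; the
#'   classical statistics reported here do not use it).
#' @return data.frame with one row per endogenous regressor.
#' @export
first_stage_diagnostics <- function(X_endog, Z, X_exog = NULL, cluster = NULL) {
  X_endog <- as.matrix(X_endog); Z <- as.matrix(Z)
  if (is.null(colnames(X_endog))) colnames(X_endog) <- paste0("endog", seq_len(ncol(X_endog)))
  W <- if (!is.null(X_exog) && ncol(as.matrix(X_exog)) > 0) as.matrix(X_exog) else NULL
  n <- nrow(X_endog)
  q <- ncol(Z)
  m_end <- ncol(X_endog)
  k_full <- 1L + q + (if (is.null(W)) 0L else ncol(W))
  res <- lapply(seq_len(m_end), function(j) {
    xj <- X_endog[, j]
    r2_full <- r2_of(xj, cbind(Z, W))
    r2_red <- r2_of(xj, W)
    f_plain <- ((r2_full - r2_red) / q) / ((1 - r2_full) / (n - k_full))
    zj <- Z[, min(j, q)]
    r2_own <- r2_of(xj, cbind(zj, W))
    partial_r2 <- (r2_own - r2_red) / (1 - r2_red)
    if (m_end > 1L) {
      others <- X_endog[, -j, drop = FALSE]
      iv <- fit_2sls_cluster(xj, others, Z, W,
                             cluster = if (is.null(cluster)) seq_len(n) else cluster)
      co <- iv$coefficients
      e <- xj - cbind(others, 1, W) %*%
        co$estimate[match(c(colnames(others), "(Intercept)",
                            colnames(W)), co$term)]
      e <- drop(e)
      r2e_full <- r2_of(e, cbind(Z, W))
      r2e_red <- r2_of(e, W)
      f_base <- ((r2e_full - r2e_red) / q) / ((1 - r2e_full) / (n - k_full))
      f_cond <- f_base * q / (q - m_end + 1)
    } else f_cond <- f_plain
    data.frame(term = colnames(X_endog)[j], F = f_plain,
               F_conditional = f_cond, partial_r2 = partial_r2)
  })
  do.call(rbind, res)
}

#' Standard covariate matrix for the trio models
#'
#' Builds the covariate block shared by all model specifications: child sex,
#' birth year, genotyping batch dummies (first level as reference), and the
#' 20 ancestry principal components per trio member; with
#' `confounders = TRUE` it appends the measured confounders (parental
#' depressive/anxiety and ADHD trait scores, parental smoking dummies,
#' parity).
#'
#' @param pheno phenotype data.frame from a `trio_cohort`.
#' @param confounders append the measured-confounder block (default
#'   `FALSE`).
#' @return numeric matrix with one row per trio (no intercept column).
#' @export
spec_covariates <- function(pheno, confounders = FALSE) {
  parts <- list(child_sex = pheno$child_sex, birth_year = pheno$birth_year)
  for (nm in c("batch_centre", "batch_chip")) {
    f <- factor(pheno[[nm]])
    if (nlevels(f) > 1L) {
      m <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, "_", levels(f)[-1])
      parts[[nm]] <- m
    }
  }
  pcs <- grep("^pc\\d+_", names(pheno), value = TRUE)
  if (length(pcs)) parts$pcs <- as.matrix(pheno[, pcs])
  if (confounders) {
    parts$traits <- as.matrix(pheno[, c("trait_depanx_mother", "trait_depanx_father",
                                        "trait_adhd_mother", "trait_adhd_father")])
    for (nm in c("smoking_mother", "smoking_father")) {
      f <- factor(pheno[[nm]])
      if (nlevels(f) > 1L) {
        m <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(m) <- paste0(nm, "_", levels(f)[-1])
        parts[[nm]] <- m
      }
    }
    parts$parity <- pheno$parity
  }
  mats <- lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    if (is.matrix(p)) p else matrix(p, ncol = 1, dimnames = list(NULL, nm))
  })
  do.call(cbind, mats)
}

#' Fit one of the four model specifications
#'
#' The four specifications mirror the analysis ladder for parental education
#' and child outcomes:
#' \describe{
#'   \item{`ols_minimal`}{outcome on both parents' years of education,
#'     adjusting for child sex, birth year, genotyping batch dummies, and
#'     20 ancestry PCs per trio member.}
#'   \item{`ols_adjusted`}{adds the measured confounders: parental
#'     depressive/anxiety and ADHD trait scores, parental smoking, parity.}
#'   \item{`mr`}{two-stage least squares with both parents' education
#'     instrumented by their own polygenic indexes; the child's index is
#'     excluded.}
#'   \item{`wfmr`}{the within-family variant: as `mr` plus the child's own
#'     standardized polygenic index as a covariate, which blocks the direct
#'     genetic transmission path.}
#' }
#' The outcome is standardized using the observed-data mean/SD (of the first
#' dataset's non-missing values by default), applied identically across
#' imputed datasets; estimates are in outcome SD units per year of education
#' (and per index SD for the child-index term). With a list of imputed
#' datasets the per-dataset fits are pooled by [pool_rubin()].
#'
#' @param data a phenotype data.frame, or a list of completed data.frames
#'   from [chained_impute()] (a `completed_data` object is accepted).
#' @param scores polygenic index table from [score_cohort()].
#' @param spec one of `"ols_minimal"`, `"ols_adjusted"`, `"mr"`, `"wfmr"`.
#' @param outcome name of the outcome column.
#' @param per_parent for the MR specs: instrument one parent at a time with
#'   the other parent's index entering as an exogenous covariate, instead of
#'   instrumenting both educations jointly (default `FALSE`, the joint
#'   reading).
#' @param sqrt_transform square-root transform the outcome before
#'   standardizing (outcome must be non-negative).
#' @param subset_sex restrict to children of one sex (value of `child_sex`),
#'   for sex-stratified sensitivity runs.
#' @param outcome_ref optional numeric vector whose non-missing values fix
#'   the standardization center/scale (e.g. the pre-imputation outcome).
#' @param diagnostics attach first-stage diagnostics for the MR specs
#'   (default `TRUE`).
#' @return a `fit_result` (single dataset) or a `pooled_fit` (list with the
#'   Rubin-pooled coefficient table, per-dataset results and diagnostics).
#' @export
run_spec <- function(data, scores,
                     spec = c("ols_minimal", "ols_adjusted", "mr", "wfmr"),
                     outcome = "smfq", per_parent = FALSE,
                     sqrt_transform = FALSE, subset_sex = NULL,
                     outcome_ref = NULL, diagnostics = TRUE) {
  spec <- match.arg(spec)
  if (inherits(data, "completed_data")) data <- data$datasets
  datasets <- if (is.data.frame(data)) list(data) else data
  need <- c(outcome, "edu_mother", "edu_father", "child_sex", "birth_year",
            "family_id")
  miss <- setdiff(need, names(datasets[[1]]))
  if (length(miss)) stop(sprintf("missing required column(s): %s",
                                 paste(miss, collapse = ", ")))

  if (is.null(outcome_ref)) outcome_ref <- datasets[[1]][[outcome]]
  if (sqrt_transform) {
    if (any(outcome_ref < 0, na.rm = TRUE))
      stop("sqrt transform needs a non-negative outcome")
    outcome_ref <- sqrt(outcome_ref)
  }
  ref <- standardize_outcome(outcome_ref)
  center <- attr(ref, "center"); scale <- attr(ref, "scale")

  fit_one <- function(df) {
    sc <- scores[match(df$family_id, scores$family_id), ]
    if (!is.null(subset_sex)) {
      keep <- df$child_sex == subset_sex
      df <- df[keep, , drop = FALSE]; sc <- sc[keep, , drop = FALSE]
    }
    y <- df[[outcome]]
    if (sqrt_transform) y <- sqrt(y)
    keep <- !is.na(y)
    df <- df[keep, , drop = FALSE]; sc <- sc[keep, , drop = FALSE]
    y <- standardize_outcome(y[keep], center = center, scale = scale)
    cl <- df$family_id
    covs <- spec_covariates(df, confounders = (spec == "ols_adjusted"))
    if (!is.null(subset_sex)) # sex is constant within a stratum
      covs <- covs[, colnames(covs) != "child_sex", drop = FALSE]
    edu <- cbind(edu_mother = df$edu_mother, edu_father = df$edu_father)
    if (spec %in% c("ols_minimal", "ols_adjusted")) {
      fit <- fit_ols_cluster(y, cbind(edu, covs), cl)
    } else {
      child_cov <- if (spec == "wfmr") cbind(pgi_child = sc$pgi_child) else NULL
      if (!per_parent) {
        Z <- cbind(pgi_mother = sc$pgi_mother, pgi_father = sc$pgi_father)
        fit <- fit_2sls_cluster(y, edu, Z, cbind(child_cov, covs), cl,
                                diagnostics = diagnostics)
      } else {
        fits <- lapply(c("mother", "father"), function(parent) {
          other <- setdiff(c("mother", "father"), parent)
          fit_2sls_cluster(
            y, edu[, paste0("edu_", parent), drop = FALSE],
            cbind(sc[[paste0("pgi_", parent)]]),
            cbind(stats::setNames(data.frame(sc[[paste0("pgi_", other)]]),
                                  paste0("pgi_", other)),
                  child_cov, covs),
            cl, diagnostics = diagnostics)
        })
        coefs <- rbind(fits[[1]]$coefficients[1, ], fits[[2]]$coefficients[1, ])
        fit <- structure(list(coefficients = coefs,
                              vcov = diag(coefs$se^2),
                              n = fits[[1]]$n, n_clusters = fits[[1]]$n_clusters,
                              method = "2SLS per-parent (cluster-robust)",
                              diagnostics = do.call(rbind, lapply(fits, `[[`, "diagnostics"))),
                         class = "fit_result")
      }
    }
    fit
  }

  fits <- lapply(datasets, fit_one)
  if (length(fits) == 1L) return(fits[[1]])
  terms <- fits[[1]]$coefficients$term
  est <- t(vapply(fits, function(f) f$coefficients$estimate, numeric(length(terms))))
  vr <- t(vapply(fits, function(f) f$coefficients$se^2, numeric(length(terms))))
  colnames(est) <- colnames(vr) <- terms
  dfcom <- fits[[1]]$n - length(terms)
  pooled <- pool_rubin(est, vr, dfcom = dfcom)
  structure(list(coefficients = pooled, fits = fits, m = length(fits),
                 n = fits[[1]]$n, n_clusters = fits[[1]]$n_clusters,
                 method = paste0(fits[[1]]$method, ", pooled over m = ",
                                 length(fits)),
                 diagnostics = fits[[1]]$diagnostics),
            class = c("pooled_fit", "fit_result"))
}
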