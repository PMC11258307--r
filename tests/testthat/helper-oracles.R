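# Independent reference implementations used as oracles. These are written
# deliberately naively (explicit loops, dense algebra) and share no code
# with the package internals they check.

# Greedy clumping, re-implemented from the definition: smallest p first,
# claim same-chromosome in-window variants with r2 >= threshold.
reference_clump <- function(sumstats, ld, p_threshold, r2_threshold, window_kb) {
  df <- sumstats[sumstats$pvalue < p_threshold, , drop = FALSE]
  df <- df[order(df$pvalue, df$chromosome, df$position), , drop = FALSE]
  kept <- character()
  while (nrow(df) > 0L) {
    top <- df[1L, ]
    kept <- c(kept, top$id)
    df <- df[-1L, , drop = FALSE]
    if (nrow(df) == 0L) break
    claim <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (df$chromosome[i] != top$chromosome) next
      if (abs(df$position[i] - top$position) > window_kb * 1000) next
      r2 <- 0
      if (!is.null(ld) && top$id %in% rownames(ld) && df$id[i] %in% colnames(ld)) {
        v <- ld[top$id, df$id[i]]
        if (!is.na(v)) r2 <- v
      }
      claim[i] <- r2 >= r2_threshold
    }
    df <- df[!claim, , drop = FALSE]
  }
  kept
}

# Clustered sandwich for OLS assembled score-by-score with explicit loops.
brute_ols_cluster <- function(y, X, cluster) {
  X <- cbind(1, X)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  u <- drop(y - X %*% beta)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    sg <- t(X[idx, , drop = FALSE]) %*% u[idx]
    meat <- meat + sg %*% t(sg)
  }
  n <- length(y); k <- ncol(X); G <- length(unique(cluster))
  bread <- solve(t(X) %*% X)
  V <- bread %*% meat %*% bread * (G / (G - 1)) * ((n - 1) / (n - k))
  list(beta = drop(beta), vcov = V)
}

# 2SLS with explicit projection matrix and structural-residual sandwich.
brute_2sls_cluster <- function(y, Xend, Z, Xexog, cluster) {
  W <- cbind(1, Xexog)
  Zf <- cbind(Z, W)
  P <- Zf %*% solve(t(Zf) %*% Zf) %*% t(Zf)
  X <- cbind(Xend, W)
  beta <- solve(t(X) %*% P %*% X, t(X) %*% P %*% y)
  u <- drop(y - X %*% beta)        # structural residuals
  Xh <- P %*% X
  A <- solve(t(Xh) %*% Xh)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    sg <- t(Xh[idx, , drop = FALSE]) %*% u[idx]
    meat <- meat + sg %*% t(sg)
  }
  n <- length(y); k <- ncol(X); G <- length(unique(cluster))
  V <- A %*% meat %*% A * (G / (G - 1)) * ((n - 1) / (n - k))
  list(beta = drop(beta), vcov = V)
}

# Cohort configured for estimator-recovery work: independent loci,
# continuous (latent-scale) outcomes, no missingness.
recovery_config <- function(n_families, n_snps, seed, ...) {
  args <- list(n_families = n_families, n_snps = n_snps, seed = seed,
               ld_adjacent_corr = 0, discretize = FALSE,
               missing_rate_outcome = 0)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# Haplotype pair fixture where every person is homozygous for the given
# dosage at a single locus.
homozygote_parent <- function(n, dosage) {
  a <- matrix(as.integer(dosage >= 1), n, 1)
  b <- matrix(as.integer(dosage == 2), n, 1)
  list(h1 = a, h2 = b)
}
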