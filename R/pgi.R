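#' Harmonize GWAS summary statistics against a genotype panel
#'
#' Aligns published effects to the alleles the dosages count. Variants absent
#' from the genotype panel are dropped; where the dosage-coded allele equals
#' the summary-statistics other allele, the beta sign is flipped and the
#' alleles (and effect-allele frequency) swapped; strand flips are resolved
#' via base complements; strand-ambiguous variants (A/T or C/G) with effect
#' allele frequency in `[0.4, 0.6]` are dropped; irreconcilable allele pairs
#' are dropped with a logged reason rather than raising an error.
#'
#' @param sumstats summary-statistics data.frame with columns `id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `eaf`.
#' @param panel genotype variant table with columns `id`, `allele_coded`,
#'   `allele_other`.
#' @return list with the harmonized `sumstats` (betas oriented to the coded
#'   allele) and an exclusion `log` data.frame (`id`, `reason`).
#' @export
harmonize_alleles <- function(sumstats, panel) {
  stopifnot(all(c("id", "effect_allele", "other_allele", "beta") %in% names(sumstats)),
            all(c("id", "allele_coded", "allele_other") %in% names(panel)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  idx <- match(sumstats$id, panel$id)
  log <- list()
  drop <- is.na(idx)
  if (any(drop)) log$absent <- data.frame(id = sumstats$id[drop],
                                          reason = "absent_from_panel")
  ss <- sumstats[!drop, , drop = FALSE]
  pn <- panel[idx[!drop], , drop = FALSE]

  ambiguous <- ss$effect_allele == comp[ss$other_allele] &
    !is.na(ss$eaf) & ss$eaf >= 0.4 & ss$eaf <= 0.6
  ambiguous[is.na(ambiguous)] <- FALSE
  if (any(ambiguous)) log$ambiguous <- data.frame(id = ss$id[ambiguous],
                                                  reason = "strand_ambiguous")
  ss <- ss[!ambiguous, , drop = FALSE]
  pn <- pn[!ambiguous, , drop = FALSE]

  same <- ss$effect_allele == pn$allele_coded & ss$other_allele == pn$allele_other
  flip <- ss$effect_allele == pn$allele_other & ss$other_allele == pn$allele_coded
  strand_same <- comp[ss$effect_allele] == pn$allele_coded &
    comp[ss$other_allele] == pn$allele_other
  strand_flip <- comp[ss$effect_allele] == pn$allele_other &
    comp[ss$other_allele] == pn$allele_coded
  strand_same[is.na(strand_same)] <- FALSE # non-SNV alleles have no complement
  strand_flip[is.na(strand_flip)] <- FALSE
  same <- same | (!same & !flip & strand_same)
  flip <- flip | (!same & !flip & strand_flip)
  bad <- !(same | flip)
  if (any(bad)) log$irreconcilable <- data.frame(id = ss$id[bad],
                                                 reason = "allele_mismatch")
  ss <- ss[!bad, , drop = FALSE]
  flip <- flip[!bad]
  if (any(flip)) {
    ea <- ss$effect_allele[flip]
    ss$effect_allele[flip] <- ss$other_allele[flip]
    ss$other_allele[flip] <- ea
    ss$beta[flip] <- -ss$beta[flip]
    if (!is.null(ss$eaf)) ss$eaf[flip] <- 1 - ss$eaf[flip]
  }
  rownames(ss) <- NULL
  list(sumstats = ss,
       log = if (length(log)) do.call(rbind, unname(log))
             else data.frame(id = character(), reason = character()))
}

#' Pairwise LD (r-squared) from dosages
#'
#' Squared Pearson correlation between dosage columns, the form of LD
#' reference the clumping routines consume.
#'
#' @param dosages numeric matrix, persons x variants, with variant ids as
#'   column names.
#' @return square symmetric matrix of r-squared values with variant-id
#'   dimnames; monomorphic variants get `NA` rows/columns.
#' @export
ld_from_dosages <- function(dosages) {
  r <- suppressWarnings(stats::cor(dosages))
  r * r
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unclaimed variant passing the p-value
#' threshold as an index variant, then removes all unclaimed variants on the
#' same chromosome within the window (base-pair distance `<=
#' window_kb * 1000`, symmetric and inclusive at the boundary) whose LD with
#' the index is `r2 >= r2_threshold`. Ties on p-value are broken by
#' (chromosome, position) ascending. The p threshold is applied as a strict
#' `<`.
#'
#' @param sumstats harmonized summary statistics (`id`, `chromosome`,
#'   `position`, `pvalue`).
#' @param ld square r-squared matrix with variant-id dimnames (see
#'   [ld_from_dosages()]), or `NULL` for no-LD clumping.
#' @param p_threshold genome-wide significance threshold (default `5e-8`).
#' @param r2_threshold LD threshold at or above which a variant is claimed
#'   by an index (default `0.01`).
#' @param window_kb window half-width in kilobases (default `10000`).
#' @param missing_ld how to treat an absent LD entry for an in-window pair:
#'   `"zero"` (assume independence, warn once) or `"error"`.
#' @return object of class `clump_result`: list with `retained` (ids in
#'   selection order), `params`, and a `dropped` data.frame (`id`, `reason`,
#'   `index`).
#' @export
clump_variants <- function(sumstats, ld = NULL, p_threshold = 5e-8,
                           r2_threshold = 0.01, window_kb = 10000,
                           missing_ld = c("zero", "error")) {
  missing_ld <- match.arg(missing_ld)
  stopifnot(p_threshold > 0, r2_threshold >= 0, window_kb >= 0)
  ss <- sumstats[order(sumstats$pvalue, sumstats$chromosome, sumstats$position), ,
                 drop = FALSE]
  ss <- ss[ss$pvalue < p_threshold, , drop = FALSE]
  below <- setdiff(sumstats$id, ss$id)
  dropped <- if (length(below))
    data.frame(id = below, reason = "p_threshold", index = NA_character_)
  else data.frame(id = character(), reason = character(), index = character())

  retained <- character()
  claimed <- rep(FALSE, nrow(ss))
  warned <- FALSE
  for (i in seq_len(nrow(ss))) {
    if (claimed[i]) next
    idx_id <- ss$id[i]
    retained <- c(retained, idx_id)
    claimed[i] <- TRUE
    in_win <- !claimed & ss$chromosome == ss$chromosome[i] &
      abs(ss$position - ss$position[i]) <= window_kb * 1000
    if (!any(in_win)) next
    cand <- which(in_win)
    r2 <- rep(NA_real_, length(cand))
    if (!is.null(ld) && idx_id %in% rownames(ld)) {
      hit <- match(ss$id[cand], colnames(ld))
      r2[!is.na(hit)] <- ld[idx_id, hit[!is.na(hit)]]
    }
    if (anyNA(r2)) {
      if (missing_ld == "error") stop(sprintf(
        "missing LD entry for in-window pair with index %s", idx_id))
      if (!warned && !is.null(ld)) {
        warning("missing LD entries treated as r2 = 0")
        warned <- TRUE
      }
      r2[is.na(r2)] <- 0
    }
    kill <- cand[r2 >= r2_threshold]
    if (length(kill)) {
      dropped <- rbind(dropped, data.frame(id = ss$id[kill],
                                           reason = "ld_with_index",
                                           index = idx_id))
      claimed[kill] <- TRUE
    }
  }
  structure(list(retained = retained,
                 params = list(p_threshold = p_threshold,
                               r2_threshold = r2_threshold,
                               window_kb = window_kb),
                 dropped = dropped),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("LD clump: %d retained, %d dropped (p < %g, r2 < %g, window %g kb)\n",
              length(x$retained), nrow(x$dropped), x$params$p_threshold,
              x$params$r2_threshold, x$params$window_kb))
  invisible(x)
}

#' Stringently clumped variant subset
#'
#' [clump_variants()] at `r2_threshold = 0.001`, the stricter independence
#' threshold used to guard summary-data MR against residual LD between
#' instruments. When run on an already-clumped panel the result is a subset
#' of it by construction.
#'
#' @inheritParams clump_variants
#' @return a `clump_result`.
#' @export
clump_strict <- function(sumstats, ld = NULL, p_threshold = 5e-8,
                         window_kb = 10000, missing_ld = c("zero", "error")) {
  clump_variants(sumstats, ld, p_threshold = p_threshold,
                 r2_threshold = 0.001, window_kb = window_kb,
                 missing_ld = missing_ld)
}

#' Raw polygenic scores from dosages and weights
#'
#' The raw score is the weighted allele count `sum_j beta_j * dosage_j` over
#' the retained variants. Every retained variant must be present in the
#' dosage matrix (genotypes carry no missingness in the analytic sample).
#'
#' @param dosages persons x variants numeric matrix with variant-id column
#'   names.
#' @param sumstats harmonized summary statistics (provides `id` and `beta`).
#' @param retained character vector of variant ids to score (e.g. the
#'   `retained` element of a `clump_result`); default: all sumstats ids.
#' @return numeric vector of raw scores, one per row of `dosages`.
#' @export
pgi_score <- function(dosages, sumstats, retained = sumstats$id) {
  miss <- setdiff(retained, colnames(dosages))
  if (length(miss)) stop(sprintf("missing dosages for %d retained variant(s): %s",
                                 length(miss), paste(utils::head(miss, 3), collapse = ", ")))
  w <- sumstats$beta[match(retained, sumstats$id)]
  if (anyNA(w)) stop("retained variants absent from summary statistics")
  drop(dosages[, retained, drop = FALSE] %*% w)
}

#' Standardize scores to mean zero, SD one
#'
#' @param x numeric vector with at least two distinct non-missing values.
#' @return standardized vector (same length, `NA`s preserved).
#' @export
standardize_score <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2L || stats::sd(obs) == 0)
    stop("need at least two distinct values to standardize")
  (x - mean(obs)) / stats::sd(obs)
}

#' Polygenic indexes for every member of a trio cohort
#'
#' Scores mother, father, and child dosages with the harmonized weights over
#' the retained variants and standardizes within role (so a unit difference
#' is one within-role SD, the scale effect sizes are reported on), or over
#' the pooled sample.
#'
#' @param cohort a `trio_cohort`.
#' @param sumstats harmonized summary statistics.
#' @param retained variant ids to score (default all sumstats ids).
#' @param by_role standardize within each role separately (default) or over
#'   all persons jointly.
#' @return data.frame with `family_id`, raw scores `raw_mother`/`raw_father`/
#'   `raw_child`, and standardized `pgi_mother`/`pgi_father`/`pgi_child`.
#' @export
score_cohort <- function(cohort, sumstats, retained = sumstats$id,
                         by_role = TRUE) {
  raw <- lapply(cohort$dosages, pgi_score, sumstats = sumstats,
                retained = retained)
  out <- data.frame(family_id = cohort$phenotypes$family_id,
                    raw_mother = raw$mother, raw_father = raw$father,
                    raw_child = raw$child, stringsAsFactors = FALSE)
  if (by_role) {
    out$pgi_mother <- standardize_score(raw$mother)
    out$pgi_father <- standardize_score(raw$father)
    out$pgi_child <- standardize_score(raw$child)
  } else {
    pooled <- standardize_score(c(raw$mother, raw$father, raw$child))
    n <- length(raw$mother)
    out$pgi_mother <- pooled[seq_len(n)]
    out$pgi_father <- pooled[n + seq_len(n)]
    out$pgi_child <- pooled[2 * n + seq_len(n)]
  }
  out
}
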