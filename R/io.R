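#' Read and write the pipeline's tab-separated interchange formats
#'
#' All tables are plain TSV with a header row; missing values are empty
#' fields. Summary statistics use the columns `id`, `chromosome`,
#' `position`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`,
#' `eaf`. Dosage tables are long by person: `person_id`, `family_id`,
#' `role` (mother/father/child), then one column per variant id.
#'
#' @param path file path.
#' @return `read_sumstats()` returns the summary-statistics data.frame after
#'   schema validation; `read_phenotypes()` a phenotype data.frame.
#' @name triomr_io
NULL

sumstat_cols <- c("id", "chromosome", "position", "effect_allele",
                  "other_allele", "beta", "se", "pvalue", "eaf")

#' @rdname triomr_io
#' @export
read_sumstats <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(sumstat_cols, names(ss))
  if (length(miss))
    stop(sprintf("summary statistics missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(ss$id)) stop("duplicate variant ids in summary statistics")
  if (any(ss$se <= 0, na.rm = TRUE)) stop("non-positive standard errors")
  if (any(ss$pvalue <= 0 | ss$pvalue > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  ss
}

#' @rdname triomr_io
#' @param sumstats summary-statistics data.frame.
#' @export
write_sumstats <- function(sumstats, path) {
  utils::write.table(sumstats[, intersect(sumstat_cols, names(sumstats))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname triomr_io
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}

#' @rdname triomr_io
#' @param phenotypes phenotype data.frame (missing written as empty fields).
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname triomr_io
#' @param cohort a `trio_cohort` whose dosages are written long by person.
#' @export
write_dosages <- function(cohort, path) {
  tabs <- lapply(c("mother", "father", "child"), function(role) {
    D <- cohort$dosages[[role]]
    data.frame(person_id = paste0(rownames(D), "_", role),
               family_id = rownames(D), role = role,
               as.data.frame(D, check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname triomr_io
#' @return `read_dosages()` returns a list of per-role dosage matrices
#'   keyed by family id.
#' @export
read_dosages <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("person_id", "family_id", "role") %in% names(tab)))
  vars <- setdiff(names(tab), c("person_id", "family_id", "role"))
  out <- lapply(split(tab, tab$role), function(d) {
    m <- as.matrix(d[, vars, drop = FALSE])
    rownames(m) <- d$family_id
    m
  })
  out[intersect(c("mother", "father", "child"), names(out))]
}
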