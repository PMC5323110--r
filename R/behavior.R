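# Composite neuropsychological scores. Raw test scores are z-scored against
# the pooled mean and SD of ALL subjects (both groups together), and each
# composite is the mean of its three member z-scores: episodic memory (EM)
# from the delayed-recall tests, executive function (EF) from the timed
# tests. EF members are timed, so a higher EF composite means slower,
# worse performance; no sign flipping is applied.

#' Pooled z-score
#'
#' Standardizes against the mean and sample SD (n - 1 denominator) of the
#' whole cohort, pooling both groups.
#'
#' @param raw numeric vector over all subjects
#' @return z-scored vector (pooled mean 0, pooled SD 1)
#' @export
zscore_pooled <- function(raw) {
  s <- stats::sd(raw, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot z-score: pooled SD is zero")
  (raw - mean(raw, na.rm = TRUE)) / s
}

#' Composite score from three member z-scores
#'
#' @param z_members matrix or data frame with one column per member test
#' @return per-subject arithmetic mean; missing members propagate to NA
#' @export
composite <- function(z_members) {
  z_members <- as.matrix(z_members)
  out <- rowMeans(z_members)
  if (anyNA(out))
    message(sum(is.na(out)), " subject(s) with missing member scores; ",
            "composite set to NA")
  out
}

# member tests of each composite
em_members <- c("AVLT_DR", "CFT_DR", "LMT_DR")
ef_members <- c("TMT_A", "TMT_B", "SCWT_C")

#' Add EM and EF composite columns to a phenotype table
#'
#' @param phenotypes data frame with the six raw test columns `AVLT_DR`,
#'   `CFT_DR`, `LMT_DR`, `TMT_A`, `TMT_B`, `SCWT_C`
#' @return the data frame with `EM` and `EF` columns appended
#' @export
add_composites <- function(phenotypes) {
  need <- c(em_members, ef_members)
  missing <- setdiff(need, names(phenotypes))
  if (length(missing))
    stop("phenotype table lacks columns: ", paste(missing, collapse = ", "))
  z <- sapply(need, function(cn) zscore_pooled(phenotypes[[cn]]))
  phenotypes$EM <- composite(z[, em_members])
  phenotypes$EF <- composite(z[, ef_members])
  phenotypes
}
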