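#' Majority consensus of an odd number of binary reads
#'
#' @param reads Numeric/logical vector of 0/1 reads from an odd number of
#'   readers.
#' @return 1 if more than half the reads are positive, else 0; `NA` if any
#'   read is missing.
#' @export
majority_read <- function(reads) {
  if (length(reads) %% 2 == 0) {
    stop("majority read requires an odd number of readers")
  }
  if (any(is.na(reads))) return(NA_real_)
  as.numeric(sum(reads) > length(reads) / 2)
}

#' Consensus visual read per subject
#'
#' Applies [majority_read()] across the `read_k` columns of a cohort table.
#'
#' @param cohort Cohort table (baseline rows) with `read_1` ... `read_k`.
#' @return Numeric vector of consensus reads (1 positive, 0 negative, `NA`
#'   where reads are missing).
#' @export
consensus_reads <- function(cohort) {
  rc <- read_column_names(cohort)
  if (length(rc) == 0) stop("no read_<k> columns in the cohort")
  apply(as.matrix(cohort[, rc, drop = FALSE]), 1, majority_read)
}

#' Fraction of consensus-positive reads per amyloid category
#'
#' @param cohort Cohort table with read columns at baseline.
#' @param statuses Per-subject amyloid category aligned with (or named by)
#'   the baseline subjects.
#' @return Data frame `category`, `n`, `n_positive`, `fraction_positive`
#'   (`NA` for empty categories).
#' @export
positivity_by_category <- function(cohort, statuses) {
  b <- baseline_rows(cohort)
  cons <- consensus_reads(b)
  if (!is.null(names(statuses))) statuses <- statuses[b$subject_id]
  stopifnot(length(statuses) == nrow(b))
  keep <- !is.na(cons)
  st <- factor(statuses[keep], amyloid_levels())
  cons <- cons[keep]
  n <- tapply(cons, st, length, default = 0L)
  k <- tapply(cons, st, sum, default = 0L)
  data.frame(category = amyloid_levels(), n = as.integer(n),
             n_positive = as.integer(k),
             fraction_positive = ifelse(n > 0, as.numeric(k / n), NA_real_))
}

#' Sensitivity, specificity and agreement over a cutoff sweep
#'
#' For each cutoff c on the grid, subjects are dichotomized as
#' quantitation-positive iff value > c (the same strict convention as
#' [classify_amyloid()]) and compared with the consensus visual read as the
#' reference: sensitivity and specificity of quantitation against the read,
#' and the agreement rate (fraction of subjects where the two match). The
#' emitted confusion counts make all three recomputable.
#'
#' @param cohort Cohort table with read columns and the value column at
#'   baseline.
#' @param cutoff_grid Increasing cutoff values; default 100 evenly spaced
#'   over the observed value range.
#' @param value_col Quantitative column (default `suvr_composite`).
#' @return Data frame `cutoff`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `agreement`.
#' @export
sweep_agreement <- function(cohort, cutoff_grid = NULL,
                            value_col = "suvr_composite") {
  b <- baseline_rows(cohort)
  cons <- consensus_reads(b)
  v <- b[[value_col]]
  keep <- !is.na(cons) & !is.na(v)
  if (!any(keep)) stop("no subjects with both reads and ", value_col)
  cons <- cons[keep]
  v <- v[keep]
  if (is.null(cutoff_grid)) {
    cutoff_grid <- seq(min(v), max(v), length.out = 100)
  }
  if (is.unsorted(cutoff_grid, strictly = TRUE)) {
    stop("cutoff_grid must be strictly increasing")
  }
  rows <- lapply(cutoff_grid, function(cc) {
    pred <- v > cc
    tp <- sum(pred & cons == 1)
    fp <- sum(pred & cons == 0)
    tn <- sum(!pred & cons == 0)
    fn <- sum(!pred & cons == 1)
    data.frame(cutoff = cc, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               agreement = (tp + tn) / length(cons))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
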