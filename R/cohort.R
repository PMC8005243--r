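#' Canonical region vocabulary
#'
#' Region names used throughout the package. The composite SUVR is the
#' unweighted mean of six cortical regions (frontal, lateral temporal,
#' occipital, parietal, anterior and posterior cingulate). The precuneus is
#' quantified but not part of the composite. Amygdala, thalamus and striatum
#' have a limited dynamic SUVR range between young controls and AD dementia
#' and are excluded from topographic interpretation.
#'
#' @return Character vector of region names.
#' @export
composite_regions <- function() {
  c("frontal", "lateral_temporal", "occipital", "parietal",
    "anterior_cingulate", "posterior_cingulate")
}

#' @rdname composite_regions
#' @export
cortical_regions <- function() c(composite_regions(), "precuneus")

#' @rdname composite_regions
#' @export
excluded_regions <- function() c("amygdala", "thalamus", "striatum")

#' @rdname composite_regions
#' @export
tau_regions <- function() {
  c("mesial_temporal", "fusiform", "inferior_temporal", "parietal_tau")
}

suvr_col <- function(region) paste0("suvr_", region)
tau_col <- function(region) paste0("tau_", region)

#' Amyloid status levels
#' @return Character vector of the three category labels, in increasing order
#'   of amyloid burden.
#' @export
amyloid_levels <- function() c("negative", "gray_zone", "established")

#' Recompute the composite SUVR from regional columns
#'
#' @param x A cohort table (or any data frame with `suvr_<region>` columns).
#' @return Numeric vector: unweighted mean over the six composite regions,
#'   `NA` where any of them is missing.
#' @export
compute_composite <- function(x) {
  cols <- suvr_col(composite_regions())
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    stop("missing regional columns: ", paste(missing_cols, collapse = ", "))
  }
  rowMeans(as.matrix(x[, cols, drop = FALSE]))
}

#' Construct/validate a cohort table
#'
#' A cohort table is a data frame with one row per subject-visit. Mandatory
#' columns: `subject_id`, `dataset_id`, `group_label`, `visit_time` (years
#' from baseline). Optional columns: `suvr_<region>`, `suvr_composite`,
#' `cl_cortex` (centiloid), `read_1` ... `read_k` (binary visual reads),
#' `progression_4yr` (0/1), `tau_<region>`. Missing values are empty cells
#' (`NA`), never sentinel numbers.
#'
#' Invariants checked: `(subject_id, visit_time)` unique; `visit_time >= 0`;
#' every subject has a baseline row at `visit_time == 0`; wherever all six
#' composite regions are present, `suvr_composite` equals their unweighted
#' mean to 1e-9.
#'
#' @param x A data frame.
#' @return `x` with class `cohort_table` prepended, invisibly validated.
#' @export
as_cohort_table <- function(x) {
  stopifnot(is.data.frame(x))
  mandatory <- c("subject_id", "dataset_id", "group_label", "visit_time")
  miss <- setdiff(mandatory, names(x))
  if (length(miss) > 0) {
    stop("cohort table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!is.numeric(x$visit_time)) stop("visit_time must be numeric")
  if (any(!is.finite(x$visit_time)) || any(x$visit_time < 0)) {
    stop("visit_time must be finite and >= 0")
  }
  key <- paste(x$subject_id, x$visit_time, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, visit_time) rows")
  }
  has_baseline <- tapply(x$visit_time, x$subject_id, function(t) any(t == 0))
  if (!all(has_baseline)) {
    stop("subject(s) without a baseline (visit_time = 0) row: ",
         paste(utils::head(names(has_baseline)[!has_baseline], 5),
               collapse = ", "))
  }
  cols <- suvr_col(composite_regions())
  if (all(cols %in% names(x)) && "suvr_composite" %in% names(x)) {
    comp <- rowMeans(as.matrix(x[, cols, drop = FALSE]))
    ok <- is.na(comp) | is.na(x$suvr_composite) |
      abs(comp - x$suvr_composite) <= 1e-9
    if (!all(ok)) {
      stop("suvr_composite disagrees with the mean of the 6 composite ",
           "regions in row(s) ", paste(utils::head(which(!ok), 5), collapse = ", "))
    }
  }
  class(x) <- unique(c("cohort_table", class(x)))
  x
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d rows, %d subjects, datasets: %s\n",
              nrow(x), length(unique(x$subject_id)),
              paste(unique(x$dataset_id), collapse = ", ")))
  NextMethod()
}

#' Baseline rows of a cohort table
#' @param x A cohort table.
#' @return The `visit_time == 0` rows.
#' @export
baseline_rows <- function(x) {
  x[x$visit_time == 0, , drop = FALSE]
}

read_column_names <- function(x) grep("^read_[0-9]+$", names(x), value = TRUE)

#' Read a cohort CSV
#'
#' UTF-8 CSV with header row and '.' decimal. Numeric columns are validated
#' cell by cell; a malformed numeric cell raises an error naming the row.
#'
#' @param path File path.
#' @return A [as_cohort_table()] validated cohort table.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  mandatory <- c("subject_id", "dataset_id", "group_label", "visit_time")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss) > 0) {
    stop("cohort file ", path, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  num_cols <- c("visit_time", "suvr_composite", "cl_cortex", "progression_4yr",
                grep("^(suvr|tau|read)_", names(raw), value = TRUE))
  num_cols <- intersect(unique(num_cols), names(raw))
  for (cc in num_cols) {
    v <- raw[[cc]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(parsed) & !is.na(v) & nzchar(trimws(v)))
    if (length(bad) > 0) {
      stop("malformed numeric cell in column '", cc, "', row ", bad[1],
           " ('", v[bad[1]], "')")
    }
    raw[[cc]] <- parsed
  }
  as_cohort_table(raw)
}

#' Write a cohort CSV
#' @param x A cohort table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}
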