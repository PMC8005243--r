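#' Spearman association between amyloid load and regional tau
#'
#' Rank correlation (average ranks for ties) of each tau region's SUVR
#' against the amyloid burden, on both the composite-SUVR and centiloid
#' scales where present.
#'
#' @param cohort Cohort table whose baseline rows carry `tau_<region>`
#'   columns and at least one of `suvr_composite` / `cl_cortex`.
#' @param tau_regions Tau regions to correlate (default [tau_regions()]
#'   present in the cohort).
#' @param min_n Minimum number of complete pairs (default 10).
#' @return Data frame `tau_region`, `amyloid_scale`, `n`, `rho`, `p`.
#' @export
correlate_amyloid_tau <- function(cohort, tau_regions = NULL, min_n = 10) {
  b <- baseline_rows(cohort)
  if (is.null(tau_regions)) {
    tau_regions <- sub("^tau_", "", grep("^tau_", names(b), value = TRUE))
  }
  scales <- c(suvr = "suvr_composite", cl = "cl_cortex")
  scales <- scales[scales %in% names(b)]
  if (length(scales) == 0) stop("no amyloid value column in the cohort")
  rows <- list()
  for (rg in tau_regions) {
    tv <- b[[tau_col(rg)]]
    for (sc in names(scales)) {
      av <- b[[scales[[sc]]]]
      keep <- !is.na(tv) & !is.na(av)
      if (sum(keep) < min_n) {
        stop("fewer than ", min_n, " complete pairs for ", rg, " on ", sc)
      }
      if (stats::sd(tv[keep]) == 0) stop("constant tau column: ", rg)
      ct <- suppressWarnings(
        stats::cor.test(av[keep], tv[keep], method = "spearman"))
      rows[[length(rows) + 1]] <- data.frame(
        tau_region = rg, amyloid_scale = sc, n = sum(keep),
        rho = unname(ct$estimate), p = ct$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regional tau by amyloid category
#'
#' Mean and SD of each tau region's SUVR per amyloid category, with a test
#' of whether tau in the gray-zone and established categories is larger than
#' in the negative category. The default contrast is a one-sided Welch
#' t-test; `test = "anova"` uses a pairwise one-way ANOVA (pooled-variance
#' F test of that category against the negative one) instead — both
#' conventions appear in this literature.
#'
#' @param cohort Cohort table with `tau_<region>` columns at baseline.
#' @param statuses Per-subject amyloid category aligned with (or named by)
#'   the baseline subjects.
#' @param tau_regions Regions to summarize (default: all present).
#' @param test `"t"` (Welch, one-sided) or `"anova"`.
#' @param min_n Minimum per-category size for a contrast (default 2).
#' @return Data frame `tau_region`, `category`, `n`, `mean`, `sd`,
#'   `p_vs_negative` (`NA` for the negative row or under-filled categories).
#' @export
compare_tau_by_category <- function(cohort, statuses, tau_regions = NULL,
                                    test = c("t", "anova"), min_n = 2) {
  test <- match.arg(test)
  b <- baseline_rows(cohort)
  if (is.null(tau_regions)) {
    tau_regions <- sub("^tau_", "", grep("^tau_", names(b), value = TRUE))
  }
  if (!is.null(names(statuses))) statuses <- statuses[b$subject_id]
  stopifnot(length(statuses) == nrow(b))
  st <- factor(statuses, amyloid_levels())
  rows <- list()
  for (rg in tau_regions) {
    tv <- b[[tau_col(rg)]]
    neg <- tv[st == "negative" & !is.na(tv)]
    for (s in amyloid_levels()) {
      x <- tv[st == s & !is.na(tv)]
      p <- NA_real_
      if (s != "negative" && length(x) >= min_n && length(neg) >= min_n) {
        p <- if (test == "t") {
          stats::t.test(x, neg, alternative = "greater")$p.value
        } else {
          d <- data.frame(v = c(x, neg),
                          g = rep(c(s, "negative"), c(length(x), length(neg))))
          summary(stats::aov(v ~ g, data = d))[[1]][["Pr(>F)"]][1]
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        tau_region = rg, category = s, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        p_vs_negative = p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
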