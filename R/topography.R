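#' Group anchors for the half-capacity reference
#'
#' The logistic trajectory's lower asymptote NS is estimated per region from
#' the mean SUVR of visually negative young controls and the carrying
#' capacity K from the difference to the mean of visually positive AD
#' dementia subjects, so the half-capacity point is the midpoint of the two
#' group means. Anchors are recomputed from the input cohort by default;
#' printed group means can be injected instead for reproduction runs.
#'
#' @param yhc,ad Cohort tables for the two anchor groups. When read columns
#'   are present, only consensus-negative yHC and consensus-positive AD rows
#'   are used.
#' @param regions Regions to anchor.
#' @return A data frame `region`, `suvr_yhc`, `suvr_ad` of class
#'   `group_anchors`. Warns if any cortical region has `suvr_ad < suvr_yhc`.
#' @export
group_anchors <- function(yhc, ad, regions = cortical_regions()) {
  pick <- function(x, want_positive) {
    x <- baseline_rows(x)
    rc <- read_column_names(x)
    if (length(rc) > 0) {
      cons <- consensus_reads(x)
      keep <- !is.na(cons) & (cons == as.numeric(want_positive))
      if (any(keep)) x <- x[keep, , drop = FALSE]
    }
    x
  }
  yhc <- pick(yhc, FALSE)
  ad <- pick(ad, TRUE)
  cols <- suvr_col(regions)
  miss <- setdiff(cols, intersect(names(yhc), names(ad)))
  if (length(miss) > 0) stop("missing region column(s): ",
                             paste(miss, collapse = ", "))
  out <- data.frame(
    region = regions,
    suvr_yhc = vapply(cols, function(cc) mean(yhc[[cc]], na.rm = TRUE),
                      numeric(1)),
    suvr_ad = vapply(cols, function(cc) mean(ad[[cc]], na.rm = TRUE),
                     numeric(1)))
  rownames(out) <- NULL
  bad <- out$suvr_ad < out$suvr_yhc & !(out$region %in% excluded_regions())
  if (any(bad)) {
    warning("AD anchor below yHC anchor in region(s): ",
            paste(out$region[bad], collapse = ", "))
  }
  class(out) <- c("group_anchors", class(out))
  out
}

#' Anchors from supplied group means
#'
#' @param suvr_yhc,suvr_ad Named numeric vectors of regional group means.
#' @return A `group_anchors` data frame.
#' @export
anchors_from_means <- function(suvr_yhc, suvr_ad) {
  stopifnot(identical(names(suvr_yhc), names(suvr_ad)))
  out <- data.frame(region = names(suvr_yhc), suvr_yhc = unname(suvr_yhc),
                    suvr_ad = unname(suvr_ad))
  class(out) <- c("group_anchors", class(out))
  out
}

#' Half-carrying-capacity reference SUVR per region
#'
#' With NS anchored at the young-control mean and NS + K at the AD mean, the
#' logistic trajectory's half-capacity value NS + K/2 is the arithmetic
#' midpoint of the two anchors.
#'
#' @param anchors A [group_anchors()] data frame.
#' @param regions Regions to return (all anchored regions by default).
#' @return Named numeric vector of reference SUVRs.
#' @export
compute_t50_reference <- function(anchors, regions = anchors$region) {
  miss <- setdiff(regions, anchors$region)
  if (length(miss) > 0) stop("no anchors for region(s): ",
                             paste(miss, collapse = ", "))
  i <- match(regions, anchors$region)
  stats::setNames((anchors$suvr_ad[i] + anchors$suvr_yhc[i]) / 2, regions)
}

#' Delta-SUVR matrix against the half-capacity reference
#'
#' `delta = SUVR - SUVR(t = T50)` per subject and region: positive where a
#' subject's regional retention has passed half of the region's dynamic
#' range (closer to AD dementia levels), negative where it is near the
#' young-control level. Subjects are sorted by ascending composite SUVR,
#' the rendering order of the continuum heat map.
#'
#' @param cohort Cohort table (baseline rows are used) with the reference's
#'   regions and `suvr_composite`.
#' @param t50_ref Named vector from [compute_t50_reference()].
#' @return A `topography_result` list: `delta` (subjects x regions data
#'   frame, sorted), `composite` (sorted composite SUVR), `subject_id`,
#'   `t50_ref`, `excluded` ([excluded_regions()] present in the input).
#' @export
compute_delta_suvr <- function(cohort, t50_ref) {
  b <- baseline_rows(cohort)
  cols <- suvr_col(names(t50_ref))
  miss <- setdiff(cols, names(b))
  if (length(miss) > 0) stop("cohort lacks region column(s): ",
                             paste(miss, collapse = ", "))
  ord <- order(b$suvr_composite)
  b <- b[ord, , drop = FALSE]
  delta <- as.data.frame(
    sweep(as.matrix(b[, cols, drop = FALSE]), 2, t50_ref),
    optional = TRUE)
  names(delta) <- names(t50_ref)
  structure(list(delta = delta, composite = b$suvr_composite,
                 subject_id = b$subject_id, t50_ref = t50_ref,
                 excluded = intersect(names(t50_ref), excluded_regions())),
            class = "topography_result")
}

#' Rank regions by earliest half-capacity crossing
#'
#' Regions whose delta-SUVR turns non-negative at a lower position on the
#' composite-SUVR continuum show pathological tracer retention earlier. The
#' crossing position of a region is estimated as the median composite SUVR
#' among the lowest decile (by composite) of the subjects whose regional
#' delta-SUVR is >= 0. Amygdala, thalamus and striatum are dropped before
#' ranking (limited dynamic range). A region that never crosses is ranked
#' last and flagged. Ties keep the input (canonical) region order.
#'
#' @param result A [compute_delta_suvr()] result.
#' @return Data frame `region`, `crossing_position` (composite SUVR; `Inf`
#'   if never crossed), `never_crossed`, in rank order.
#' @export
rank_regions_by_onset <- function(result) {
  stopifnot(inherits(result, "topography_result"))
  regions <- setdiff(names(result$t50_ref), excluded_regions())
  comp <- result$composite
  if (!any(comp < min(result$t50_ref[regions])) ||
      !any(comp > max(result$t50_ref[regions]))) {
    warning("cohort may not span the full continuum around the half-capacity ",
            "references; crossing positions can be truncated")
  }
  pos <- vapply(regions, function(rg) {
    cross <- which(result$delta[[rg]] >= 0)
    if (length(cross) == 0) return(Inf)
    k <- max(1L, ceiling(0.1 * length(cross)))
    stats::median(comp[cross[seq_len(k)]]) # subjects already sorted by composite
  }, numeric(1))
  ord <- order(pos) # stable: ties keep canonical input order
  data.frame(region = regions[ord], crossing_position = unname(pos[ord]),
             never_crossed = !is.finite(pos[ord]))
}
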