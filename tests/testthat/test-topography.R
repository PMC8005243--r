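test_that("half-capacity reference is the midpoint of the group anchors", {
  anchors <- anchors_from_means(
    suvr_yhc = c(composite = 1.16, frontal = 1.09),
    suvr_ad = c(composite = 1.58, frontal = 1.57))
  t50 <- compute_t50_reference(anchors)
  expect_equal(unname(t50["composite"]), 1.37)
  expect_equal(unname(t50["frontal"]), 1.33)
  # degenerate anchors collapse to the common value
  same <- anchors_from_means(c(r = 1.2), c(r = 1.2))
  expect_equal(unname(compute_t50_reference(same)), 1.2)
  expect_error(compute_t50_reference(anchors, regions = "occipital"),
               "no anchors")
})

test_that("anchors recomputed from cohorts use the visual consensus rows", {
  yhc <- make_cohort(n = 6, composite = rep(1.16, 6))
  yhc$suvr_frontal <- c(rep(1.09, 5), 9) # one visually positive outlier
  yhc$read_1 <- yhc$read_2 <- yhc$read_3 <- c(rep(0, 5), 1)
  ad <- make_cohort(n = 4, composite = rep(1.58, 4))
  ad$suvr_frontal <- c(rep(1.57, 3), 0.5)
  ad$read_1 <- ad$read_2 <- ad$read_3 <- c(rep(1, 3), 0)
  anc <- group_anchors(yhc, ad, regions = "frontal")
  expect_equal(anc$suvr_yhc, 1.09) # outlier read-positive row excluded
  expect_equal(anc$suvr_ad, 1.57)
})

test_that("delta-SUVR is the exact shift from the half-capacity point", {
  cohort <- make_cohort(n = 3, composite = c(1.16, 1.37, 1.58))
  cohort$suvr_frontal <- c(1.16, 1.37, 1.58)
  t50 <- c(frontal = 1.37)
  res <- compute_delta_suvr(cohort, t50)
  expect_equal(res$delta$frontal, c(-0.21, 0, 0.21))
  expect_equal(res$composite, sort(cohort$suvr_composite))

  # affine shift property: adding c to a region adds c to its delta
  shift <- cohort
  shift$suvr_frontal <- shift$suvr_frontal + 0.05
  res2 <- compute_delta_suvr(shift, t50)
  expect_equal(res2$delta$frontal, res$delta$frontal + 0.05)
})

test_that("region ranking drops excluded regions and flags non-crossers", {
  n <- 40
  comp <- seq(1.1, 1.7, length.out = n)
  cohort <- make_cohort(n = n, composite = comp)
  cohort$suvr_early_region <- comp          # crosses at 1.30
  cohort$suvr_late_region <- comp - 0.2     # crosses at 1.50
  cohort$suvr_never <- rep(0.5, n)          # never crosses
  cohort$suvr_striatum <- comp              # excluded from interpretation
  t50 <- c(early_region = 1.30, late_region = 1.30, never = 1.30,
           striatum = 1.0)
  rk <- suppressWarnings(rank_regions_by_onset(compute_delta_suvr(cohort, t50)))
  expect_false("striatum" %in% rk$region)
  expect_equal(rk$region, c("early_region", "late_region", "never"))
  expect_true(rk$never_crossed[3])
  expect_lt(rk$crossing_position[1], rk$crossing_position[2])

  # identical regions tie and keep the canonical input order
  tie <- make_cohort(n = n, composite = comp)
  tie$suvr_b_region <- comp
  tie$suvr_a_region <- comp
  rk2 <- rank_regions_by_onset(
    compute_delta_suvr(tie, c(b_region = 1.3, a_region = 1.3)))
  expect_equal(rk2$region, c("b_region", "a_region"))
})

test_that("ranking is invariant to common affine rescaling within a region", {
  set.seed(710)
  cohort <- generate_logistic_cohort(default_trajectories(), n = 250,
                                     t_range = c(0, 30), noise_sd = 0.02,
                                     seed = 711)
  anchors <- anchors_from_means(
    vapply(default_trajectories(), `[[`, numeric(1), "ns"),
    vapply(default_trajectories(), function(p) p$ns + p$k, numeric(1)))
  t50 <- compute_t50_reference(anchors)
  rk1 <- suppressWarnings(rank_regions_by_onset(compute_delta_suvr(cohort, t50)))

  scaled <- cohort
  scaled$suvr_frontal <- 3 * scaled$suvr_frontal + 0.7
  t50_scaled <- t50
  t50_scaled["frontal"] <- 3 * t50_scaled["frontal"] + 0.7
  # composite untouched: positions must be identical
  rk2 <- suppressWarnings(
    rank_regions_by_onset(compute_delta_suvr(scaled, t50_scaled)))
  expect_equal(rk1$region, rk2$region)
  expect_equal(rk1$crossing_position, rk2$crossing_position)
})

test_that("staggered logistic onset order is recovered from cross-sections", {
  traj <- default_trajectories()
  t50_true <- vapply(traj, `[[`, numeric(1), "t50")
  anchors <- anchors_from_means(
    vapply(traj, `[[`, numeric(1), "ns"),
    vapply(traj, function(p) p$ns + p$k, numeric(1)))
  ref <- compute_t50_reference(anchors)
  rhos <- vapply(1:20, function(s) {
    cohort <- generate_logistic_cohort(traj, n = 300, t_range = c(0, 30),
                                       noise_sd = 0.02, seed = 7000 + s)
    rk <- rank_regions_by_onset(compute_delta_suvr(cohort, ref))
    cor(match(names(t50_true), rk$region), rank(t50_true),
        method = "spearman")
  }, numeric(1))
  expect_true(all(rhos >= 0.8))
})
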