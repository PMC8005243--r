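test_that("logistic trajectory hits its landmarks and stays in its band", {
  p <- logistic_params("composite", ns = 1.16, k = 0.42, r = 0.3, t50 = 15)
  expect_equal(logistic_suvr(15, p), 1.16 + 0.42 / 2) # half capacity = 1.37
  expect_equal(logistic_suvr(15, p), 1.37)
  expect_equal(logistic_suvr(-1e6, p), 1.16, tolerance = 1e-9) # lower asymptote
  expect_error(logistic_suvr(Inf, p), "finite")
  expect_error(logistic_params("x", ns = 1, k = -1, r = 0.3, t50 = 10),
               "positive")

  set.seed(401)
  for (i in 1:25) {
    pr <- logistic_params("r", ns = runif(1, 0.8, 1.5), k = runif(1, 0.1, 1),
                          r = runif(1, 0.05, 1), t50 = runif(1, 5, 25))
    t <- sort(runif(50, pr$t50 - 20, pr$t50 + 20))
    v <- logistic_suvr(t, pr)
    expect_true(all(v > pr$ns & v < pr$ns + pr$k))
    expect_true(all(diff(v) > 0))
  }
})

test_that("cross-sectional generator is deterministic and moment-faithful", {
  spec <- list(group_spec("yHC", 65, c(composite = 1.16),
                          c(composite = 0.04), cl_mean = 2.82, cl_sd = 5.36))
  a <- generate_cross_sectional(spec, seed = 7)
  b <- generate_cross_sectional(spec, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_cross_sectional(spec, seed = 8)))

  # degenerate Gaussian: everyone exactly at the mean
  d <- generate_cross_sectional(list(group_spec("g", 20, c(composite = 1.3),
                                               c(composite = 0))), seed = 1)
  expect_true(all(d$suvr_composite == 1.3))

  # CLT bound 3*sd/sqrt(n) on the centiloid mean
  big <- generate_cross_sectional(list(
    group_spec("yHC", 10000, c(composite = 1.16), c(composite = 0.04),
               cl_mean = 2.82, cl_sd = 5.36)), seed = 21)
  expect_lt(abs(mean(big$cl_cortex) - 2.82), 0.15)
  expect_error(generate_cross_sectional(list(), seed = 1), "empty")
})

test_that("regional draws keep the composite identity and group moments", {
  scen <- default_scenario()
  cohort <- generate_cross_sectional(list(
    group_spec("yHC", 500, scen$yhc$means, scen$yhc$sds)), seed = 31)
  expect_equal(cohort$suvr_composite, compute_composite(cohort),
               tolerance = 1e-12)
  # seeded moment convergence, 3*sd/sqrt(n) per region
  for (rg in names(scen$yhc$means)) {
    m <- mean(cohort[[paste0("suvr_", rg)]])
    expect_lt(abs(m - scen$yhc$means[[rg]]),
              3 * scen$yhc$sds[[rg]] / sqrt(500))
  }
})

test_that("longitudinal generator reduces to exact lines without noise", {
  base <- make_cohort(n = 1, composite = 1.30)
  cuts <- published_cutoffs("suvr")
  # percent spec chosen so alpha = 0.03/yr at baseline 1.30
  pct <- 100 * 0.03 / 1.30
  out <- generate_longitudinal(base, c(0, 2),
                               list(negative = c(0, 0), gray_zone = c(pct, 0),
                                    established = c(0, 0)),
                               noise_sd = 0, cutoffs = cuts, seed = 5)
  expect_equal(out$suvr_composite[out$visit_time == 2], 1.36)
  spec0 <- list(negative = c(0, 0), gray_zone = c(0, 0),
                established = c(0, 0))
  expect_error(generate_longitudinal(base, c(1, 2), spec0, 0, cuts, 1),
               "baseline")
})

test_that("zero-mean slope specification gives an unbiased fitted group mean", {
  base <- make_cohort(n = 400, composite = rnorm(400, 1.15, 0.03))
  cuts <- published_cutoffs("suvr")
  out <- generate_longitudinal(base, c(0, 2),
                               list(negative = c(0, 1), gray_zone = c(0, 1),
                                    established = c(0, 1)),
                               noise_sd = 0.01, cutoffs = cuts, seed = 9)
  est <- fit_cohort_slopes(out, scale = "suvr")
  expect_lt(abs(mean(est$abeta_dep)), 3 * sd(est$abeta_dep) / sqrt(nrow(est)))
})

test_that("tau coupling spans independence to comonotonicity", {
  # coupling 1 with well-separated, variance-ordered category distributions:
  # the blended deviate is a strictly monotone map of the CL rank
  cl <- c(seq(-10, 10, length.out = 60), seq(20, 30, length.out = 40),
          seq(45, 120, length.out = 100))
  cohort <- make_cohort(n = 200, composite = rep(1.2, 200), cl = cl)
  spec1 <- tau_spec(means = list(fusiform = c(negative = 1.0,
                                              gray_zone = 2.0,
                                              established = 3.0)),
                    sds = list(fusiform = c(negative = 0.05,
                                            gray_zone = 0.05,
                                            established = 0.05)),
                    rank_coupling = 1)
  t1 <- generate_tau(cohort, spec1, published_cutoffs("cl"), seed = 3)
  expect_equal(cor(t1$cl_cortex, t1$tau_fusiform, method = "spearman"), 1)

  # coupling 0 with identical category distributions: pooled independence
  spec0 <- tau_spec(means = list(fusiform = c(negative = 1.2,
                                              gray_zone = 1.2,
                                              established = 1.2)),
                    sds = list(fusiform = c(negative = 0.1, gray_zone = 0.1,
                                            established = 0.1)),
                    rank_coupling = 0)
  t0 <- generate_tau(cohort, spec0, published_cutoffs("cl"), seed = 4)
  expect_lt(abs(cor(t0$cl_cortex, t0$tau_fusiform, method = "spearman")),
            0.15)
})

test_that("tau generator recovers the per-category moments it was given", {
  rv <- reference_values()
  set.seed(51)
  cl <- c(rnorm(120, 0, 7), rnorm(60, 24, 5), rnorm(120, 75, 30))
  cohort <- make_cohort(n = 300, composite = rep(1.2, 300), cl = cl)
  spec <- tau_spec(rv$tau$means, rv$tau$sds, rank_coupling = 0.5)
  out <- generate_tau(cohort, spec, published_cutoffs("cl"), seed = 52)
  st <- classify_amyloid(out$cl_cortex, 13.5, 35.7)
  for (s in amyloid_levels()) {
    x <- out$tau_fusiform[st == s]
    mu <- rv$tau$means$fusiform[[s]]
    sdv <- rv$tau$sds$fusiform[[s]]
    expect_lt(abs(mean(x) - mu), 3 * sdv / sqrt(length(x)))
  }
})

test_that("visual reads follow the per-category positivity probabilities", {
  cuts <- published_cutoffs("suvr")
  estab <- make_cohort(n = 50, composite = rep(1.5, 50))
  all_pos <- generate_visual_reads(
    estab, read_spec(3, c(negative = 0, gray_zone = 0, established = 1)),
    cuts, seed = 6)
  expect_true(all(consensus_reads(all_pos) == 1))

  neg <- make_cohort(n = 50, composite = rep(1.10, 50))
  all_neg <- generate_visual_reads(
    neg, read_spec(3, c(negative = 0, gray_zone = 0.5, established = 1)),
    cuts, seed = 7)
  expect_true(all(consensus_reads(all_neg) == 0))

  gray <- make_cohort(n = 500, composite = rep(1.30, 500))
  reads <- generate_visual_reads(
    gray, read_spec(1, c(negative = 0, gray_zone = 0.2, established = 1)),
    cuts, seed = 8)
  frac <- mean(reads$read_1)
  expect_true(frac > 0.15 && frac < 0.25) # binomial 3-sigma band

  expect_error(read_spec(2), "n_readers")
})

test_that("child seeds are deterministic, distinct and within integer range", {
  s1 <- child_seed(42, "simulate_yhc")
  expect_identical(s1, child_seed(42, "simulate_yhc"))
  stages <- c("simulate_yhc", "simulate_ds2", "scd_base", "mci_base",
              "tau_draw", "reads_ds2")
  seeds <- vapply(stages, child_seed, integer(1), master = 42)
  expect_equal(anyDuplicated(seeds), 0)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})
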