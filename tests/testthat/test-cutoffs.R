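test_that("early cutoff is mean + 2 SD with normality bookkeeping", {
  # samples constructed to have the printed moments exactly
  cl_vals <- sample_with_moments(65, 2.82, 5.36, seed = 1)
  yhc <- make_cohort(n = 65, composite = sample_with_moments(65, 1.16, 0.04,
                                                             seed = 2),
                     cl = cl_vals)
  out <- derive_early_cutoffs(yhc, scale = "cl")
  expect_equal(out$early_cutoff, 2.82 + 2 * 5.36, tolerance = 1e-9) # 13.54
  expect_equal(round(out$early_cutoff, 2), 13.54)
  expect_true(out$normality_p > 0.05)

  lt <- make_cohort(n = 65)
  lt$suvr_lateral_temporal <- sample_with_moments(65, 1.09, 0.03, seed = 3)
  lt$suvr_occipital <- sample_with_moments(65, 1.18, 0.04, seed = 4)
  out2 <- derive_early_cutoffs(lt, regions = c("lateral_temporal", "occipital"))
  expect_equal(round(out2$early_cutoff, 2), c(1.15, 1.26))

  expect_error(derive_early_cutoffs(make_cohort(n = 2),
                                    regions = "composite"),
               "at least 3")
  const <- make_cohort(n = 20, composite = rep(1.2, 20))
  expect_warning(out3 <- derive_early_cutoffs(const, regions = "composite"),
                 "zero variance")
  expect_equal(out3$early_cutoff, 1.2)
  set.seed(99)
  skewed <- make_cohort(n = 65, composite = 1.1 + rexp(65, 20)^2)
  expect_warning(derive_early_cutoffs(skewed, regions = "composite"),
                 "Shapiro")
})

test_that("established cutoff reproduces the hand-enumerated examples", {
  r1 <- derive_established_cutoff(c(1.0, 1.1), c(1.5, 1.6))
  expect_equal(r1$cutoff, 1.3)
  expect_equal(r1$youden_j, 1)
  expect_equal(r1$sensitivity, 1)
  expect_equal(r1$specificity, 1)
  expect_equal(r1$auc, 1)

  r2 <- derive_established_cutoff(c(1, 2, 3), c(2.5, 3.5))
  expect_equal(r2$cutoff, 2.25)
  expect_equal(r2$youden_j, 2 / 3)
  expect_equal(r2$auc, 5 / 6)

  # identical class multisets are exchangeable
  r3 <- derive_established_cutoff(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$auc, 0.5)

  expect_error(derive_established_cutoff(numeric(0), 1), "non-empty")
  expect_error(derive_established_cutoff(rep(1, 5), rep(1, 5)), "identical")
})

test_that("ROC agrees with a brute-force oracle on random small instances", {
  set.seed(501)
  for (i in 1:100) {
    n1 <- sample(2:20, 1)
    n2 <- sample(2:20, 1)
    # mixture of continuous and tied discrete values
    neg <- round(rnorm(n1, 1.2, 0.1), sample(1:3, 1))
    pos <- round(rnorm(n2, 1.4, 0.15), sample(1:3, 1))
    if (length(unique(c(neg, pos))) < 2) next
    got <- derive_established_cutoff(neg, pos)
    want <- brute_force_roc(neg, pos)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden_j, want$youden_j)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
    expect_equal(got$auc, want$auc, tolerance = 1e-9)
  }
})

test_that("ROC AUC equals the Mann-Whitney statistic and the pROC estimate", {
  skip_if_not_installed("pROC")
  set.seed(502)
  neg <- rnorm(40, 1.2, 0.08)
  pos <- c(rnorm(35, 1.5, 0.15), neg[1:3]) # inject exact ties
  got <- derive_established_cutoff(neg, pos)
  u <- unname(wilcox.test(pos, neg, exact = FALSE)$statistic)
  expect_equal(got$auc, u / (length(pos) * length(neg)), tolerance = 1e-9)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(0, 1), c(length(neg), length(pos))),
    predictor = c(neg, pos), quiet = TRUE)))
  expect_equal(got$auc, proc_auc, tolerance = 1e-9)
})

test_that("the selected cutoff dominates every candidate's Youden index", {
  set.seed(503)
  neg <- rnorm(30, 1.2, 0.07)
  pos <- rnorm(25, 1.45, 0.12)
  got <- derive_established_cutoff(neg, pos)
  u <- sort(unique(c(neg, pos)))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  j_all <- vapply(cand, function(cc) {
    mean(pos > cc) + mean(neg <= cc) - 1
  }, numeric(1))
  expect_true(all(got$youden_j >= j_all - 1e-12))
})

test_that("binormal AUC matches the printed discrimination of the ROC cohort", {
  expect_equal(round(auc_binormal(1.21, 0.06, 1.58, 0.17), 2), 0.98)
  expect_equal(round(auc_binormal(6.8, 8.8, 81.0, 33.2), 2), 0.98)
  expect_equal(auc_binormal(1.3, 0.1, 1.3, 0.2), 0.5) # equal means
  expect_error(auc_binormal(1, 0, 2, 1), "positive")
})

test_that("classification respects the inclusive gray-zone boundaries", {
  expect_equal(as.character(classify_amyloid(1.20, 1.25, 1.38)), "negative")
  expect_equal(as.character(classify_amyloid(1.25, 1.25, 1.38)), "gray_zone")
  expect_equal(as.character(classify_amyloid(1.38, 1.25, 1.38)), "gray_zone")
  expect_equal(as.character(classify_amyloid(1.40, 1.25, 1.38)), "established")
  expect_error(classify_amyloid(1.3, 1.4, 1.2), "early cutoff")

  # partition + monotonicity over a value sweep
  v <- seq(0.9, 1.8, by = 0.001)
  st <- classify_amyloid(v, 1.25, 1.38)
  expect_false(anyNA(st))
  expect_true(all(diff(as.integer(st)) >= 0))
  expect_setequal(levels(st), amyloid_levels())
})

test_that("cutoff_set warns when the cutoffs are out of order", {
  expect_silent(cutoff_set(1.25, 1.38, "suvr"))
  expect_warning(cutoff_set(1.40, 1.38, "suvr"), "not below")
})

test_that("mixture confirmation recovers a separated two-component truth", {
  set.seed(600)
  x <- c(rnorm(1400, 0, 5), rnorm(600, 80, 30))
  fit <- fit_mixture_confirmation(x, seed = 601)
  expect_lt(abs(fit$means[1] - 0), 1)
  expect_equal(fit$early_cutoff, fit$means[1] + 2 * fit$sds[1])
  expect_gt(fit$estab_cutoff, fit$means[1])
  expect_lt(fit$estab_cutoff, fit$means[2])
  # posterior equality at the derived established cutoff
  post1 <- fit$weight * dnorm(fit$estab_cutoff, fit$means[1], fit$sds[1])
  post2 <- (1 - fit$weight) * dnorm(fit$estab_cutoff, fit$means[2],
                                    fit$sds[2])
  expect_equal(post1, post2, tolerance = 1e-6)

  skip_if_not_installed("mclust")
  # Mclust resolves its helpers from the attached search path
  withr::local_package("mclust")
  mc <- suppressWarnings(mclust::Mclust(x, G = 2, modelNames = "V",
                                        verbose = FALSE))
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.5)

  expect_error(fit_mixture_confirmation(rnorm(30), seed = 1), "at least 50")
  # single-component data: either the components collapse or EM stalls
  set.seed(602)
  expect_error(fit_mixture_confirmation(rnorm(500, 10, 0.5), seed = 1),
               "collapsed|converge")
})
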