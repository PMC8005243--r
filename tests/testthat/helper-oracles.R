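# Independent brute-force oracles, kept free of the package's own code paths.

# Exhaustive ROC oracle: rebuild the candidate grid, recompute every
# confusion matrix by explicit counting, pick max J / max specificity /
# largest threshold by explicit comparison, and compute AUC by looping over
# all class pairs (ties count one half).
brute_force_roc <- function(neg, pos) {
  u <- sort(unique(c(neg, pos)))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- NULL
  for (cc in cand) {
    tp <- 0; fn <- 0
    for (v in pos) if (v > cc) tp <- tp + 1 else fn <- fn + 1
    tn <- 0; fp <- 0
    for (v in neg) if (v > cc) fp <- fp + 1 else tn <- tn + 1
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    j <- sens + spec - 1
    cand_rec <- list(cutoff = cc, sensitivity = sens, specificity = spec,
                     youden_j = j)
    if (is.null(best) || j > best$youden_j ||
        (j == best$youden_j && spec > best$specificity) ||
        (j == best$youden_j && spec == best$specificity && cc > best$cutoff)) {
      best <- cand_rec
    }
  }
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1 else if (p == n) wins <- wins + 0.5
  }
  best$auc <- wins / (length(pos) * length(neg))
  best
}

# sample with exact first two moments: mean + sd * standardized deviates
sample_with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

# tiny cohort table builder for unit tests
make_cohort <- function(n = 10, composite = seq(1.1, 1.6, length.out = n),
                        cl = NULL, dataset_id = "fix", group = "test") {
  df <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                   dataset_id = dataset_id, group_label = group,
                   visit_time = 0, suvr_composite = composite)
  if (!is.null(cl)) df$cl_cortex <- cl
  as_cohort_table(df)
}
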