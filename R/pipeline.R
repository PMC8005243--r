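fnv1a_hash <- function(x) {
  # tiny stable config hash for provenance (polynomial hash of the JSON
  # encoding, kept inside exact double-integer range)
  bytes <- utf8ToInt(paste(as.character(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)),
    collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' @param scenario Scenario list (see [default_scenario()]) or a path to a
#'   YAML scenario file.
#' @param seed Non-negative integer master seed; every stage derives its own
#'   [child_seed()] from it.
#' @param scale `"suvr"`, `"cl"` or `"both"`.
#' @param cutoff_overrides Optional list with elements `suvr` and/or `cl`,
#'   each `c(early, estab)` (e.g. the published 13.5/35.7 CL pair). When
#'   present, classification uses the overrides and the cutoff-derivation
#'   stage records them instead of deriving.
#' @param outdir Optional output directory for stage CSVs and the JSON
#'   report.
#' @param stages Character vector of stages to run (dependency order is
#'   enforced); default all.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = default_scenario(), seed = 1,
                            scale = c("both", "suvr", "cl"),
                            cutoff_overrides = NULL, outdir = NULL,
                            stages = c("simulate", "centiloid", "cutoffs",
                                       "classify", "topography",
                                       "longitudinal", "tau", "concordance")) {
  scale <- match.arg(scale)
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stopifnot(length(seed) == 1, is.finite(seed), seed >= 0)
  if (!is.null(cutoff_overrides)) {
    for (sc in names(cutoff_overrides)) {
      v <- cutoff_overrides[[sc]]
      if (v[1] > v[2]) stop("override early cutoff must not exceed the ",
                            "established cutoff (", sc, ")")
    }
  }
  structure(list(scenario = scenario, seed = as.integer(seed), scale = scale,
                 cutoff_overrides = cutoff_overrides, outdir = outdir,
                 stages = stages),
            class = "pipeline_config")
}

scales_of <- function(config) {
  if (config$scale == "both") c("suvr", "cl") else config$scale
}

simulate_scenario <- function(scenario, seed) {
  sz <- scenario$sizes
  yhc <- generate_cross_sectional(list(
    group_spec("yHC", sz$yhc, scenario$yhc$means, scenario$yhc$sds,
               cl_mean = scenario$yhc$cl[["mean"]],
               cl_sd = scenario$yhc$cl[["sd"]], dataset_id = "ds1")),
    seed = child_seed(seed, "simulate_yhc"), rho = scenario$rho)
  ds2 <- generate_cross_sectional(list(
    group_spec("eHC", sz$ehc, scenario$ehc$means, scenario$ehc$sds,
               cl_mean = scenario$ehc$cl[["mean"]],
               cl_sd = scenario$ehc$cl[["sd"]], dataset_id = "ds2"),
    group_spec("AD", sz$ad, scenario$ad$means, scenario$ad$sds,
               cl_mean = scenario$ad$cl[["mean"]],
               cl_sd = scenario$ad$cl[["sd"]], dataset_id = "ds2")),
    seed = child_seed(seed, "simulate_ds2"), rho = scenario$rho)
  cut_suvr <- published_cutoffs("suvr")
  cut_cl <- published_cutoffs("cl")
  rspec <- read_spec(scenario$n_readers, scenario$reads)
  yhc <- generate_visual_reads(yhc, rspec, cut_suvr,
                               child_seed(seed, "reads_yhc"))
  ds2 <- generate_visual_reads(ds2, rspec, cut_suvr,
                               child_seed(seed, "reads_ds2"))
  scd0 <- simulate_mixture_baseline(scenario$scd_mixture, sz$scd, "ds3",
                                    "SCD", child_seed(seed, "scd_base"))
  scd_suvr <- generate_longitudinal(scd0, scenario$visits$scd,
                                    scenario$scd_rates$suvr,
                                    scenario$noise_sd$suvr, cut_suvr,
                                    child_seed(seed, "scd_long_suvr"),
                                    scale = "suvr")
  scd_cl <- generate_longitudinal(scd0, scenario$visits$scd,
                                  scenario$scd_rates$cl,
                                  scenario$noise_sd$cl, cut_cl,
                                  child_seed(seed, "scd_long_cl"),
                                  scale = "cl")
  mci0 <- simulate_mixture_baseline(scenario$mci_mixture, sz$mci, "ds4",
                                    "MCI", child_seed(seed, "mci_base"))
  mci0 <- generate_progression(mci0, scenario$progression, cut_suvr,
                               child_seed(seed, "mci_prog"))
  mci_suvr <- generate_longitudinal(mci0, scenario$visits$mci,
                                    scenario$mci_rates$suvr,
                                    scenario$noise_sd$suvr, cut_suvr,
                                    child_seed(seed, "mci_long_suvr"),
                                    scale = "suvr")
  mci_cl <- generate_longitudinal(mci0, scenario$visits$mci,
                                  scenario$mci_rates$cl,
                                  scenario$noise_sd$cl, cut_cl,
                                  child_seed(seed, "mci_long_cl"),
                                  scale = "cl")
  scd0 <- generate_visual_reads(scd0, rspec, cut_suvr,
                                child_seed(seed, "reads_scd"))
  mci0 <- generate_visual_reads(mci0, rspec, cut_suvr,
                                child_seed(seed, "reads_mci"))
  tau0 <- simulate_mixture_baseline(scenario$tau_cl_mixture, sz$tau, "ds5",
                                    "eHC/MCI/AD",
                                    child_seed(seed, "tau_base"),
                                    cl_only = TRUE)
  tau0 <- generate_tau(tau0, tau_spec(scenario$tau$means, scenario$tau$sds,
                                      scenario$tau_coupling),
                       cut_cl, child_seed(seed, "tau_draw"))
  list(yhc = yhc, ds2 = ds2, scd_base = scd0, scd_suvr = scd_suvr,
       scd_cl = scd_cl, mci_base = mci0, mci_suvr = mci_suvr,
       mci_cl = mci_cl, tau = tau0)
}

# synthetic centiloid-transfer pair table (identity relation + small noise)
synthesize_calibration_pairs <- function(seed, n = 30) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  ref_cl <- stats::runif(n, 0, 100)
  calib <- centiloid_calibration()
  ref_suvr <- cl_to_suvr(ref_cl, calib)
  rbind(
    data.frame(scale = "cl", reference_value = ref_cl,
               local_value = ref_cl + stats::rnorm(n, 0, 0.5)),
    data.frame(scale = "suvr", reference_value = ref_suvr,
               local_value = ref_suvr + stats::rnorm(n, 0, 0.003)))
}

operative_cutoffs <- function(config, cutoff_table) {
  out <- list()
  for (sc in scales_of(config)) {
    ov <- config$cutoff_overrides[[sc]]
    if (!is.null(ov)) {
      out[[sc]] <- cutoff_set(ov[1], ov[2], scale = sc,
                              provenance = list(method = "override"))
    } else if (is.null(cutoff_table)) {
      out[[sc]] <- published_cutoffs(sc)
    } else {
      row <- cutoff_table[cutoff_table$scale == sc &
                            cutoff_table$region %in% c("composite", "cortex"), ]
      out[[sc]] <- cutoff_set(row$early_cutoff[1], row$estab_cutoff[1],
                              scale = sc,
                              provenance = list(method = "derived"))
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate the scenario's
#' five datasets; validate the centiloid calibration on a synthetic transfer
#' pair set; derive (or take as overrides) the early and established cutoffs;
#' classify subjects into the three-category continuum; delta-SUVR topography
#' on the regional datasets; longitudinal accumulation rates and progression;
#' tau association; visual-vs-quantitative concordance. Identical
#' configuration and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return An `analysis_report` list with one element per stage plus
#'   provenance (config hash, seed, dataset sizes).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  scenario <- config$scenario
  seed <- config$seed
  report <- list(provenance = list(
    seed = seed, scale = config$scale,
    config_hash = fnv1a_hash(list(scenario = scenario, scale = config$scale,
                                  overrides = config$cutoff_overrides)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  sim <- withCallingHandlers(simulate_scenario(scenario, seed),
                             warning = note)
  report$datasets <- lapply(
    sim[c("yhc", "ds2", "scd_suvr", "mci_suvr", "tau")],
    function(x) list(rows = nrow(x),
                     subjects = length(unique(x$subject_id))))

  if ("centiloid" %in% config$stages) {
    pairs <- synthesize_calibration_pairs(child_seed(seed, "calibration"))
    val <- validate_calibration(pairs)
    report$centiloid <- list(fits = val$fits, pass_flag = val$pass_flag)
  }

  cutoff_table <- NULL
  if ("cutoffs" %in% config$stages && is.null(config$cutoff_overrides)) {
    cons2 <- consensus_reads(sim$ds2)
    neg <- sim$ds2[sim$ds2$group_label == "eHC" & cons2 == 0, ]
    pos <- sim$ds2[sim$ds2$group_label == "AD" & cons2 == 1, ]
    cutoff_table <- withCallingHandlers(
      derive_cutoff_table(sim$yhc, neg, pos), warning = note)
    report$cutoffs <- cutoff_table
    mix <- withCallingHandlers(tryCatch(
      fit_mixture_confirmation(
        c(sim$yhc$cl_cortex, sim$ds2$cl_cortex,
          baseline_rows(sim$scd_cl)$cl_cortex,
          baseline_rows(sim$mci_cl)$cl_cortex, sim$tau$cl_cortex),
        seed = child_seed(seed, "mixture")),
      error = function(e) NULL), warning = note)
    if (!is.null(mix)) {
      report$mixture_confirmation <- mix[c("means", "sds", "weight",
                                           "early_cutoff", "estab_cutoff")]
    }
  } else if (!is.null(config$cutoff_overrides)) {
    report$cutoffs <- list(method = "override",
                           overrides = config$cutoff_overrides)
  }
  cuts <- operative_cutoffs(config, cutoff_table)

  status_of <- function(cohort, sc) {
    value_col <- if (sc == "suvr") "suvr_composite" else "cl_cortex"
    b <- baseline_rows(cohort)
    stats::setNames(classify_amyloid(b[[value_col]], cuts[[sc]]$early,
                                     cuts[[sc]]$estab), b$subject_id)
  }

  if ("classify" %in% config$stages) {
    report$classification <- lapply(stats::setNames(nm = scales_of(config)),
      function(sc) {
        pool <- list(yhc = sim$yhc, ds2 = sim$ds2,
                     scd = if (sc == "suvr") sim$scd_suvr else sim$scd_cl,
                     mci = if (sc == "suvr") sim$mci_suvr else sim$mci_cl,
                     tau = if (sc == "cl") sim$tau else NULL)
        pool <- Filter(Negate(is.null), pool)
        pool <- Filter(function(x) {
          vc <- if (sc == "suvr") "suvr_composite" else "cl_cortex"
          vc %in% names(x) && !all(is.na(baseline_rows(x)[[vc]]))
        }, pool)
        lapply(pool, function(x) as.list(table(status_of(x, sc))))
      })
  }

  if ("topography" %in% config$stages) {
    anchors <- withCallingHandlers(group_anchors(sim$yhc,
      sim$ds2[sim$ds2$group_label == "AD", ]), warning = note)
    t50 <- compute_t50_reference(anchors)
    topo_cohort <- rbind(
      sim$yhc[c("subject_id", "dataset_id", "group_label", "visit_time",
                suvr_col(cortical_regions()), "suvr_composite")],
      sim$ds2[c("subject_id", "dataset_id", "group_label", "visit_time",
                suvr_col(cortical_regions()), "suvr_composite")])
    topo <- compute_delta_suvr(as_cohort_table(topo_cohort), t50)
    ranking <- withCallingHandlers(rank_regions_by_onset(topo),
                                   warning = note)
    report$topography <- list(
      t50_reference = as.list(t50), ranking = ranking,
      n_subjects = length(topo$subject_id))
    attr(report, "topography_result") <- topo
  }

  if ("longitudinal" %in% config$stages) {
    long <- list()
    for (sc in scales_of(config)) {
      rate_col <- if (sc == "suvr") "abeta_dep" else "alpha"
      for (ds in c("scd", "mci")) {
        cohort <- sim[[paste0(ds, "_", sc)]]
        est <- fit_cohort_slopes(cohort, scale = sc)
        st <- status_of(cohort, sc)
        long[[paste(ds, sc, sep = "_")]] <-
          summarize_category_rates(est, st, rate_col = rate_col)
      }
    }
    report$accumulation <- long
    report$progression <- summarize_progression(
      sim$mci_base, status_of(sim$mci_base, scales_of(config)[1]))
  }

  if ("tau" %in% config$stages) {
    report$tau_association <- list(
      spearman = correlate_amyloid_tau(sim$tau),
      by_category = compare_tau_by_category(sim$tau,
                                            status_of(sim$tau, "cl")))
  }

  if ("concordance" %in% config$stages) {
    conc <- list()
    for (sc in scales_of(config)) {
      value_col <- if (sc == "suvr") "suvr_composite" else "cl_cortex"
      pool <- list(sim$yhc, sim$ds2, sim$scd_base, sim$mci_base)
      pool <- Filter(function(x) {
        length(read_column_names(x)) > 0 && value_col %in% names(x)
      }, pool)
      common <- Reduce(intersect, lapply(pool, names))
      visual <- as_cohort_table(do.call(rbind, lapply(pool, `[`, common)))
      st <- status_of(visual, sc)
      conc[[sc]] <- list(
        positivity = positivity_by_category(visual, st),
        sweep = sweep_agreement(visual, value_col = value_col))
    }
    report$concordance <- conc
  }

  report$warnings <- warnings_log
  report$cutoffs_used <- lapply(cuts, function(x) x[c("early", "estab",
                                                      "scale")])
  class(report) <- "analysis_report"
  if (!is.null(config$outdir)) {
    write_report_files(report, sim, config$outdir)
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report (seed", x$provenance$seed, ", hash",
      x$provenance$config_hash, ")\n  sections:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  invisible(x)
}

write_report_files <- function(report, sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  common <- c("subject_id", "dataset_id", "group_label", "visit_time")
  all_cohorts <- list(sim$yhc, sim$ds2, sim$scd_suvr, sim$scd_cl,
                      sim$mci_suvr, sim$mci_cl, sim$mci_base, sim$tau)
  cols <- unique(unlist(lapply(all_cohorts, names)))
  filled <- lapply(all_cohorts, function(d) {
    d[setdiff(cols, names(d))] <- NA
    d[cols]
  })
  merged <- do.call(rbind, filled)
  merged <- merged[!duplicated(merged[c("subject_id", "visit_time")]), ]
  utils::write.csv(merged, file.path(outdir, "cohort.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(report$cutoffs) && is.data.frame(report$cutoffs)) {
    utils::write.csv(report$cutoffs, file.path(outdir, "cutoffs.csv"),
                     row.names = FALSE, na = "")
  }
  topo <- attr(report, "topography_result")
  if (!is.null(topo)) {
    dm <- cbind(subject_id = topo$subject_id,
                suvr_composite = topo$composite, topo$delta)
    utils::write.csv(dm, file.path(outdir, "delta_suvr_matrix.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(report$topography$ranking,
                     file.path(outdir, "region_ranking.csv"),
                     row.names = FALSE, na = "")
  }
  if (!is.null(report$accumulation)) {
    rates <- do.call(rbind, Map(cbind, sample_scale = names(report$accumulation),
                                report$accumulation))
    utils::write.csv(rates, file.path(outdir, "rates_by_category.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(report$progression, file.path(outdir, "progression.csv"),
                     row.names = FALSE, na = "")
  }
  if (!is.null(report$tau_association)) {
    utils::write.csv(report$tau_association$spearman,
                     file.path(outdir, "tau_association.csv"),
                     row.names = FALSE, na = "")
  }
  if (!is.null(report$concordance)) {
    for (sc in names(report$concordance)) {
      utils::write.csv(report$concordance[[sc]]$sweep,
                       file.path(outdir, paste0("concordance_sweep_", sc,
                                                ".csv")),
                       row.names = FALSE, na = "")
    }
  }
  write_report(report, file.path(outdir, "report.json"))
  invisible(outdir)
}

#' Write / read the JSON analysis report
#'
#' @param report An `analysis_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  attr(out, "topography_result") <- NULL
  out$schema_version <- "1.0"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read / write a scenario YAML file
#'
#' Scenario lists round-trip through YAML; data-frame components (the
#' baseline mixtures) are stored as column lists.
#'
#' @param path YAML file path.
#' @return `read_scenario()`: the scenario list. `write_scenario()`: `path`.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  for (nm in c("scd_mixture", "mci_mixture", "tau_cl_mixture")) {
    if (!is.null(sc[[nm]])) sc[[nm]] <- as.data.frame(sc[[nm]])
  }
  for (nm in c("yhc", "ehc", "ad")) {
    for (f in c("means", "sds", "cl")) {
      if (!is.null(sc[[nm]][[f]])) sc[[nm]][[f]] <- unlist(sc[[nm]][[f]])
    }
  }
  for (nm in c("reads", "progression")) {
    if (!is.null(sc[[nm]])) sc[[nm]] <- unlist(sc[[nm]])
  }
  if (!is.null(sc$trajectories)) {
    sc$trajectories <- lapply(sc$trajectories, function(p) {
      logistic_params(p$region, p$ns, p$k, p$r, p$t50)
    })
  }
  sc
}

#' @param scenario A scenario list.
#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  scenario$trajectories <- lapply(scenario$trajectories, unclass)
  # named atomic vectors must become maps, or YAML drops their names
  to_tree <- function(x) {
    if (is.data.frame(x)) x
    else if (is.list(x)) lapply(x, to_tree)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(to_tree(scenario), path)
  invisible(path)
}
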