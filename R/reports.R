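# Report assembly and pipeline entry points.
#
# `run_analysis()` drives the full analysis of an ingested trial (manifest
# CSV + per-patient series CSVs + optional biomarker CSV); `run_simulation()`
# generates a trial from a config, writes it to disk in the same layout,
# and analyses it. Every run directory receives a JSON manifest capturing
# the command, config, seed, inputs, outputs and package version, which
# suffices to reproduce the run.

# Arm-comparison table over the four burden outcomes (Table-2 shape).
arm_comparison_table <- function(trial, conf = 0.95, threshold = 65,
                                 method = "trapezoid") {
  outcomes <- c(`Number of hypotensive episodes, n` = "n_episodes",
                `Total time spent in hypotension, min` = "total_time_min",
                `Time in hypotension relative to surgical duration, %` =
                  "relative_time_pct",
                `Time-weighted average of hypotension, mmHg` = "twa_mmhg")
  rows <- lapply(seq_along(outcomes), function(i) {
    gc <- compare_arms(trial, outcomes[[i]], conf = conf,
                       threshold = threshold, method = method)
    data.frame(outcome = names(outcomes)[i],
               median_intervention = gc$median_intervention,
               iqr_intervention = gc$iqr_intervention,
               median_control = gc$median_control,
               iqr_control = gc$iqr_control,
               median_difference = gc$hl_difference,
               ci_low = gc$ci_low, ci_high = gc$ci_high,
               p_value = gc$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Correlation long table (Table-3 shape): burden outcomes x analytes.
correlation_table <- function(corr) {
  stopifnot(inherits(corr, "burden_correlations"))
  rows <- expand.grid(outcome = corr$outcomes, analyte = corr$analytes,
                      stringsAsFactors = FALSE)
  rows$rho <- mapply(function(o, a) corr$rho[o, a],
                     rows$outcome, rows$analyte)
  rows$p_value <- mapply(function(o, a) corr$p_value[o, a],
                         rows$outcome, rows$analyte)
  rows$n <- mapply(function(o, a) corr$n[o, a],
                   rows$outcome, rows$analyte)
  rows$significance <- ifelse(!is.finite(rows$p_value), "",
                              ifelse(rows$p_value < 0.001, "**",
                                     ifelse(rows$p_value < 0.05, "*", "")))
  rows
}

# Biomarker pre/post difference table (Table-4 shape).
biomarker_difference_table <- function(trial, conf = 0.95) {
  diffs <- group_biomarker_differences(trial, conf = conf)
  bm_pre <- delta_matrix(trial, "delta")  # ensures pairing
  arms <- vapply(trial$patients, function(p) p$arm, "")
  pre <- do.call(rbind, lapply(trial$patients, function(p)
    p$biomarkers_pre$values))
  post <- do.call(rbind, lapply(trial$patients, function(p)
    p$biomarkers_post$values))
  rows <- lapply(biomarker_analytes, function(a) {
    gi <- arms == "intervention"; gcn <- arms == "control"
    data.frame(analyte = a, units = biomarker_units()[[a]],
               pre_median_intervention = stats::median(pre[gi, a]),
               post_median_intervention = stats::median(post[gi, a]),
               pre_median_control = stats::median(pre[gcn, a]),
               post_median_control = stats::median(post[gcn, a]),
               median_difference = diffs[[a]]$hl_difference,
               ci_low = diffs[[a]]$ci_low, ci_high = diffs[[a]]$ci_high,
               p_value = diffs[[a]]$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_manifest <- function(out_dir, command, config, seeds, inputs,
                           outputs) {
  manifest <- list(
    command = command,
    config = config,
    seeds = seeds,
    inputs = inputs,
    outputs = outputs,
    tool = "hypoburden",
    version = as.character(utils::packageVersion("hypoburden")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

analysis_outputs <- function(trial, out_dir, conf, threshold, method,
                             value_mode) {
  bt <- burden_table(trial, threshold = threshold, method = method)
  utils::write.csv(bt, file.path(out_dir, "burden_per_patient.csv"),
                   row.names = FALSE)
  outputs <- "burden_per_patient.csv"
  arms <- vapply(trial$patients, function(p) p$arm, "")
  two_arms <- length(unique(arms)) == 2 && min(table(arms)) >= 2
  if (two_arms) {
    cmp <- arm_comparison_table(trial, conf = conf, threshold = threshold,
                                method = method)
    utils::write.csv(cmp, file.path(out_dir, "arm_comparison.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, "arm_comparison.csv")
  } else {
    writeLines("insufficient data: need >= 2 patients in each arm",
               file.path(out_dir, "arm_comparison_SKIPPED.txt"))
    outputs <- c(outputs, "arm_comparison_SKIPPED.txt")
  }
  has_bio <- all(vapply(trial$patients, function(p)
    !is.null(p$biomarkers_pre) && !is.null(p$biomarkers_post), NA))
  if (has_bio) {
    corr <- burden_correlations(trial, value_mode = value_mode,
                                threshold = threshold)
    utils::write.csv(correlation_table(corr),
                     file.path(out_dir, "burden_correlations.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, "burden_correlations.csv")
    if (two_arms) {
      utils::write.csv(biomarker_difference_table(trial, conf = conf),
                       file.path(out_dir, "biomarker_differences.csv"),
                       row.names = FALSE)
      outputs <- c(outputs, "biomarker_differences.csv")
    }
    jsonlite::write_json(
      list(burden = bt,
           correlations = correlation_table(corr)),
      file.path(out_dir, "analysis.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, "analysis.json")
  }
  outputs
}

#' Analyse an ingested trial
#'
#' Reads a trial (manifest CSV naming per-patient MAP series, optional wide
#' biomarker CSV), computes per-patient burden summaries, arm comparisons,
#' biomarker/burden correlations and biomarker differences, and writes
#' CSV/JSON reports plus a run manifest into `out_dir`.
#'
#' @param manifest_csv Trial manifest: `patient_id`, `arm`, `series_path`,
#'   optional `duration_min`.
#' @param out_dir Output directory (created if needed).
#' @param biomarker_csv Optional biomarker CSV (see [read_biomarkers()]).
#' @param threshold Hypotension threshold, mmHg.
#' @param method Area method (`"trapezoid"` or `"maxdepth_x_time"`).
#' @param value_mode Biomarker value mode for correlations (`"delta"` or
#'   `"post"`).
#' @param conf Confidence level.
#' @return Invisibly, the list of files written.
#' @export
run_analysis <- function(manifest_csv, out_dir, biomarker_csv = NULL,
                         threshold = 65, method = "trapezoid",
                         value_mode = "delta", conf = 0.95) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trial <- read_trial(manifest_csv, biomarker_csv)
  outputs <- analysis_outputs(trial, out_dir, conf, threshold, method,
                              value_mode)
  write_manifest(out_dir, "analyze",
                 config = list(threshold = threshold, method = method,
                               value_mode = value_mode, conf = conf),
                 seeds = NULL,
                 inputs = c(manifest_csv, biomarker_csv),
                 outputs = outputs)
  invisible(file.path(out_dir, outputs))
}

#' Simulate a trial and write the dataset plus its full analysis
#'
#' Writes per-patient MAP series CSVs, the trial manifest, the biomarker
#' CSV, the event log (JSON), the analysis reports, and a run manifest.
#'
#' @param config A [sim_config()] (or a YAML path readable by
#'   [read_sim_config()]).
#' @param out_dir Output directory.
#' @param seed Master seed (default `config$seed`).
#' @inheritParams run_analysis
#' @return Invisibly, the simulated [trial_dataset()].
#' @export
run_simulation <- function(config = sim_config(), out_dir,
                           seed = config$seed, threshold = config$threshold,
                           method = "trapezoid", value_mode = "delta",
                           conf = 0.95) {
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  dir.create(file.path(out_dir, "series"), recursive = TRUE,
             showWarnings = FALSE)
  trial <- simulate_trial(config, seed = seed)
  man <- data.frame(
    patient_id = vapply(trial$patients, function(p) p$patient_id, ""),
    arm = vapply(trial$patients, function(p) p$arm, ""),
    series_path = vapply(trial$patients, function(p)
      file.path("series", paste0(p$patient_id, ".csv")), ""),
    duration_min = vapply(trial$patients, function(p)
      p$series$duration_min, 0),
    stringsAsFactors = FALSE)
  for (p in trial$patients) {
    write_map_series(p$series,
                     file.path(out_dir, "series",
                               paste0(p$patient_id, ".csv")))
  }
  utils::write.csv(man, file.path(out_dir, "trial_manifest.csv"),
                   row.names = FALSE)
  write_biomarkers(trial, file.path(out_dir, "biomarkers.csv"))
  events <- lapply(trial$patients, function(p) p$events)
  names(events) <- man$patient_id
  jsonlite::write_json(events, file.path(out_dir, "event_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  outputs <- analysis_outputs(trial, out_dir, conf, threshold, method,
                              value_mode)
  cfg_out <- config
  cfg_out$rules <- unclass(cfg_out$rules)
  write_manifest(out_dir, "simulate", config = unclass(cfg_out),
                 seeds = list(master = seed), inputs = NULL,
                 outputs = c("trial_manifest.csv", "biomarkers.csv",
                             "event_log.json", outputs))
  invisible(trial)
}

#' Read or write a simulation configuration as YAML
#'
#' @param path YAML path.
#' @return `read_sim_config` returns a [sim_config()];
#'   `write_sim_config` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$rules)) raw$rules <- do.call(rule_config, raw$rules)
  for (nm in c("duration_median_min", "duration_sdlog")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$rules <- unclass(cfg$rules)
  cfg$duration_median_min <- as.list(cfg$duration_median_min)
  cfg$duration_sdlog <- as.list(cfg$duration_sdlog)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
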