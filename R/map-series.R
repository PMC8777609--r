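#' Construct a MAP time series for one surgery
#'
#' A `map_series` holds the beat-averaged mean arterial pressure (MAP) stream
#' for a single patient, nominally sampled every 20 s by the hemodynamic
#' monitor. Times are seconds from surgery start; values are MAP in mmHg.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing, first time >= 0.
#' @param values Numeric vector of MAP values in mmHg, finite and > 0.
#' @param patient_id Opaque patient identifier.
#' @param duration_min Surgery duration in minutes. Defaults to the last
#'   sample time; must cover the whole series.
#' @param nominal_step Expected sampling interval in seconds (default 20).
#'   Irregular spacing is permitted but flagged in the `irregular` attribute.
#'
#' @return An object of class `map_series` with fields `patient_id`, `times`,
#'   `values`, `duration_min`, `nominal_step`, `irregular`.
#' @export
#' @examples
#' s <- map_series(c(0, 20, 40), c(72, 70, 68), patient_id = "p1",
#'                 duration_min = 1)
#' s$values
map_series <- function(times, values, patient_id = "patient",
                       duration_min = NULL, nominal_step = 20) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) == 0L) {
    stop_hypoburden("MAP series is empty", "hypoburden_empty_series")
  }
  if (length(times) != length(values)) {
    stop_hypoburden("times and values must have equal length",
                    "hypoburden_format_error")
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop_hypoburden("times must be finite", "hypoburden_format_error")
  }
  if (any(diff(times) <= 0)) {
    stop_hypoburden("times must be strictly increasing",
                    "hypoburden_ordering_error")
  }
  if (times[1] < 0) {
    stop_hypoburden("first time must be >= 0", "hypoburden_ordering_error")
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values <= 0)) {
    stop_hypoburden("MAP values must be finite and > 0 mmHg",
                    "hypoburden_format_error")
  }
  if (is.null(duration_min)) duration_min <- times[length(times)] / 60
  assert_scalar_number(duration_min, "duration_min", positive = TRUE)
  if (times[length(times)] > duration_min * 60 + 1e-9) {
    stop_hypoburden("last sample time exceeds surgery duration",
                    "hypoburden_ordering_error")
  }
  irregular <- length(times) > 1L &&
    any(abs(diff(times) - nominal_step) > 1e-6)
  structure(
    list(patient_id = patient_id, times = times, values = values,
         duration_min = duration_min, nominal_step = nominal_step,
         irregular = irregular),
    class = "map_series"
  )
}

#' @export
print.map_series <- function(x, ...) {
  cat(sprintf(
    "MAP series for %s: %d samples over %.1f min (%.1f-%.1f mmHg)%s\n",
    x$patient_id, length(x$times), x$duration_min,
    min(x$values), max(x$values),
    if (x$irregular) " [irregular spacing]" else ""))
  invisible(x)
}

#' Read a MAP series from a delimited text file
#'
#' Expects a header with a time column (seconds) and a MAP column (mmHg).
#' Rows with a non-finite MAP are dropped; the drop count is reported as a
#' message and stored in the `dropped` attribute.
#'
#' @param path Path to the delimited file.
#' @param time_col,map_col Column names (defaults `time_s`, `map_mmhg`).
#' @param sep Field delimiter (default comma).
#' @param patient_id Identifier attached to the series.
#' @param duration_min Surgery duration in minutes (default: last time).
#' @param quiet Suppress the dropped-row message.
#' @return A validated [map_series()] object.
#' @export
read_map_series <- function(path, time_col = "time_s", map_col = "map_mmhg",
                            sep = ",", patient_id = NULL,
                            duration_min = NULL, quiet = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c(time_col, map_col) %in% names(df))) {
    stop_hypoburden(
      sprintf("file '%s' must contain columns '%s' and '%s'",
              path, time_col, map_col),
      "hypoburden_format_error")
  }
  tt <- as.numeric(df[[time_col]])
  vv <- as.numeric(df[[map_col]])
  keep <- is.finite(vv)
  dropped <- sum(!keep)
  if (dropped > 0 && !quiet) {
    message(sprintf("read_map_series: dropped %d row(s) with non-finite MAP",
                    dropped))
  }
  tt <- tt[keep]; vv <- vv[keep]
  if (length(tt) == 0L) {
    stop_hypoburden(sprintf("file '%s' is empty after cleaning", path),
                    "hypoburden_empty_series")
  }
  if (is.null(patient_id)) {
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  }
  s <- map_series(tt, vv, patient_id = patient_id,
                  duration_min = duration_min)
  attr(s, "dropped") <- dropped
  s
}

#' Write a MAP series to CSV
#'
#' @param series A [map_series()].
#' @param path Output path.
#' @param time_col,map_col Column names to write.
#' @return `path`, invisibly.
#' @export
write_map_series <- function(series, path, time_col = "time_s",
                             map_col = "map_mmhg") {
  stopifnot(inherits(series, "map_series"))
  df <- data.frame(series$times, series$values)
  names(df) <- c(time_col, map_col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Piecewise-linear evaluation of the MAP trace at arbitrary times within
# the sampled span.
map_at <- function(series, t) {
  stats::approx(series$times, series$values, xout = t, rule = 2)$y
}

#' Resample a MAP series onto a uniform grid
#'
#' Values are linearly interpolated onto a uniform grid from the first to the
#' last timestamp; both endpoints are preserved. The final grid point is the
#' last original timestamp even when the span is not a multiple of `step`.
#'
#' @param series A [map_series()].
#' @param step Grid step in seconds (> 0, smaller than the series span).
#' @return A [map_series()] on the uniform grid.
#' @export
resample_map_series <- function(series, step) {
  stopifnot(inherits(series, "map_series"))
  assert_scalar_number(step, "step", positive = TRUE)
  span <- series$times[length(series$times)] - series$times[1]
  if (length(series$times) > 1L && step > span) {
    stop_hypoburden("step exceeds the series span",
                    "hypoburden_degenerate_grid")
  }
  grid <- seq(series$times[1], series$times[length(series$times)], by = step)
  last <- series$times[length(series$times)]
  if (abs(grid[length(grid)] - last) > 1e-9) grid <- c(grid, last)
  map_series(grid, map_at(series, grid), patient_id = series$patient_id,
             duration_min = series$duration_min, nominal_step = step)
}

#' Assemble a two-arm trial dataset
#'
#' @param patients A list; each element a list with fields `patient_id`,
#'   `arm` (`"intervention"` or `"control"`), `series` (a [map_series()]),
#'   and optionally `biomarkers_pre` / `biomarkers_post`
#'   ([biomarker_panel()] at T0 and T2).
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(patients) {
  ids <- vapply(patients, function(p) as.character(p$patient_id), "")
  if (anyDuplicated(ids)) {
    stop_hypoburden("duplicate patient_id in trial", "hypoburden_format_error")
  }
  arms <- vapply(patients, function(p) as.character(p$arm), "")
  if (!all(arms %in% c("intervention", "control"))) {
    stop_hypoburden("arm must be 'intervention' or 'control'",
                    "hypoburden_format_error")
  }
  for (p in patients) stopifnot(inherits(p$series, "map_series"))
  structure(list(patients = patients), class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  arms <- vapply(x$patients, function(p) p$arm, "")
  cat(sprintf("Two-arm trial: %d patients (%d intervention, %d control)\n",
              length(arms), sum(arms == "intervention"),
              sum(arms == "control")))
  invisible(x)
}

#' Read a trial from a manifest CSV
#'
#' The manifest names one patient per row: `patient_id`, `arm`,
#' `series_path` (relative paths resolved against the manifest directory)
#' and optionally `duration_min`. Biomarker panels, if any, are supplied
#' separately via [read_biomarkers()].
#'
#' @param manifest_csv Path to the manifest.
#' @param biomarker_csv Optional wide biomarker CSV (see [read_biomarkers()]).
#' @return A [trial_dataset()].
#' @export
read_trial <- function(manifest_csv, biomarker_csv = NULL) {
  man <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "series_path")
  if (!all(need %in% names(man))) {
    stop_hypoburden("manifest must have patient_id, arm, series_path",
                    "hypoburden_format_error")
  }
  base <- dirname(normalizePath(manifest_csv))
  panels <- if (!is.null(biomarker_csv)) read_biomarkers(biomarker_csv)
  patients <- lapply(seq_len(nrow(man)), function(i) {
    sp <- man$series_path[i]
    if (!file.exists(sp)) sp <- file.path(base, sp)
    dur <- if ("duration_min" %in% names(man)) man$duration_min[i]
    s <- read_map_series(sp, patient_id = man$patient_id[i],
                         duration_min = dur, quiet = TRUE)
    p <- list(patient_id = man$patient_id[i], arm = man$arm[i], series = s)
    if (!is.null(panels)) {
      key <- as.character(man$patient_id[i])
      p$biomarkers_pre <- panels$pre[[key]]
      p$biomarkers_post <- panels$post[[key]]
    }
    p
  })
  trial_dataset(patients)
}
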