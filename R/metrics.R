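# Hypotension burden metrics on the piecewise-linear MAP trace.
#
# All quantities treat the sampled MAP stream as a continuous piecewise-linear
# function of time; threshold crossings are located exactly by interpolation
# between samples. MAP exactly equal to the threshold is NOT hypotension
# (the strict "< 65 mmHg" convention).

# Refine the trace so every threshold crossing is a breakpoint. Returns
# times, values, and a logical `below` per segment (between breakpoints).
refine_at_threshold <- function(series, threshold) {
  t <- series$times; v <- series$values
  n <- length(t)
  if (n == 1L) {
    return(list(times = t, values = v, below = logical(0)))
  }
  v0 <- v[-n]; v1 <- v[-1]
  cross <- which((v0 - threshold) * (v1 - threshold) < 0)
  tc <- t[cross] + (threshold - v[cross]) / (v[cross + 1L] - v[cross]) *
    (t[cross + 1L] - t[cross])
  ord <- order(c(t, tc))
  tt <- c(t, tc)[ord]
  vv <- c(v, rep(threshold, length(tc)))[ord]
  mid <- (vv[-length(vv)] + vv[-1]) / 2
  list(times = tt, values = vv, below = mid < threshold)
}

#' Detect hypotensive episodes in a MAP series
#'
#' An episode is a maximal contiguous interval with MAP below the threshold
#' on the piecewise-linear trace. Crossing times are exact (linear
#' interpolation between samples). Episodes shorter than `min_duration` are
#' discarded, then episodes separated by a gap shorter than `merge_gap` are
#' merged.
#'
#' @param series A [map_series()].
#' @param threshold Hypotension threshold in mmHg (default 65; MAP strictly
#'   below counts).
#' @param min_duration Minimum episode duration in seconds (default 0).
#' @param merge_gap Gaps shorter than this many seconds between consecutive
#'   episodes are merged into one episode (default 0: never merge).
#' @return A data.frame with one row per episode: `start` and `end`
#'   (seconds), `duration` (minutes), `nadir` (mmHg), `max_depth`
#'   (mmHg below threshold).
#' @export
#' @examples
#' s <- map_series(c(0, 60, 120), c(70, 60, 70), duration_min = 2)
#' detect_episodes(s, threshold = 65)
detect_episodes <- function(series, threshold = 65, min_duration = 0,
                            merge_gap = 0) {
  stopifnot(inherits(series, "map_series"))
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  r <- refine_at_threshold(series, threshold)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), nadir = numeric(0),
                      max_depth = numeric(0))
  if (!any(r$below)) return(empty)
  runs <- rle(r$below)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  keep <- which(runs$values)
  eps <- data.frame(
    start = r$times[idx_start[keep]],
    end = r$times[idx_end[keep] + 1L]
  )
  eps$nadir <- vapply(seq_len(nrow(eps)), function(k) {
    sel <- r$times >= eps$start[k] & r$times <= eps$end[k]
    min(r$values[sel])
  }, 0)
  if (min_duration > 0) {
    eps <- eps[eps$end - eps$start >= min_duration, , drop = FALSE]
  }
  if (merge_gap > 0 && nrow(eps) > 1L) {
    merged <- eps[1, , drop = FALSE]
    for (k in 2:nrow(eps)) {
      if (eps$start[k] - merged$end[nrow(merged)] < merge_gap) {
        merged$end[nrow(merged)] <- eps$end[k]
        merged$nadir[nrow(merged)] <-
          min(merged$nadir[nrow(merged)], eps$nadir[k])
      } else {
        merged <- rbind(merged, eps[k, , drop = FALSE])
      }
    }
    eps <- merged
  }
  if (nrow(eps) == 0L) return(empty)
  eps$duration <- (eps$end - eps$start) / 60
  eps$max_depth <- threshold - eps$nadir
  rownames(eps) <- NULL
  eps[, c("start", "end", "duration", "nadir", "max_depth")]
}

# Time (minutes) spent strictly below threshold on the piecewise-linear trace.
time_below_threshold <- function(series, threshold = 65) {
  r <- refine_at_threshold(series, threshold)
  if (!length(r$below)) return(0)
  sum(diff(r$times)[r$below]) / 60
}

#' Area under the hypotension threshold
#'
#' Two methods are provided. `"trapezoid"` integrates the deficit
#' `max(0, threshold - MAP(t))` over time on the piecewise-linear trace (the
#' true area under the threshold). `"maxdepth_x_time"` follows the common
#' bedside shorthand: (threshold - global nadir) x total time below
#' threshold. The two coincide when every hypotensive excursion sits at a
#' constant depth; otherwise the trapezoid area is smaller.
#'
#' @param series A [map_series()].
#' @param threshold Threshold in mmHg (default 65).
#' @param method `"trapezoid"` (default) or `"maxdepth_x_time"`.
#' @return Area in mmHg.min.
#' @export
area_under_threshold <- function(series, threshold = 65,
                                 method = c("trapezoid", "maxdepth_x_time")) {
  stopifnot(inherits(series, "map_series"))
  method <- match.arg(method)
  r <- refine_at_threshold(series, threshold)
  if (!any(r$below)) return(0)
  if (method == "trapezoid") {
    d <- pmax(0, threshold - r$values)
    seg <- (d[-length(d)] + d[-1]) / 2 * diff(r$times)
    sum(seg[r$below]) / 60
  } else {
    depth <- threshold - min(r$values)
    depth * time_below_threshold(series, threshold)
  }
}

#' Summarize hypotension burden for one surgery
#'
#' Bundles the four burden outcomes: number of hypotensive episodes,
#' absolute time in hypotension (min), time in hypotension relative to
#' surgical duration (%), area under the threshold (mmHg.min), and the
#' time-weighted average (TWA) of hypotension, defined as area under the
#' threshold divided by total surgery duration (mmHg).
#'
#' @inheritParams detect_episodes
#' @param method Area method passed to [area_under_threshold()].
#' @return An object of class `hypo_summary` (also a list) with fields
#'   `n_episodes`, `total_time_min`, `relative_time_pct`, `area_mmhg_min`,
#'   `twa_mmhg`, `threshold`, `duration_min`, `episodes` (data.frame).
#' @export
#' @examples
#' s <- map_series(c(0, 60, 120), c(70, 60, 70), duration_min = 100)
#' hypo_summary(s)
hypo_summary <- function(series, threshold = 65,
                         method = c("trapezoid", "maxdepth_x_time"),
                         min_duration = 0, merge_gap = 0) {
  stopifnot(inherits(series, "map_series"))
  method <- match.arg(method)
  if (series$duration_min <= 0) {
    stop_hypoburden("surgery duration must be > 0",
                    "hypoburden_degenerate_input")
  }
  eps <- detect_episodes(series, threshold, min_duration, merge_gap)
  total <- time_below_threshold(series, threshold)
  area <- area_under_threshold(series, threshold, method)
  structure(
    list(n_episodes = nrow(eps),
         total_time_min = total,
         relative_time_pct = 100 * total / series$duration_min,
         area_mmhg_min = area,
         twa_mmhg = area / series$duration_min,
         threshold = threshold,
         duration_min = series$duration_min,
         method = method,
         episodes = eps),
    class = "hypo_summary"
  )
}

#' @export
print.hypo_summary <- function(x, ...) {
  cat(sprintf("Hypotension burden (MAP < %g mmHg), %.0f-min surgery:\n",
              x$threshold, x$duration_min))
  cat(sprintf("  episodes: %d | time: %.2f min (%.2f%%) | area: %.2f mmHg.min | TWA: %.3f mmHg\n",
              x$n_episodes, x$total_time_min, x$relative_time_pct,
              x$area_mmhg_min, x$twa_mmhg))
  invisible(x)
}

#' Per-patient burden table for a trial
#'
#' @param trial A [trial_dataset()].
#' @inheritParams hypo_summary
#' @return A data.frame with one row per patient: `patient_id`, `arm`, the
#'   four burden outcomes, and `duration_min`.
#' @export
burden_table <- function(trial, threshold = 65,
                         method = c("trapezoid", "maxdepth_x_time")) {
  stopifnot(inherits(trial, "trial_dataset"))
  method <- match.arg(method)
  rows <- lapply(trial$patients, function(p) {
    s <- hypo_summary(p$series, threshold = threshold, method = method)
    data.frame(patient_id = as.character(p$patient_id), arm = p$arm,
               n_episodes = s$n_episodes,
               total_time_min = s$total_time_min,
               relative_time_pct = s$relative_time_pct,
               area_mmhg_min = s$area_mmhg_min,
               twa_mmhg = s$twa_mmhg,
               duration_min = s$duration_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
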