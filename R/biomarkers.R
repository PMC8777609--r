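# Biomarker panels and their association with hypotension burden.
#
# The eight analytes: NGAL (kidney injury), NSE and S100B (brain injury),
# HIF-1a (hypoxia signalling), acetyl-CoA (metabolic rewiring), hs troponin
# (myocardial injury), LOOH (lipid peroxidation), GSH (antioxidant reserve).
# Panels are drawn pre-induction (T0) and at the end of surgery (T2).

biomarker_analytes <- c("ngal", "nse", "hif1a", "s100b", "acetyl_coa",
                        "hs_troponin", "looh", "gsh")

#' Names and units of the biomarker panel
#'
#' @return Named character vector mapping analyte field names to units.
#' @export
biomarker_units <- function() {
  c(ngal = "ng/mL", nse = "ng/mL", hif1a = "ng/mL", s100b = "pg/mL",
    acetyl_coa = "pmol/uL", hs_troponin = "pg/mL", looh = "nmol/uL",
    gsh = "nmol/uL")
}

#' Construct a biomarker panel at one time point
#'
#' @param values Named numeric vector (or list) covering the eight analytes
#'   `ngal`, `nse`, `hif1a`, `s100b`, `acetyl_coa`, `hs_troponin`, `looh`,
#'   `gsh`; all concentrations finite and >= 0.
#' @param timepoint `"T0"` (pre-induction) or `"T2"` (end of surgery).
#' @param patient_id Optional identifier used for pairing checks.
#' @return A list of class `biomarker_panel`.
#' @export
biomarker_panel <- function(values, timepoint = c("T0", "T2"),
                            patient_id = NULL) {
  timepoint <- match.arg(timepoint)
  values <- unlist(values)
  if (!all(biomarker_analytes %in% names(values))) {
    stop_hypoburden("panel must name all eight analytes",
                    "hypoburden_format_error")
  }
  values <- values[biomarker_analytes]
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_hypoburden("concentrations must be finite and >= 0",
                    "hypoburden_format_error")
  }
  structure(list(values = values, timepoint = timepoint,
                 patient_id = patient_id),
            class = "biomarker_panel")
}

#' Pre/post biomarker change for one patient
#'
#' Elementwise T2 minus T0 concentrations.
#'
#' @param pre Panel at T0.
#' @param post Panel at T2 for the same patient.
#' @return Named numeric vector of per-analyte deltas.
#' @export
#' @examples
#' v <- c(ngal = 2, nse = 2, hif1a = 0.2, s100b = 0.4, acetyl_coa = 0.1,
#'        hs_troponin = 40, looh = 5, gsh = 7.5)
#' pre <- biomarker_panel(v, "T0")
#' post <- biomarker_panel(replace(v, "gsh", 7.0), "T2")
#' compute_deltas(pre, post)["gsh"]
compute_deltas <- function(pre, post) {
  stopifnot(inherits(pre, "biomarker_panel"),
            inherits(post, "biomarker_panel"))
  if (pre$timepoint != "T0" || post$timepoint != "T2") {
    stop_hypoburden("pre must be T0 and post must be T2",
                    "hypoburden_pairing_error")
  }
  if (!is.null(pre$patient_id) && !is.null(post$patient_id) &&
      !identical(pre$patient_id, post$patient_id)) {
    stop_hypoburden("panels belong to different patients",
                    "hypoburden_pairing_error")
  }
  post$values - pre$values
}

# Per-patient delta (or post-value) matrix for a trial; rows = patients.
delta_matrix <- function(trial, value_mode = c("delta", "post")) {
  value_mode <- match.arg(value_mode)
  rows <- lapply(trial$patients, function(p) {
    if (is.null(p$biomarkers_pre) || is.null(p$biomarkers_post)) {
      return(rep(NA_real_, length(biomarker_analytes)))
    }
    if (value_mode == "delta") {
      compute_deltas(p$biomarkers_pre, p$biomarkers_post)
    } else {
      p$biomarkers_post$values
    }
  })
  m <- do.call(rbind, rows)
  colnames(m) <- biomarker_analytes
  rownames(m) <- vapply(trial$patients, function(p)
    as.character(p$patient_id), "")
  m
}

#' Spearman correlations of biomarkers with hypotension burden
#'
#' Computes the full Spearman matrix over the eight analytes and the four
#' burden outcomes across all patients (arms pooled). By default analyte
#' values enter as T2 minus T0 deltas, isolating the intraoperative change;
#' `value_mode = "post"` uses raw T2 values instead. Cells with fewer than 3
#' complete pairs are `NA`.
#'
#' @param trial A [trial_dataset()] whose patients carry biomarker panels.
#' @param value_mode `"delta"` (default) or `"post"`.
#' @param threshold Hypotension threshold in mmHg.
#' @return A list of class `burden_correlations` with matrices `rho` and
#'   `p_value` (rows: analytes then burden outcomes; columns the same), and
#'   `n` (pair counts).
#' @export
burden_correlations <- function(trial, value_mode = c("delta", "post"),
                                threshold = 65) {
  stopifnot(inherits(trial, "trial_dataset"))
  value_mode <- match.arg(value_mode)
  bm <- delta_matrix(trial, value_mode)
  bt <- burden_table(trial, threshold = threshold)
  burden_cols <- c("n_episodes", "total_time_min", "relative_time_pct",
                   "twa_mmhg")
  dat <- cbind(bm, as.matrix(bt[, burden_cols]))
  vars <- colnames(dat)
  k <- length(vars)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  npair <- matrix(0L, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- is.finite(dat[, i]) & is.finite(dat[, j])
      npair[i, j] <- sum(ok)
      if (i == j) { rho[i, j] <- 1; p[i, j] <- 0; next }
      if (sum(ok) < 3) next
      if (length(unique(dat[ok, i])) == 1L ||
          length(unique(dat[ok, j])) == 1L) next
      sc <- spearman_cor(dat[ok, i], dat[ok, j])
      rho[i, j] <- sc$rho; p[i, j] <- sc$p_value
    }
  }
  structure(list(rho = rho, p_value = p, n = npair,
                 analytes = biomarker_analytes, outcomes = burden_cols,
                 value_mode = value_mode),
            class = "burden_correlations")
}

#' @export
print.burden_correlations <- function(x, digits = 3, ...) {
  cat(sprintf("Spearman correlations (%s values) x burden outcomes:\n",
              x$value_mode))
  print(round(x$rho[x$outcomes, x$analytes, drop = FALSE], digits))
  invisible(x)
}

#' Between-arm differences of biomarker changes
#'
#' For each analyte, the Hodges-Lehmann difference of per-patient T2-T0
#' deltas, intervention minus control, with confidence interval and
#' Mann-Whitney p-value.
#'
#' @param trial A [trial_dataset()] with paired panels for every patient.
#' @param conf Confidence level (default 0.95).
#' @return Named list of `group_comparison` objects, one per analyte.
#' @export
group_biomarker_differences <- function(trial, conf = 0.95) {
  stopifnot(inherits(trial, "trial_dataset"))
  bm <- delta_matrix(trial, "delta")
  if (any(!is.finite(bm))) {
    stop_hypoburden("every patient needs paired T0/T2 panels",
                    "hypoburden_pairing_error")
  }
  arms <- vapply(trial$patients, function(p) p$arm, "")
  out <- lapply(biomarker_analytes, function(a) {
    group_comparison_values(bm[arms == "intervention", a],
                            bm[arms == "control", a],
                            a, conf = conf)
  })
  names(out) <- biomarker_analytes
  out
}

#' Read biomarker panels from a wide CSV
#'
#' Expects columns `patient_id`, `timepoint` (T0/T2) and the eight analyte
#' columns named as in [biomarker_units()].
#'
#' @param path CSV path.
#' @return A list with named lists `pre` and `post` of [biomarker_panel()]s
#'   keyed by patient id.
#' @export
read_biomarkers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", biomarker_analytes)
  if (!all(need %in% names(df))) {
    stop_hypoburden("biomarker CSV missing required columns",
                    "hypoburden_format_error")
  }
  pre <- list(); post <- list()
  for (i in seq_len(nrow(df))) {
    pan <- biomarker_panel(as.numeric(df[i, biomarker_analytes]) |>
                             stats::setNames(biomarker_analytes),
                           timepoint = df$timepoint[i],
                           patient_id = as.character(df$patient_id[i]))
    key <- as.character(df$patient_id[i])
    if (df$timepoint[i] == "T0") pre[[key]] <- pan else post[[key]] <- pan
  }
  list(pre = pre, post = post)
}

#' Write trial biomarker panels to a wide CSV
#'
#' @param trial A [trial_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_biomarkers <- function(trial, path) {
  rows <- list()
  for (p in trial$patients) {
    for (tp in c("pre", "post")) {
      pan <- p[[paste0("biomarkers_", tp)]]
      if (is.null(pan)) next
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = as.character(p$patient_id),
        timepoint = pan$timepoint,
        t(pan$values), stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
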