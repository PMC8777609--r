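# Synthetic two-arm trial generator.
#
# MAP trajectories follow a mean-reverting (AR(1)/Ornstein-Uhlenbeck)
# background around an intraoperative baseline, perturbed by hypotensive
# stress events arriving as a Poisson process. Each event pulls MAP down in
# a triangular pulse of drawn depth and duration. In the intervention arm
# an impending event is alerted ahead of its nadir with a configurable
# sensitivity; an alerted event is averted with the treatment-efficacy
# probability (the proactive policy call is recorded in the event log).
# Established hypotension is treated reactively in both arms, which
# shortens the recovery limb of the pulse but does not avert the episode.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: two arms of
#' 20 patients, permuted blocks of 4 and 6, surgery durations lognormal
#' around medians of 207 (intervention) and 237 (control) minutes, a 20 s
#' MAP sampling cadence, alerting 300 s ahead with 85% sensitivity, and a
#' control/intervention hypotension incidence of 80% / 38%. `event_rate`
#' and `treatment_efficacy` defaults were fixed by a one-off root-finding
#' calibration of the incidence targets and are not meant to be tuned
#' per run.
#'
#' @param n_per_arm Patients per arm.
#' @param block_sizes Permuted block sizes (even, 1:1 within block).
#' @param duration_median_min,duration_sdlog Lognormal surgery-duration
#'   parameters per arm (minutes; named `intervention`, `control`).
#' @param sampling_step MAP sampling interval, seconds.
#' @param baseline_map Intraoperative baseline MAP, mmHg.
#' @param reversion_rate Mean-reversion rate of the background process,
#'   1/seconds.
#' @param noise_sd Stationary SD of the background process, mmHg.
#' @param event_rate Hypotensive stress events per hour.
#' @param event_depth_shape,event_depth_mean Gamma depth distribution
#'   (mmHg).
#' @param event_duration_median_min,event_duration_sdlog Lognormal full
#'   event duration (minutes).
#' @param threshold Hypotension threshold, mmHg.
#' @param control_incidence,intervention_incidence Target probabilities of
#'   at least one episode (informational; encoded by the calibrated
#'   defaults).
#' @param alert_sensitivity Probability an impending event raises an alert.
#' @param alert_lead Seconds before the event nadir at which the alert
#'   fires.
#' @param treatment_efficacy Probability an alerted event is averted.
#' @param reactive_attenuation Factor (< 1) shrinking the recovery limb of
#'   an established hypotensive event under reactive treatment.
#' @param rules A [rule_config()] for the policy calls.
#' @param biomarker_baseline Per-analyte lognormal baseline (`median`,
#'   `sdlog`).
#' @param biomarker_model Per-analyte response: `metric` (burden outcome
#'   driving the change), `slope` (analyte units per metric unit), `drift`
#'   (burden-independent mean change), `noise_sd`.
#' @param seed Master seed; per-patient substreams are derived from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_arm = 20,
                       block_sizes = c(4, 6),
                       duration_median_min = c(intervention = 207,
                                               control = 237),
                       duration_sdlog = c(intervention = 0.228,
                                          control = 0.374),
                       sampling_step = 20,
                       baseline_map = 73,
                       reversion_rate = 1 / 120,
                       noise_sd = 2,
                       event_rate = 0.585,
                       event_depth_shape = 3,
                       event_depth_mean = 12,
                       event_duration_median_min = 10,
                       event_duration_sdlog = 0.5,
                       threshold = 65,
                       control_incidence = 0.80,
                       intervention_incidence = 0.38,
                       alert_sensitivity = 0.85,
                       alert_lead = 300,
                       treatment_efficacy = 0.804,
                       reactive_attenuation = 0.5,
                       rules = rule_config(),
                       biomarker_baseline = default_biomarker_baseline(),
                       biomarker_model = default_biomarker_model(),
                       seed = 20220113) {
  cfg <- list(n_per_arm = n_per_arm, block_sizes = block_sizes,
              duration_median_min = duration_median_min,
              duration_sdlog = duration_sdlog,
              sampling_step = sampling_step, baseline_map = baseline_map,
              reversion_rate = reversion_rate, noise_sd = noise_sd,
              event_rate = event_rate,
              event_depth_shape = event_depth_shape,
              event_depth_mean = event_depth_mean,
              event_duration_median_min = event_duration_median_min,
              event_duration_sdlog = event_duration_sdlog,
              threshold = threshold,
              control_incidence = control_incidence,
              intervention_incidence = intervention_incidence,
              alert_sensitivity = alert_sensitivity,
              alert_lead = alert_lead,
              treatment_efficacy = treatment_efficacy,
              reactive_attenuation = reactive_attenuation,
              rules = rules,
              biomarker_baseline = biomarker_baseline,
              biomarker_model = biomarker_model,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c("control_incidence", "intervention_incidence",
             "alert_sensitivity", "treatment_efficacy",
             "reactive_attenuation")
  for (nm in probs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop_hypoburden(sprintf("`%s` must be a probability in [0, 1]", nm),
                      "hypoburden_config_error")
    }
  }
  for (nm in c("sampling_step", "baseline_map", "reversion_rate",
               "event_depth_shape", "event_depth_mean",
               "event_duration_median_min", "threshold")) {
    assert_scalar_number(cfg[[nm]], nm, positive = TRUE)
  }
  for (nm in c("noise_sd", "event_rate", "alert_lead",
               "event_duration_sdlog")) {
    v <- assert_scalar_number(cfg[[nm]], nm)
    if (v < 0) stop_hypoburden(sprintf("`%s` must be >= 0", nm),
                               "hypoburden_config_error")
  }
  if (cfg$n_per_arm < 1 || cfg$n_per_arm != round(cfg$n_per_arm)) {
    stop_hypoburden("n_per_arm must be a positive integer",
                    "hypoburden_config_error")
  }
  if (any(cfg$block_sizes %% 2 != 0) || any(cfg$block_sizes <= 0)) {
    stop_hypoburden("block sizes must be positive and even",
                    "hypoburden_config_error")
  }
  invisible(cfg)
}

default_biomarker_baseline <- function() {
  list(ngal = c(median = 2.1, sdlog = 0.50),
       nse = c(median = 2.0, sdlog = 0.55),
       hif1a = c(median = 0.17, sdlog = 0.45),
       s100b = c(median = 0.34, sdlog = 0.60),
       acetyl_coa = c(median = 0.13, sdlog = 0.80),
       hs_troponin = c(median = 37, sdlog = 0.55),
       looh = c(median = 5.2, sdlog = 0.70),
       gsh = c(median = 7.2, sdlog = 0.50))
}

default_biomarker_model <- function() {
  list(ngal = list(metric = "twa_mmhg", slope = 1.55, drift = 0.0,
                   noise_sd = 0.45),
       nse = list(metric = "twa_mmhg", slope = 2.0, drift = -0.5,
                  noise_sd = 0.70),
       hif1a = list(metric = "twa_mmhg", slope = 0, drift = -0.01,
                    noise_sd = 0.04),
       s100b = list(metric = "n_episodes", slope = 0.252, drift = 0.3,
                    noise_sd = 0.50),
       acetyl_coa = list(metric = "twa_mmhg", slope = 0, drift = 0.15,
                         noise_sd = 0.15),
       hs_troponin = list(metric = "twa_mmhg", slope = 0, drift = -2,
                          noise_sd = 12),
       looh = list(metric = "twa_mmhg", slope = 0, drift = -0.3,
                   noise_sd = 2.0),
       gsh = list(metric = "twa_mmhg", slope = -5.0, drift = -0.5,
                  noise_sd = 2.2))
}

#' Permuted-block randomization
#'
#' Draws a random sequence of block sizes summing exactly to `n_total`
#' (uniform over the configured sizes, by rejection) and permutes a
#' balanced 1:1 assignment within each block. Deterministic given `seed`.
#'
#' @param n_total Total number of patients.
#' @param block_sizes Even block sizes (default 4 and 6).
#' @param seed Integer seed.
#' @return Character vector of length `n_total` with values
#'   `"intervention"` / `"control"`, with the block-size sequence in the
#'   `blocks` attribute.
#' @export
#' @examples
#' table(randomize_blocks(40, c(4, 6), seed = 1))
randomize_blocks <- function(n_total, block_sizes = c(4, 6), seed = 1) {
  if (any(block_sizes %% 2 != 0) || any(block_sizes <= 0)) {
    stop_hypoburden("block sizes must be positive and even",
                    "hypoburden_config_error")
  }
  if (n_total < min(block_sizes)) {
    stop_hypoburden("n_total smaller than the smallest block",
                    "hypoburden_config_error")
  }
  with_seed(seed, {
    blocks <- NULL
    for (try in 1:100000) {
      blocks <- integer(0)
      remaining <- n_total
      while (remaining > 0) {
        feasible <- block_sizes[block_sizes <= remaining]
        if (!length(feasible)) break
        b <- if (length(feasible) == 1L) feasible else sample(feasible, 1L)
        blocks <- c(blocks, b)
        remaining <- remaining - b
      }
      if (remaining == 0) break
      blocks <- NULL
    }
    if (is.null(blocks)) {
      stop_hypoburden("block sizes cannot sum to n_total",
                      "hypoburden_config_error")
    }
    arms <- unlist(lapply(blocks, function(b) {
      sample(rep(c("intervention", "control"), b / 2))
    }))
    attr(arms, "blocks") <- blocks
    arms
  })
}

#' Simulate one surgery's MAP trajectory
#'
#' @param arm `"intervention"` or `"control"`.
#' @param config A [sim_config()].
#' @param seed Integer seed for this surgery (derive per-patient seeds from
#'   the master seed with distinct indices).
#' @param patient_id Identifier for the returned series.
#' @return A list with `series` (a [map_series()]) and `events` (a
#'   data.frame logging every stress event: nadir `time` in seconds,
#'   `depth` mmHg, `duration_min`, `alerted`, `averted`, policy `action`,
#'   `trigger`).
#' @export
simulate_surgery <- function(arm = c("control", "intervention"),
                             config = sim_config(), seed = 1,
                             patient_id = "sim") {
  arm <- match.arg(arm)
  validate_sim_config(config)
  with_seed(seed, {
    dur_min <- stats::rlnorm(1, log(config$duration_median_min[[arm]]),
                             config$duration_sdlog[[arm]])
    dur_sec <- max(config$sampling_step * 10, dur_min * 60)
    dur_min <- dur_sec / 60
    t <- seq(0, dur_sec, by = config$sampling_step)
    n <- length(t)

    # mean-reverting background (exact AR(1) discretization of OU)
    phi <- exp(-config$reversion_rate * config$sampling_step)
    innov_sd <- config$noise_sd * sqrt(1 - phi^2)
    x0 <- stats::rnorm(1, 0, config$noise_sd)
    bg <- if (config$noise_sd == 0) rep(0, n) else {
      as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                               method = "recursive", init = x0))
    }

    n_ev <- stats::rpois(1, config$event_rate * dur_sec / 3600)
    ev <- data.frame(time = numeric(0), depth = numeric(0),
                     duration_min = numeric(0), alerted = logical(0),
                     averted = logical(0), action = character(0),
                     trigger = character(0))
    dip <- rep(0, n)
    if (n_ev > 0) {
      te <- sort(stats::runif(n_ev, 0, dur_sec))
      depth <- stats::rgamma(n_ev, shape = config$event_depth_shape,
                             scale = config$event_depth_mean /
                               config$event_depth_shape)
      edur <- stats::rlnorm(n_ev, log(config$event_duration_median_min),
                            config$event_duration_sdlog) * 60
      alerted <- rep(FALSE, n_ev); averted <- rep(FALSE, n_ev)
      action <- rep(NA_character_, n_ev)
      trigger <- rep(NA_character_, n_ev)
      for (k in seq_len(n_ev)) {
        # does this event, alone, establish hypotension?
        crosses <- config$baseline_map - depth[k] < config$threshold
        if (arm == "intervention") {
          alerted[k] <- stats::runif(1) < config$alert_sensitivity
          if (alerted[k]) {
            state <- hemodynamic_state(
              map = config$baseline_map,
              hpi = stats::runif(1, config$rules$alert_threshold + 1, 100),
              svv = stats::rlnorm(1, log(12), 0.35),
              eadyn = stats::rlnorm(1, log(1.0), 0.25),
              dpdt_max = stats::rlnorm(1, log(900), 0.30))
            rec <- proactive_policy(state, config$rules)
            action[k] <- rec$action; trigger[k] <- rec$trigger
            averted[k] <- stats::runif(1) < config$treatment_efficacy
          }
        }
        if (averted[k]) next
        w <- edur[k] / 2
        w_up <- if (crosses) w * config$reactive_attenuation else w
        if (crosses) {
          state <- hemodynamic_state(
            map = config$baseline_map - depth[k],
            hpi = 0,
            svv = stats::rlnorm(1, log(12), 0.35),
            eadyn = stats::rlnorm(1, log(1.0), 0.25),
            dpdt_max = stats::rlnorm(1, log(900), 0.30))
          rec <- reactive_policy(state, config$rules)
          if (is.na(trigger[k])) {          # keep a proactive call if logged
            action[k] <- rec$action; trigger[k] <- rec$trigger
          }
        }
        rel <- t - te[k]
        shape <- ifelse(rel <= 0, pmax(0, 1 + rel / w),
                        pmax(0, 1 - rel / w_up))
        dip <- dip + depth[k] * shape
      }
      ev <- data.frame(time = te, depth = depth, duration_min = edur / 60,
                       alerted = alerted, averted = averted,
                       action = action, trigger = trigger,
                       stringsAsFactors = FALSE)
    }
    values <- pmax(30, config$baseline_map + bg - dip)
    list(series = map_series(t, values, patient_id = patient_id,
                             duration_min = dur_min,
                             nominal_step = config$sampling_step),
         events = ev)
  })
}

#' Simulate pre/post biomarker panels for one patient
#'
#' Baseline (T0) concentrations are lognormal per analyte; the T2 value
#' adds a burden-coupled change: `drift + slope * metric + noise`, where
#' the metric is one of the patient's burden outcomes (S100B is keyed to
#' episode count, NGAL/NSE/GSH to the time-weighted average). Negative
#' generated concentrations are truncated at 0 with a warning.
#'
#' @param summary A [hypo_summary()] for the patient's surgery.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param patient_id Identifier attached to the panels.
#' @return A list with `pre` and `post` [biomarker_panel()]s.
#' @export
simulate_biomarkers <- function(summary, config = sim_config(), seed = 1,
                                patient_id = NULL) {
  stopifnot(inherits(summary, "hypo_summary"))
  metrics <- c(n_episodes = summary$n_episodes,
               total_time_min = summary$total_time_min,
               relative_time_pct = summary$relative_time_pct,
               twa_mmhg = summary$twa_mmhg)
  with_seed(seed, {
    pre <- vapply(biomarker_analytes, function(a) {
      b <- config$biomarker_baseline[[a]]
      stats::rlnorm(1, log(b[["median"]]), b[["sdlog"]])
    }, 0)
    post <- vapply(biomarker_analytes, function(a) {
      m <- config$biomarker_model[[a]]
      pre[[a]] + m$drift + m$slope * metrics[[m$metric]] +
        stats::rnorm(1, 0, m$noise_sd)
    }, 0)
    if (any(post < 0)) {
      warning(sprintf("truncated %d negative concentration(s) at 0",
                      sum(post < 0)))
      post <- pmax(post, 0)
    }
    list(pre = biomarker_panel(pre, "T0", patient_id = patient_id),
         post = biomarker_panel(post, "T2", patient_id = patient_id))
  })
}

#' Simulate a complete two-arm trial
#'
#' Randomizes arms by permuted blocks, simulates each surgery and its
#' biomarker pair, and returns a [trial_dataset()] ready for
#' [compare_arms()], [burden_correlations()] and
#' [group_biomarker_differences()]. Fully reproducible from
#' `(config, seed)`: per-patient substreams are derived from the master
#' seed, so any patient can be regenerated in isolation.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (default `config$seed`).
#' @return A `trial_dataset`; each patient additionally carries the event
#'   log as `$events`. The config and seed are stored as attributes.
#' @export
simulate_trial <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  n_total <- 2L * as.integer(config$n_per_arm)
  # degenerate-n contract: when the configured blocks cannot compose
  # n_total (e.g. one patient per arm), fall back to a single balanced
  # block of size n_total
  arms <- tryCatch(
    randomize_blocks(n_total, config$block_sizes,
                     seed = derive_seed(seed, 0L, 1L)),
    hypoburden_config_error = function(e) {
      randomize_blocks(n_total, n_total, seed = derive_seed(seed, 0L, 1L))
    })
  ids <- sprintf("P%03d", seq_len(n_total))
  patients <- lapply(seq_len(n_total), function(i) {
    surg <- simulate_surgery(arms[i], config,
                             seed = derive_seed(seed, i, 2L),
                             patient_id = ids[i])
    summ <- hypo_summary(surg$series, threshold = config$threshold)
    bio <- suppressWarnings(
      simulate_biomarkers(summ, config, seed = derive_seed(seed, i, 3L),
                          patient_id = ids[i]))
    list(patient_id = ids[i], arm = arms[i], series = surg$series,
         events = surg$events, biomarkers_pre = bio$pre,
         biomarkers_post = bio$post)
  })
  out <- trial_dataset(patients)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  out
}

#' Simulated incidence of hypotension in one arm
#'
#' Fraction of simulated surgeries with at least one hypotensive episode
#' (on the piecewise-linear trace, MAP dips below the threshold iff some
#' sample does).
#'
#' @param arm `"control"` or `"intervention"`.
#' @param n Number of simulated surgeries.
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @return Proportion in [0, 1].
#' @export
simulate_incidence <- function(arm = c("control", "intervention"),
                               n = 1000, config = sim_config(), seed = 1) {
  arm <- match.arg(arm)
  hits <- vapply(seq_len(n), function(i) {
    s <- simulate_surgery(arm, config, seed = derive_seed(seed, i, 4L))
    any(s$series$values < config$threshold)
  }, NA)
  mean(hits)
}

#' Monte-Carlo power for a two-group comparison of hypotension incidence
#'
#' Simulates `reps` trials with binary incidence `p1` (control) vs `p2`
#' (intervention), tests each with a two-sided two-proportion z-test
#' (pooled standard error under the null; the canonical chi-square-
#' equivalent test), and reports the rejection rate. `test = "t_test"`
#' instead applies a Welch t-test to the 0/1 encoding; the two are
#' asymptotically equivalent.
#'
#' @param p1,p2 True incidences in (0, 1).
#' @param n_per_arm Patients per arm.
#' @param alpha Two-sided significance level.
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param seed Integer seed.
#' @param test `"two_proportion"` (default) or `"t_test"`.
#' @return A list with `power`, `se` (binomial standard error), `reps`,
#'   `n_per_arm`, `alpha`, `test`.
#' @export
#' @examples
#' power_simulation(0.80, 0.38, n_per_arm = 20, reps = 2000, seed = 1)
power_simulation <- function(p1, p2, n_per_arm = 20, alpha = 0.05,
                             reps = 20000, seed = 1,
                             test = c("two_proportion", "t_test")) {
  test <- match.arg(test)
  for (p in c(p1, p2)) {
    if (!(p > 0 && p < 1)) {
      stop_hypoburden("incidences must be in (0, 1)",
                      "hypoburden_config_error")
    }
  }
  if (reps < 1000) {
    stop_hypoburden("reps must be >= 1000", "hypoburden_config_error")
  }
  n <- n_per_arm
  reject <- with_seed(seed, {
    x1 <- stats::rbinom(reps, n, p1)
    x2 <- stats::rbinom(reps, n, p2)
    if (test == "two_proportion") {
      pb <- (x1 + x2) / (2 * n)
      se <- sqrt(pb * (1 - pb) * 2 / n)
      z <- ifelse(se == 0, 0, (x1 / n - x2 / n) / se)
      abs(z) > stats::qnorm(1 - alpha / 2)
    } else {
      ph1 <- x1 / n; ph2 <- x2 / n
      v1 <- ph1 * (1 - ph1) * n / (n - 1)
      v2 <- ph2 * (1 - ph2) * n / (n - 1)
      se <- sqrt((v1 + v2) / n)
      df <- ifelse(se == 0, 1,
                   ((v1 + v2) / n)^2 /
                     ((v1 / n)^2 / (n - 1) + (v2 / n)^2 / (n - 1)))
      tt <- ifelse(se == 0, ifelse(ph1 != ph2, Inf, 0),
                   (ph1 - ph2) / se)
      abs(tt) > stats::qt(1 - alpha / 2, df)
    }
  })
  pw <- mean(reject)
  list(power = pw, se = sqrt(pw * (1 - pw) / reps), reps = reps,
       n_per_arm = n_per_arm, alpha = alpha, test = test)
}

#' Closed-form power of the pooled two-proportion z-test
#'
#' Normal-approximation power for a two-sided comparison of two binomial
#' proportions; the analytic counterpart of [power_simulation()].
#'
#' @inheritParams power_simulation
#' @return Power in [0, 1].
#' @export
power_two_prop_analytic <- function(p1, p2, n_per_arm = 20, alpha = 0.05) {
  n <- n_per_arm
  pb <- (p1 + p2) / 2
  se0 <- sqrt(2 * pb * (1 - pb) / n)
  se1 <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
  za <- stats::qnorm(1 - alpha / 2)
  d <- abs(p1 - p2)
  stats::pnorm((d - za * se0) / se1) + stats::pnorm((-d - za * se0) / se1)
}
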