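test_that("permuted-block randomization balances every block", {
  a <- randomize_blocks(4, c(4), seed = 1)
  expect_equal(unname(table(a)["intervention"]), 2)

  for (s in 1:50) {
    a <- randomize_blocks(40, c(4, 6), seed = s)
    expect_equal(sum(a == "intervention"), 20)
    expect_equal(sum(a == "control"), 20)
    expect_true(all(attr(a, "blocks") %in% c(4, 6)))
    expect_equal(sum(attr(a, "blocks")), 40)
  }
  # determinism
  expect_identical(randomize_blocks(40, c(4, 6), seed = 9),
                   randomize_blocks(40, c(4, 6), seed = 9))
})

test_that("prefix imbalance never exceeds half the largest block", {
  for (s in 1:200) {
    a <- randomize_blocks(40, c(4, 6), seed = s)
    run <- cumsum(a == "intervention") - cumsum(a == "control")
    expect_lte(max(abs(run)), 3)
  }
})

test_that("impossible block compositions raise a configuration error", {
  expect_error(randomize_blocks(5, c(4, 6)),
               class = "hypoburden_config_error")
  expect_error(randomize_blocks(40, c(3, 5)),
               class = "hypoburden_config_error")
})

test_that("a noiseless, eventless surgery is flat at baseline with zero burden", {
  cfg <- sim_config(noise_sd = 0, event_rate = 0)
  s <- simulate_surgery("control", cfg, seed = 5)
  expect_true(all(s$series$values == cfg$baseline_map))
  su <- hypo_summary(s$series)
  expect_identical(su$n_episodes, 0L)
  expect_equal(su$twa_mmhg, 0)
  expect_identical(nrow(s$events), 0L)
})

test_that("perfect alerting and treatment avert all intervention-arm hypotension", {
  cfg <- sim_config(alert_sensitivity = 1, treatment_efficacy = 1)
  for (s in 1:10) {
    surg <- simulate_surgery("intervention", cfg, seed = s)
    expect_equal(hypo_summary(surg$series)$twa_mmhg, 0)
    if (nrow(surg$events)) expect_true(all(surg$events$averted))
  }
})

test_that("generated series always satisfy the data-model invariants", {
  cfg <- sim_config()
  for (s in 1:10) {
    arm <- if (s %% 2) "control" else "intervention"
    surg <- simulate_surgery(arm, cfg, seed = s)
    x <- surg$series
    expect_s3_class(x, "map_series")
    expect_true(all(diff(x$times) > 0))
    expect_true(all(x$values > 0))
    expect_lte(x$times[length(x$times)], x$duration_min * 60 + 1e-9)
    # event-log consistency: averted implies alerted; alerted events carry
    # a proactive trigger
    ev <- surg$events
    if (nrow(ev)) {
      expect_true(all(!ev$averted | ev$alerted))
      expect_true(all(ev$trigger[ev$alerted] == "proactive_alert"))
      expect_true(all(is.na(ev$action) |
                        ev$action %in% c("fluid", "vasopressor",
                                         "inotrope", "observe")))
    }
  }
})

test_that("simulation is bit-reproducible from (config, seed)", {
  cfg <- sim_config(n_per_arm = 3)
  t1 <- simulate_trial(cfg, seed = 77)
  t2 <- simulate_trial(cfg, seed = 77)
  expect_identical(t1$patients, t2$patients)
  t3 <- simulate_trial(cfg, seed = 78)
  expect_false(identical(t1$patients, t3$patients))
})

test_that("per-patient substreams regenerate a patient in isolation", {
  cfg <- sim_config(n_per_arm = 3)
  tr <- simulate_trial(cfg, seed = 42)
  p4 <- tr$patients[[4]]
  again <- simulate_surgery(p4$arm, cfg,
                            seed = hypoburden:::derive_seed(42, 4, 2L),
                            patient_id = p4$patient_id)
  expect_identical(again$series, p4$series)
})

test_that("greater treatment efficacy lowers intervention-arm burden", {
  mean_twa <- function(eff) {
    cfg <- sim_config(treatment_efficacy = eff)
    mean(vapply(1:60, function(s) {
      surg <- simulate_surgery("intervention", cfg, seed = 9000 + s)
      hypo_summary(surg$series)$twa_mmhg
    }, 0))
  }
  tw <- vapply(c(0.2, 0.6, 0.95), mean_twa, 0)
  expect_true(tw[1] > tw[2] && tw[2] > tw[3])
})

test_that("zero-slope biomarker models decouple deltas from burden", {
  cfg <- sim_config(n_per_arm = 30)
  for (a in names(cfg$biomarker_model)) cfg$biomarker_model[[a]]$slope <- 0
  tr <- simulate_trial(cfg, seed = 55)
  bc <- burden_correlations(tr)
  expect_lt(abs(bc$rho["s100b", "n_episodes"]), 0.35)
  expect_lt(abs(bc$rho["ngal", "twa_mmhg"]), 0.35)
})

test_that("a noiseless positive slope gives perfect rank correlation with its metric", {
  cfg <- sim_config()
  cfg$biomarker_model$ngal$noise_sd <- 0
  twa <- seq(0.1, 2, length.out = 15)
  deltas <- vapply(seq_along(twa), function(i) {
    su <- structure(list(n_episodes = i, total_time_min = i,
                         relative_time_pct = i, twa_mmhg = twa[i]),
                    class = "hypo_summary")
    # other analytes keep their noise and may truncate at zero; only the
    # noiseless NGAL channel is under test
    b <- suppressWarnings(simulate_biomarkers(su, cfg, seed = 200 + i))
    compute_deltas(b$pre, b$post)[["ngal"]]
  }, 0)
  expect_equal(spearman_cor(deltas, twa)$rho, 1)
})

test_that("negative generated concentrations are truncated at zero with a warning", {
  cfg <- sim_config()
  cfg$biomarker_model$gsh$drift <- -1000
  su <- hypo_summary(dip_series(1))
  expect_warning(b <- simulate_biomarkers(su, cfg, seed = 3),
                 "truncated")
  expect_equal(b$post$values[["gsh"]], 0)
})

test_that("default trials have 40 patients, 20 per arm", {
  tr <- simulate_trial(sim_config(), seed = 99)
  arms <- vapply(tr$patients, function(p) p$arm, "")
  expect_length(arms, 40)
  expect_equal(sum(arms == "intervention"), 20)
})

test_that("power is near alpha under the null and matches the analytic formula", {
  null <- power_simulation(0.5, 0.5, n_per_arm = 20, reps = 5000, seed = 3)
  expect_lt(null$power, 0.06)
  expect_gt(null$power, 0.02)

  pw <- power_simulation(0.80, 0.38, n_per_arm = 20, reps = 10000, seed = 4)
  analytic <- power_two_prop_analytic(0.80, 0.38, 20)
  expect_lt(abs(pw$power - analytic), 3 * pw$se + 0.01)

  tt <- power_simulation(0.80, 0.38, n_per_arm = 20, reps = 5000, seed = 5,
                         test = "t_test")
  expect_lt(abs(tt$power - pw$power), 0.05)
})

test_that("power is monotone in sample size and effect size", {
  p_n <- vapply(c(10, 20, 40), function(n) {
    power_simulation(0.80, 0.38, n_per_arm = n, reps = 4000, seed = 6)$power
  }, 0)
  expect_true(p_n[1] < p_n[2] && p_n[2] < p_n[3])

  p_d <- vapply(c(0.55, 0.45, 0.38), function(p2) {
    power_simulation(0.80, p2, n_per_arm = 20, reps = 4000, seed = 7)$power
  }, 0)
  expect_true(p_d[1] < p_d[2] && p_d[2] < p_d[3])
})

test_that("configuration validation rejects invalid settings", {
  expect_error(sim_config(alert_sensitivity = 1.2),
               class = "hypoburden_config_error")
  expect_error(sim_config(block_sizes = c(3, 5)),
               class = "hypoburden_config_error")
  expect_error(sim_config(event_rate = -1),
               class = "hypoburden_config_error")
  expect_error(power_simulation(0, 0.4), class = "hypoburden_config_error")
  expect_error(power_simulation(0.5, 0.4, reps = 10),
               class = "hypoburden_config_error")
})
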