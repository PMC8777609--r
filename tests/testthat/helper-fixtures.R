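# Fixture builders and independent oracles shared across the suite.
# All fixtures are generated in code; no data files.

# The textbook burden example: a 100-min surgery at a baseline of 70 mmHg
# with five disjoint 1-min hypotensive excursions at a constant 60 mmHg.
# Transitions use ramps of width `delta` seconds so the trace stays a valid
# function of time; the idealized rectangular-dip quantities (5 episodes,
# 5 min, 25 mmHg.min, TWA 0.25) are approached to within ~delta/24.
worked_example_series <- function(delta = 1e-6) {
  starts <- 600 + (0:4) * 1000
  t <- 0; v <- 70
  for (s in starts) {
    t <- c(t, s - delta, s, s + 60, s + 60 + delta)
    v <- c(v, 70, 60, 60, 70)
  }
  t <- c(t, 6000); v <- c(v, 70)
  map_series(t, v, patient_id = "worked", duration_min = 100)
}

# A series with `k` rectangular 1-min dips to 60 mmHg; used for
# shift-recovery constructions.
dip_series <- function(k, duration_min = 100, delta = 1e-6) {
  if (k == 0) {
    return(map_series(c(0, duration_min * 60), c(70, 70),
                      duration_min = duration_min))
  }
  gap <- floor((duration_min * 60 - 120) / k)
  starts <- 60 + (0:(k - 1)) * gap
  t <- 0; v <- 70
  for (s in starts) {
    t <- c(t, s - delta, s, s + 60, s + 60 + delta)
    v <- c(v, 70, 60, 60, 70)
  }
  t <- c(t, duration_min * 60); v <- c(v, 70)
  map_series(t, v, duration_min = duration_min)
}

# Random piecewise-linear MAP series crossing the 65 mmHg threshold.
random_series <- function(n_pts = 30, duration_min = 60, lo = 55, hi = 80) {
  span <- duration_min * 60
  t <- sort(c(0, stats::runif(n_pts - 2, 0, span), span))
  while (any(diff(t) <= 0)) t <- sort(c(0, stats::runif(n_pts - 2, 0, span), span))
  map_series(t, stats::runif(n_pts, lo, hi), duration_min = duration_min)
}

# Manual piecewise-linear evaluation (independent of stats::approx).
pw_linear_eval <- function(times, values, t0) {
  vapply(t0, function(tt) {
    if (tt <= times[1]) return(values[1])
    n <- length(times)
    if (tt >= times[n]) return(values[n])
    i <- max(which(times <= tt))
    if (times[i] == tt) return(values[i])
    values[i] + (values[i + 1] - values[i]) *
      (tt - times[i]) / (times[i + 1] - times[i])
  }, 0)
}

# Riemann-sum oracle for the area under the threshold, mmHg.min. Segments
# that straddle the threshold are split at a crossing located numerically
# by uniroot on the interpolant, so each midpoint sum runs over a piece on
# which the deficit is linear (where the midpoint rule is exact).
riemann_area_oracle <- function(series, threshold = 65, n_sub = 64) {
  t <- series$times; v <- series$values
  f <- function(tt) stats::approx(t, v, xout = tt)$y
  total <- 0
  for (i in seq_len(length(t) - 1L)) {
    brk <- c(t[i], t[i + 1L])
    if ((v[i] - threshold) * (v[i + 1L] - threshold) < 0) {
      r <- stats::uniroot(function(z) f(z) - threshold,
                          lower = t[i], upper = t[i + 1L],
                          tol = 1e-13)$root
      brk <- sort(c(brk, r))
    }
    for (j in seq_len(length(brk) - 1L)) {
      h <- (brk[j + 1L] - brk[j]) / n_sub
      if (h <= 0) next
      mid <- brk[j] + (seq_len(n_sub) - 0.5) * h
      total <- total + sum(pmax(0, threshold - f(mid))) * h
    }
  }
  total / 60
}

# Full-enumeration Mann-Whitney oracle: exact two-sided p over all
# C(m+n, m) assignments of the pooled ranks (tie-free data).
mw_enum_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  N <- m + n
  u_obs <- sum(rank(c(x, y))[seq_len(m)]) - m * (m + 1) / 2
  subsets <- utils::combn(N, m)
  us <- apply(subsets, 2, function(ix) sum(ix) - m * (m + 1) / 2)
  p_lo <- mean(us <= u_obs); p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Burden outcome names used throughout.
burden_outcomes <- c("n_episodes", "total_time_min", "relative_time_pct",
                     "twa_mmhg")

# Complete named analyte vector for panel construction.
analyte_values <- function(...) {
  base <- c(ngal = 2.1, nse = 2.0, hif1a = 0.17, s100b = 0.34,
            acetyl_coa = 0.13, hs_troponin = 37, looh = 5.2, gsh = 7.5)
  mods <- c(...)
  if (length(mods)) base[names(mods)] <- mods
  base
}
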