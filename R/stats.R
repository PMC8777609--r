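# Nonparametric statistics for small two-arm trials, implemented directly:
# Mann-Whitney U (exact null distribution by the classical count recursion,
# or tie- and continuity-corrected normal approximation), Hodges-Lehmann
# median difference with an order-statistic confidence interval, Spearman
# rank correlation, Pearson chi-square, and a Lilliefors-type
# Kolmogorov-Smirnov normality test with Monte-Carlo p-values.

# Cache of exact Mann-Whitney null count vectors, keyed by "m,n".
.u_null_cache <- new.env(parent = emptyenv())

# counts[u + 1] = number of arrangements of m x's and n y's with U = u,
# u = 0..mn, via f(u; m, n) = f(u - n; m - 1, n) + f(u; m, n - 1).
u_null_counts <- function(m, n) {
  key <- paste(m, n, sep = ",")
  if (!is.null(.u_null_cache[[key]])) return(.u_null_cache[[key]])
  # table[[i + 1]] holds counts for (i, current nn)
  tab <- vector("list", m + 1L)
  for (nn in 0:n) {
    newtab <- vector("list", m + 1L)
    newtab[[1L]] <- 1  # m = 0: U always 0
    if (nn == 0L) {
      for (i in seq_len(m)) newtab[[i + 1L]] <- 1
    } else {
      for (i in seq_len(m)) {
        a <- c(rep(0, nn), newtab[[i]])  # f(u - nn; i - 1, nn)
        b <- tab[[i + 1L]]             # f(u; i, nn - 1)
        len <- i * nn + 1L
        a <- c(a, rep(0, max(0L, len - length(a))))[seq_len(len)]
        b <- c(b, rep(0, max(0L, len - length(b))))[seq_len(len)]
        newtab[[i + 1L]] <- a + b
      }
    }
    tab <- newtab
  }
  out <- tab[[m + 1L]]
  .u_null_cache[[key]] <- out
  out
}

# Midrank-based U statistic of x relative to y (counts pairs x > y, ties 0.5).
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for a difference between two independent samples.
#' The exact p-value enumerates the null distribution of U over all
#' arrangements (valid without ties); the normal approximation applies a tie
#' correction to the variance and a 0.5 continuity correction. `"auto"`
#' (default) uses the exact path when `n_x * n_y <= exact_limit` and the
#' pooled data are tie-free.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param mode `"auto"`, `"exact"`, or `"normal_approx"`.
#' @param exact_limit Largest `n_x * n_y` for which `"auto"` stays exact
#'   (default 400).
#' @return A list with `statistic` (U of `x` vs `y`), `p_value`, and
#'   `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx"),
                           exact_limit = 400) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y) || anyNA(c(x, y))) {
    stop_hypoburden("both samples must be non-empty and free of NA",
                    "hypoburden_insufficient_data")
  }
  m <- length(x); n <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  u <- u_statistic(x, y)
  if (mode == "auto") {
    mode <- if (m * n <= exact_limit && !ties) "exact" else "normal_approx"
  }
  if (mode == "exact") {
    if (ties) {
      stop_hypoburden("exact Mann-Whitney p-value requires tie-free data",
                      "hypoburden_config_error")
    }
    counts <- u_null_counts(m, n)
    total <- sum(counts)
    cdf <- cumsum(counts) / total
    lo <- cdf[u + 1L]                               # P(U <= u)
    hi <- 1 - if (u == 0) 0 else cdf[u]             # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
  } else {
    N <- m + n
    tie_tab <- table(c(x, y))
    sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    mu <- m * n / 2
    z <- u - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = u, p_value = p, method = mode)
}

#' Hodges-Lehmann estimate of a location difference
#'
#' The estimate is the median of all `n_x * n_y` pairwise differences
#' `x_i - y_j`. The confidence interval takes order statistics of the sorted
#' pairwise differences at ranks given by the Mann-Whitney null
#' distribution: exact ranks for small samples, a normal approximation of
#' the rank otherwise, always widening to the nearest achievable rank
#' (conservative).
#'
#' @param x,y Numeric samples.
#' @param conf Confidence level in (0, 1), default 0.95.
#' @param exact_limit Largest `n_x * n_y` using the exact rank.
#' @return A list with `estimate`, `ci_low`, `ci_high`, `conf`.
#' @export
#' @examples
#' hodges_lehmann(c(1, 5), c(2, 3))
hodges_lehmann <- function(x, y, conf = 0.95, exact_limit = 400) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y) || anyNA(c(x, y))) {
    stop_hypoburden("both samples must be non-empty and free of NA",
                    "hypoburden_insufficient_data")
  }
  if (!(conf > 0 && conf < 1)) {
    stop_hypoburden("conf must be in (0, 1)", "hypoburden_config_error")
  }
  m <- length(x); n <- length(y)
  d <- sort(as.vector(outer(x, y, "-")))
  est <- stats::median(d)
  alpha <- 1 - conf
  mn <- m * n
  if (mn <= exact_limit) {
    counts <- u_null_counts(m, n)
    cdf <- cumsum(counts) / sum(counts)
    # largest k with P(U <= k - 1) <= alpha/2
    k <- max(0L, sum(cdf <= alpha / 2 + 1e-12))
  } else {
    N <- m + n
    sigma <- sqrt(mn * (N + 1) / 12)
    k <- floor(mn / 2 - stats::qnorm(1 - alpha / 2) * sigma)
  }
  k <- max(1L, min(as.integer(k), floor(mn / 2)))
  list(estimate = est, ci_low = d[k], ci_high = d[mn + 1L - k], conf = conf)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with a two-sided p-value from the
#' t-distribution approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Paired numeric samples, `n >= 3`, neither constant.
#' @return A list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop_hypoburden("Spearman correlation needs at least 3 complete pairs",
                    "hypoburden_insufficient_data")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop_hypoburden("correlation undefined for a constant vector",
                    "hypoburden_degenerate_input")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction; degrees of freedom `(r - 1)(c - 1)`.
#'
#' @param tab Matrix of non-negative integer counts with positive row and
#'   column margins.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_hypoburden("counts must be non-negative integers",
                    "hypoburden_degenerate_table")
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop_hypoburden("table has a zero margin", "hypoburden_degenerate_table")
  }
  expected <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# KS distance between the ECDF of x and a normal fitted by sample mean/SD.
ks_normal_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  f <- stats::pnorm(z)
  max(max(seq_len(n) / n - f), max(f - (seq_len(n) - 1) / n))
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' One-sample KS statistic against a normal distribution with the sample
#' mean and standard deviation plugged in (the Lilliefors construction).
#' Because parameters are estimated, the classical KS null does not apply;
#' the p-value is obtained by Monte-Carlo simulation of the null with a
#' fixed internal seed (the caller's RNG stream is untouched).
#'
#' @param x Numeric sample, `n >= 3`, not constant.
#' @param reps Monte-Carlo replicates (default 2000).
#' @param mc_seed Seed for the null simulation.
#' @return A list with `statistic`, `p_value`, `reps`.
#' @export
ks_normality <- function(x, reps = 2000, mc_seed = 20220113) {
  x <- as.numeric(x)
  if (length(x) < 3) {
    stop_hypoburden("normality test needs n >= 3",
                    "hypoburden_insufficient_data")
  }
  if (stats::sd(x) == 0) {
    stop_hypoburden("normality test undefined for a constant sample",
                    "hypoburden_degenerate_input")
  }
  d <- ks_normal_statistic(x)
  n <- length(x)
  exceed <- with_seed(mc_seed, {
    sum(vapply(seq_len(reps), function(i) {
      ks_normal_statistic(stats::rnorm(n))
    }, 0) >= d - 1e-15)
  })
  list(statistic = d, p_value = (1 + exceed) / (reps + 1), reps = reps)
}

# Shared assembly of a two-group comparison from raw per-patient values.
group_comparison_values <- function(x_int, x_ctrl, outcome_name,
                                    conf = 0.95) {
  if (length(x_int) < 1 || length(x_ctrl) < 1) {
    stop_hypoburden("both arms must be represented",
                    "hypoburden_insufficient_data")
  }
  insufficient <- length(x_int) < 2 || length(x_ctrl) < 2
  hl <- hodges_lehmann(x_int, x_ctrl, conf = conf)
  mw <- mann_whitney_u(x_int, x_ctrl)
  structure(
    list(outcome_name = outcome_name,
         median_intervention = stats::median(x_int),
         iqr_intervention = iqr_width(x_int),
         median_control = stats::median(x_ctrl),
         iqr_control = iqr_width(x_ctrl),
         hl_difference = hl$estimate,
         ci_low = hl$ci_low, ci_high = hl$ci_high,
         p_value = mw$p_value, u_statistic = mw$statistic,
         conf = conf, alpha = 1 - conf,
         n_intervention = length(x_int), n_control = length(x_ctrl),
         insufficient_data = insufficient),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s\n  intervention: %.3g (IQR %.3g, n=%d) | control: %.3g (IQR %.3g, n=%d)\n",
              x$outcome_name,
              x$median_intervention, x$iqr_intervention, x$n_intervention,
              x$median_control, x$iqr_control, x$n_control))
  cat(sprintf("  HL difference %.3g (%.0f%% CI %.3g, %.3g), p = %.4g%s\n",
              x$hl_difference, 100 * x$conf, x$ci_low, x$ci_high, x$p_value,
              if (x$insufficient_data) " [insufficient data]" else ""))
  invisible(x)
}

#' Compare a hypotension burden outcome between arms
#'
#' Assembles per-arm medians and IQR widths, the Hodges-Lehmann median
#' difference oriented intervention minus control (so a benefit of the
#' intervention is negative), its confidence interval, and the Mann-Whitney
#' p-value.
#'
#' @param trial A [trial_dataset()].
#' @param outcome One of `"n_episodes"`, `"total_time_min"`,
#'   `"relative_time_pct"`, `"twa_mmhg"`, `"area_mmhg_min"`.
#' @param conf Confidence level (default 0.95).
#' @param threshold Hypotension threshold in mmHg.
#' @param method Area method, see [area_under_threshold()].
#' @return A `group_comparison` object.
#' @export
compare_arms <- function(trial, outcome = "twa_mmhg", conf = 0.95,
                         threshold = 65,
                         method = c("trapezoid", "maxdepth_x_time")) {
  bt <- burden_table(trial, threshold = threshold,
                     method = match.arg(method))
  if (!outcome %in% names(bt)) {
    stop_hypoburden(sprintf("unknown outcome '%s'", outcome),
                    "hypoburden_config_error")
  }
  if (any(!is.finite(bt[[outcome]]))) {
    stop_hypoburden("outcome missing for some patients",
                    "hypoburden_insufficient_data")
  }
  group_comparison_values(bt[[outcome]][bt$arm == "intervention"],
                          bt[[outcome]][bt$arm == "control"],
                          outcome, conf = conf)
}
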