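test_that("Mann-Whitney exact p matches hand enumeration on separated samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2 / choose(6, 3)
})

test_that("identical samples give a central U and p = 1", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  r <- mann_whitney_u(x, x)
  expect_equal(r$statistic, length(x)^2 / 2)
  expect_equal(r$p_value, 1)
})

test_that("exact Mann-Whitney p equals the full-enumeration oracle", {
  set.seed(71)
  for (i in 1:12) {
    m <- sample(3:8, 1); n <- sample(3:8, 1)
    x <- rnorm(m); y <- rnorm(n, 0.8)
    r <- mann_whitney_u(x, y, mode = "exact")
    expect_equal(r$p_value, mw_enum_oracle(x, y), tolerance = 1e-12)
    # and the established implementation agrees
    expect_equal(r$p_value, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("tied data take the corrected normal approximation", {
  x <- c(1, 2, 2, 3, 5, 5); y <- c(2, 4, 4, 5, 6, 7)
  r <- mann_whitney_u(x, y)
  expect_identical(r$method, "normal_approx")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(mann_whitney_u(x, y, mode = "exact"),
               class = "hypoburden_config_error")
})

test_that("exact and approximate p agree closely at n = 20 per arm", {
  set.seed(81)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20, 0.3)
    pe <- mann_whitney_u(x, y, mode = "exact")$p_value
    pa <- mann_whitney_u(x, y, mode = "normal_approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Hodges-Lehmann estimate is the median of pairwise differences", {
  expect_equal(hodges_lehmann(c(1, 5), c(2, 3))$estimate, 0.5)
  x <- c(1, 2, 3)
  expect_equal(hodges_lehmann(x, x + 2)$estimate, -2)
  set.seed(91)
  for (i in 1:10) {
    x <- rnorm(sample(3:40, 1)); y <- rnorm(sample(3:40, 1))
    hl <- hodges_lehmann(x, y)
    expect_equal(hl$estimate, median(as.vector(outer(x, y, "-"))),
                 tolerance = 1e-12)
    # antisymmetry
    expect_equal(hl$estimate, -hodges_lehmann(y, x)$estimate,
                 tolerance = 1e-12)
    expect_true(hl$ci_low <= hl$estimate && hl$estimate <= hl$ci_high)
  }
})

test_that("Hodges-Lehmann interval matches the established implementation on the exact path", {
  set.seed(101)
  for (i in 1:15) {
    m <- sample(5:20, 1); n <- sample(5:20, 1)
    x <- rnorm(m); y <- rnorm(n, 0.5)
    hl <- hodges_lehmann(x, y)
    wt <- suppressWarnings(wilcox.test(x, y, conf.int = TRUE))
    expect_equal(hl$estimate, unname(wt$estimate), tolerance = 1e-12)
    if (m * n <= 400) {
      expect_equal(c(hl$ci_low, hl$ci_high), as.numeric(wt$conf.int),
                   tolerance = 1e-12)
    } else {
      # the approximate rank widens conservatively
      expect_lte(hl$ci_low, wt$conf.int[1] + 1e-12)
      expect_gte(hl$ci_high, wt$conf.int[2] - 1e-12)
    }
  }
})

test_that("Hodges-Lehmann CI covers a pure shift near the nominal rate", {
  set.seed(111)
  shift <- 1.5
  cover <- vapply(1:2000, function(i) {
    x <- rnorm(20) + shift; y <- rnorm(20)
    hl <- hodges_lehmann(x, y)
    hl$ci_low <= shift && shift <= hl$ci_high
  }, NA)
  expect_gte(mean(cover), 0.95 - 0.03)
})

test_that("Spearman correlation equals rank-then-Pearson and flags degeneracy", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)
  set.seed(121)
  for (i in 1:8) {
    x <- rnorm(6); y <- rnorm(6)
    sc <- spearman_cor(x, y)
    ref <- cor.test(rank(x), rank(y), method = "pearson")
    expect_equal(sc$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(sc$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(spearman_cor(rep(1, 5), 1:5),
               class = "hypoburden_degenerate_input")
  expect_error(spearman_cor(1:2, 2:1),
               class = "hypoburden_insufficient_data")
})

test_that("chi-square matches the hand formula and the reference implementation", {
  expect_equal(chi_square(rbind(c(5, 10), c(5, 10)))$statistic, 0)
  expect_equal(chi_square(rbind(c(5, 10), c(5, 10)))$p_value, 1)

  # trial gender table: 10/10 vs 12/8
  tab <- rbind(c(10, 10), c(12, 8))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square(tab)$statistic, sum((tab - e)^2 / e))
  ref <- chisq.test(tab, correct = FALSE)
  expect_equal(chi_square(tab)$statistic, unname(ref$statistic))
  expect_equal(chi_square(tab)$p_value, ref$p.value)

  set.seed(131)
  for (i in 1:5) {
    t2 <- matrix(rpois(6, 12) + 1, 2, 3)
    ref <- chisq.test(t2, correct = FALSE)
    expect_equal(chi_square(t2)$statistic, unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(chi_square(t2)$df, unname(ref$parameter))
  }
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))),
               class = "hypoburden_degenerate_table")
})

test_that("KS normality statistic equals a naive pointwise oracle", {
  set.seed(141)
  x <- rgamma(40, 2)
  d <- ks_normality(x, reps = 1000)$statistic
  # naive loop over the ECDF
  z <- sort(x); n <- length(z)
  f <- pnorm(z, mean(x), sd(x))
  d_oracle <- 0
  for (i in seq_len(n)) {
    d_oracle <- max(d_oracle, abs(i / n - f[i]), abs((i - 1) / n - f[i]))
  }
  expect_equal(d, d_oracle, tolerance = 1e-12)
  expect_equal(d, unname(nortest::lillie.test(x)$statistic),
               tolerance = 1e-12)
})

test_that("KS normality accepts normal data and rejects exponential data", {
  set.seed(151)
  x_norm <- rnorm(500)
  x_exp <- rexp(500)
  expect_gt(ks_normality(x_norm, reps = 2000)$p_value, 0.05)
  expect_lt(ks_normality(x_exp, reps = 2000)$p_value, 0.01)
  expect_error(ks_normality(rep(2, 10)),
               class = "hypoburden_degenerate_input")
})

test_that("identical arms give a null comparison", {
  s <- lapply(1:5, function(k) dip_series(k))
  patients <- c(
    lapply(1:5, function(i) list(patient_id = paste0("i", i),
                                 arm = "intervention", series = s[[i]])),
    lapply(1:5, function(i) list(patient_id = paste0("c", i),
                                 arm = "control", series = s[[i]])))
  tr <- trial_dataset(patients)
  gc <- compare_arms(tr, "n_episodes")
  expect_equal(gc$hl_difference, 0)
  expect_true(gc$ci_low <= 0 && gc$ci_high >= 0)
  expect_equal(gc$p_value, 1)
})

test_that("a pure shift in episode count is recovered with the trial's sign convention", {
  # control arm has 5 more episodes per patient than intervention
  patients <- c(
    lapply(1:6, function(i) list(patient_id = paste0("i", i),
                                 arm = "intervention",
                                 series = dip_series(i))),
    lapply(1:6, function(i) list(patient_id = paste0("c", i),
                                 arm = "control",
                                 series = dip_series(i + 5))))
  tr <- trial_dataset(patients)
  gc <- compare_arms(tr, "n_episodes")
  expect_equal(gc$hl_difference, -5)
  expect_lt(gc$ci_high, 0)
})

test_that("unknown outcomes and empty samples raise typed errors", {
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "hypoburden_insufficient_data")
  expect_error(hodges_lehmann(1:3, numeric(0)),
               class = "hypoburden_insufficient_data")
  tr <- trial_dataset(list(
    list(patient_id = "a", arm = "control", series = dip_series(1)),
    list(patient_id = "b", arm = "intervention", series = dip_series(2))))
  expect_error(compare_arms(tr, "nonexistent"),
               class = "hypoburden_config_error")
})
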