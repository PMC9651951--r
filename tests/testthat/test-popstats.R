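test_that("quadratic regression recovers exact and noisy laws", {
  x <- seq(0.5, 7, length.out = 40)
  r <- regress_quadratic(0.11 + 0.14 * x, x)
  expect_equal(r$terms$estimate,
               c(0.11, 0.14, 0), tolerance = 1e-10)
  expect_equal(r$adj_r_squared, 1, tolerance = 1e-8)

  set.seed(14)
  y <- 1 - 0.11 * x^2 + stats::rnorm(40, 0, 0.05)
  r2 <- regress_quadratic(y, x)
  quad <- r2$terms[r2$terms$term == "quadratic", ]
  expect_lt(quad$p.value, 0.001)
  expect_lt(quad$estimate, 0)

  expect_error(regress_quadratic(1:10, rep(2, 10)), "collinear")
})

test_that("pure-noise regressions favour the null in the long run", {
  set.seed(15)
  wins <- vapply(1:60, function(i) {
    y <- stats::rnorm(131)
    x <- stats::runif(131, 0.35, 7.2)
    regress_quadratic(y, x)$best_model == "null"
  }, TRUE)
  expect_gt(mean(wins), 0.8)
})

test_that("sign-split chi-square reproduces its worked values", {
  expect_equal(sign_split_chi2(93, 131)$statistic, 22.3, tolerance = 0.05)
  expect_equal(sign_split_chi2(50, 100)$statistic, 0)
  expect_equal(sign_split_chi2(60, 100)$statistic, 2 * 9.5^2 / 50)
  # symmetry in k and n - k
  for (kn in list(c(10, 40), c(93, 131), c(3, 7))) {
    expect_equal(sign_split_chi2(kn[1], kn[2])$statistic,
                 sign_split_chi2(kn[2] - kn[1], kn[2])$statistic)
  }
  expect_error(sign_split_chi2(1, 0))
})

test_that("exponent posterior summaries match normal-theory oracles", {
  expect_equal(
    alpha_posterior_summary(rep(1, 200)),
    tibble::tibble(mean = 1, sd = 0, ci_lower = 1, ci_upper = 1,
                   frac_in_window = 1, sd_from_zero = Inf))
  set.seed(16)
  d <- stats::rnorm(1e5, 1, 0.1)
  s <- alpha_posterior_summary(d)
  expect_equal(s$frac_in_window, stats::pnorm(1) - stats::pnorm(-1),
               tolerance = 0.01)
  d2 <- stats::rnorm(1e5, 0.92, 0.095)
  s2 <- alpha_posterior_summary(d2)
  expect_equal(s2$mean, 0.92, tolerance = 0.005)
  expect_equal(s2$ci_lower, 0.92 - 1.96 * 0.095, tolerance = 0.01)
  expect_equal(s2$ci_upper, 0.92 + 1.96 * 0.095, tolerance = 0.01)
  # window fraction is a probability and grows with the window
  s3 <- alpha_posterior_summary(d2, window = c(0.8, 1.2))
  expect_true(s2$frac_in_window >= 0 && s2$frac_in_window <= 1)
  expect_gte(s3$frac_in_window, s2$frac_in_window)
})

test_that("the CDF is straight in log time exactly when compression is log", {
  expect_equal(cdf_log_linearity(peak_sequence(0.35, 1.5, 9))$r_squared, 1,
               tolerance = 1e-9)
  set.seed(17)
  r2_log <- cdf_log_linearity(rbpowerlaw(1e4, 1, 0.35, 7.2))$r_squared
  r2_unif <- cdf_log_linearity(stats::runif(1e4, 0.35, 7.2))$r_squared
  expect_gt(r2_log, 0.99)
  expect_lt(r2_unif, r2_log - 0.05)
})

test_that("early/late split behaves at the boundaries and in calibration", {
  set.seed(18)
  cells <- tibble::tibble(M = rbpowerlaw(131, 1, 0.35, 7.2))
  cells$sigma_w <- 0.11 + 0.14 * cells$M + stats::rnorm(131, 0, 0.05)
  rep <- early_late_analysis(cells, threshold = 2)
  expect_equal(sum(rep$groups$n), 131)
  # groups of a log-compressed population are not uniform on their ranges,
  # but after min-max normalisation they share a distribution
  expect_gt(rep$two_sample$ks_p, 0.01)

  # all cells early: late group too small, warned and skipped
  expect_warning(
    early_late_analysis(tibble::tibble(M = runif(20, 0.4, 1.5),
                                       sigma_w = runif(20, 0.2, 0.4)),
                        threshold = 2),
    "late group")
  # threshold at the max peak behaves the same way
  expect_warning(
    early_late_analysis(cells, threshold = max(cells$M) + 0.1),
    "late group")
})

test_that("uniform-KS within groups rejects for large log-compressed samples", {
  set.seed(19)
  cells <- tibble::tibble(M = rbpowerlaw(4000, 1, 0.35, 7.2))
  cells$sigma_w <- 0.11 + 0.14 * cells$M + stats::rnorm(4000, 0, 0.05)
  rep <- early_late_analysis(cells, threshold = 2)
  expect_true(all(rep$groups$ks_p < 0.01))
})

test_that("normalised two-sample KS keeps its nominal level", {
  set.seed(20)
  rejections <- vapply(1:60, function(i) {
    cells <- tibble::tibble(M = rbpowerlaw(131, 1, 0.35, 7.2),
                            sigma_w = 0.3)
    suppressWarnings(
      early_late_analysis(cells, threshold = 2)$two_sample$ks_p < 0.05)
  }, TRUE)
  expect_lte(mean(rejections), 0.12)
})

test_that("JZS Bayes factors point the right way", {
  set.seed(21)
  strong <- stats::rnorm(40, 0.5, 0.5)
  null <- stats::rnorm(40, 0, 0.5)
  expect_gt(bf_ttest(strong)$bf10, 10)
  expect_lt(bf_ttest(null)$bf10, 1)
  # Monte-Carlo check of the marginal-likelihood integral over g
  t_obs <- mean(strong) / (stats::sd(strong) / sqrt(40))
  r <- sqrt(2) / 2
  set.seed(22)
  g <- 1 / stats::rgamma(2e5, 1 / 2, rate = r^2 / 2)
  num <- mean((1 + 40 * g)^(-1 / 2) *
                (1 + t_obs^2 / ((1 + 40 * g) * 39))^(-40 / 2))
  den <- (1 + t_obs^2 / 39)^(-40 / 2)
  expect_equal(bf_ttest(strong)$bf10, num / den, tolerance = 0.02)
  # one-sided variant boosts a positive effect, demotes a negative one
  expect_gt(bf_ttest(strong, alternative = "greater")$bf10,
            bf_ttest(strong)$bf10)
  expect_lt(bf_ttest(-strong, alternative = "greater")$bf10, 0.1)
  # two-sample
  expect_gt(bf_ttest(strong, null)$bf10, 1)
})

test_that("event correlations recover coupling and its decay with peak", {
  cfg <- generator_config(n_time_cells = 60, n_distractor_cells = 0,
                          n_interneurons = 0, trials_per_cell = 40,
                          event_coupling = 1, seed = 23)
  sim <- simulate_population(cfg)
  trials <- dplyr::rename(sim$truth_trials, mu_i = "mu_i")
  cells <- dplyr::select(sim$truth_cells, "unit_id", "M")
  rep <- event_correlation_analysis(trials[, c("unit_id", "trial_id", "mu_i")],
                                    sim$events, cells)
  expect_gt(rep$bf_positive$bf10, 10)
  early_r <- mean(rep$per_cell$r[rep$per_cell$M < 2])
  late_r <- mean(rep$per_cell$r[rep$per_cell$M >= 2])
  expect_gt(early_r, late_r)

  # no coupling: correlations hover near zero
  cfg0 <- generator_config(n_time_cells = 60, n_distractor_cells = 0,
                           n_interneurons = 0, trials_per_cell = 40,
                           event_coupling = 0, seed = 23)
  sim0 <- simulate_population(cfg0)
  rep0 <- event_correlation_analysis(
    sim0$truth_trials[, c("unit_id", "trial_id", "mu_i")],
    sim0$events, dplyr::select(sim0$truth_cells, "unit_id", "M"))
  expect_lt(abs(mean(rep0$per_cell$r)), 0.08)

  # a cell with only two event trials is excluded with a warning
  tr2 <- tibble::tibble(unit_id = "x", trial_id = 1:2, mu_i = c(1, 2))
  ev2 <- tibble::tibble(unit_id = "x", trial_id = 1:2,
                        event_offset_s = c(0.1, -0.2))
  cl2 <- tibble::tibble(unit_id = "x", M = 1)
  expect_warning(event_correlation_analysis(tr2, ev2, cl2), "excluded")
})
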