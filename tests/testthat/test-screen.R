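test_that("a strong field is recovered and a single spike is degenerate", {
  set.seed(4)
  cell <- simulate_cell(M = 3, sigma_w = 0.4, sigma_t = 0, a1 = 0.8,
                        spikes_per_trial_mean = 20, n_trials = 40, delay = 8)
  fit <- fit_time_field(cell$spikes$spike_time_s, 40, 8, n_starts = 12)
  expect_equal(fit$mu_hat, 3, tolerance = 0.1)
  expect_gt(fit$llr, 5.66)

  # one spike at t = 4: constant-model rate ML gives m log(rate) - m
  f1 <- fit_time_field(4.0, 1, 8, n_starts = 8)
  expect_equal(f1$loglik_const, log(1 / 8) - 1)
  expect_gte(f1$llr, 0)

  # empty unit: flagged, not an exception
  f0 <- fit_time_field(numeric(0), 10, 8)
  expect_true(is.na(f0$llr))
})

test_that("screening applies every criterion with the right reasons", {
  sim <- small_sim()
  scr <- screen_units(sim$spikes, sim$delay,
                      screen_config(n_starts = 10, seed = 5))
  kind <- sim$truth_cells$kind[match(scr$unit_id, sim$truth_cells$unit_id)]
  # interneurons fail on the rate ceiling specifically
  expect_true(all(scr$fail_reason[kind == "interneuron"] == "rate_ceiling"))
  # uniform distractors never pass
  expect_true(all(!scr$is_time_cell[kind == "distractor"]))
  # generated time cells pass at a high rate
  expect_gte(mean(scr$is_time_cell[kind == "time_cell"]), 0.75)
  # per-criterion flags are all reported
  expect_true(all(c("pass_rate", "pass_llr", "pass_even_odd", "pass_peak",
                    "fail_reason") %in% names(scr)))
})

test_that("a monotone ramp is not admitted as a time field within the delay", {
  # density rising toward the end of the delay: the best Gaussian centre sits
  # at or beyond the delay edge, so the peak criterion rejects the unit
  set.seed(10)
  t <- 8 * sqrt(stats::runif(600))
  spikes <- tibble::tibble(unit_id = "ramp",
                           trial_id = rep(1:30, each = 20),
                           spike_time_s = sort(t))
  scr <- screen_units(spikes, 8, screen_config(n_starts = 12, seed = 1))
  expect_false(is.na(scr$fail_reason) && scr$mu_hat < 7)
})

test_that("LLR false-positive rate under the constant model is calibrated", {
  set.seed(6)
  n_units <- 200
  llrs <- vapply(seq_len(n_units), function(i) {
    m <- stats::rpois(1, 320)
    fit_time_field(stats::runif(m, 0, 8), 40, 8, n_starts = 10,
                   seed = i)$llr
  }, 0)
  fpr <- mean(llrs > 5.66)
  expect_gte(fpr, 0.001)
  expect_lte(fpr, 0.05)
})

test_that("unit bookkeeping removes boundary and low-trial cells in order", {
  # 159 screened cells: 14 with peaks outside the bounds, then 14 of the
  # remainder with fewer than 20 spiking trials -> 131 survive
  tbl <- tibble::tibble(
    unit_id = sprintf("u%03d", 1:159),
    mu_hat = c(runif(7, 0.1, 0.3), runif(7, 7.3, 7.9),
               runif(145, 0.4, 7.1)),
    n_trials = c(rep(40, 14), rep(15, 14), rep(40, 131))
  )
  kept <- filter_for_hbm(tbl, c(0.35, 7.2), min_trials = 20)
  expect_equal(nrow(kept), 131)
  expect_equal(attr(kept, "n_boundary_removed"), 14)
  expect_equal(attr(kept, "n_low_trial_removed"), 14)

  # identity when nothing is excluded; exactly-20 trials is retained
  tbl2 <- tibble::tibble(unit_id = c("a", "b"), mu_hat = c(1, 5),
                         n_trials = c(20, 30))
  kept2 <- filter_for_hbm(tbl2, c(0.35, 7.2))
  expect_equal(kept2$unit_id, c("a", "b"))
  # idempotent and order-stable
  again <- filter_for_hbm(kept, c(0.35, 7.2), min_trials = 20)
  expect_equal(again$unit_id, kept$unit_id)
})

test_that("bounds search walks its grid and honours degenerate input", {
  set.seed(8)
  peaks <- rbpowerlaw(150, 1, 0.35, 7.2)
  b <- select_bounds(peaks, estimator = "ml")
  expect_equal(nrow(b$grid), 7 * 5)
  expect_true(all(!b$grid$skipped))
  # single-pair grid returns that pair
  b1 <- select_bounds(peaks, lower_grid = 0.35, upper_grid = 7.2,
                      estimator = "ml")
  expect_equal(c(b1$chosen_lower, b1$chosen_upper), c(0.35, 7.2))
  expect_equal(nrow(b1$grid), 1)
  # pairs leaving too few peaks are skipped with a warning
  expect_warning(
    select_bounds(peaks[1:12], lower_grid = c(0.35, 7.0),
                  upper_grid = 7.2, estimator = "ml", min_peaks = 10),
    "skipped")
})

test_that("exponent estimators agree with each other on clean data", {
  set.seed(9)
  x <- rbpowerlaw(2000, 1, 0.35, 7.2)
  a_ml <- fit_bpl_alpha(x, 0.35, 7.2, "ml")
  a_post <- fit_bpl_alpha(x, 0.35, 7.2, "posterior")
  expect_equal(a_ml, 1, tolerance = 0.1)
  expect_equal(a_post, a_ml, tolerance = 0.02)
})
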