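test_that("degenerate parameter settings collapse to their closed forms", {
  set.seed(1)
  # a1 = 0: pure uniform background
  cell <- simulate_cell(M = 4, sigma_w = 0.5, sigma_t = 0.5, a1 = 0,
                        spikes_per_trial_mean = 100, n_trials = 100,
                        delay = 8)
  expect_equal(mean(cell$spikes$spike_time_s), 4, tolerance = 0.08)
  # sigma_t = 0: every trial's field at M exactly
  cell <- simulate_cell(M = 3, sigma_w = 0.4, sigma_t = 0, a1 = 0.8,
                        spikes_per_trial_mean = 10, n_trials = 30, delay = 8)
  expect_true(all(cell$trials$mu_i == 3))
  # pure field far from the edges: pooled sd recovers sigma_w
  set.seed(2)
  cell <- simulate_cell(M = 4, sigma_w = 0.5, sigma_t = 0, a1 = 1,
                        spikes_per_trial_mean = 100, n_trials = 100,
                        delay = 8)
  expect_equal(stats::sd(cell$spikes$spike_time_s), 0.5, tolerance = 0.02)
  expect_error(simulate_cell(4, -1, 0, 0.5, 10, 10, 8), "sigma_w")
})

test_that("spikes and trial fields always stay inside the delay", {
  set.seed(3)
  # peak near the boundary with large jitter: resampling keeps everything in
  cell <- simulate_cell(M = 7.5, sigma_w = 1, sigma_t = 2, a1 = 0.9,
                        spikes_per_trial_mean = 20, n_trials = 200, delay = 8)
  expect_true(all(cell$spikes$spike_time_s >= 0 &
                    cell$spikes$spike_time_s <= 8))
  expect_true(all(cell$trials$mu_i >= 0 & cell$trials$mu_i <= 8))
  # spikes sorted within trial
  by_trial <- split(cell$spikes$spike_time_s, cell$spikes$trial_id)
  expect_true(all(vapply(by_trial, function(v) !is.unsorted(v), TRUE)))
})

test_that("population generation is reproducible and obeys its laws", {
  cfg <- generator_config(n_time_cells = 131, n_distractor_cells = 4,
                          n_interneurons = 2, trials_per_cell = 20, seed = 7)
  sim1 <- simulate_population(cfg)
  sim2 <- simulate_population(cfg)
  expect_identical(sim1$spikes, sim2$spikes)
  expect_identical(sim1$truth_cells, sim2$truth_cells)

  tc <- sim1$truth_cells[sim1$truth_cells$kind == "time_cell", ]
  expect_equal(nrow(tc), 131)
  expect_true(all(tc$M >= 0.35 & tc$M <= 7.2))
  # width and jitter laws are deterministic functions of M
  fit <- stats::lm(sigma_w ~ M, data = tc)
  expect_equal(unname(stats::coef(fit)), c(0.11, 0.14), tolerance = 1e-10)
  expect_equal(tc$sigma_t,
               pmax(0.05, -0.33 + 0.84 * tc$M - 0.11 * tc$M^2),
               tolerance = 1e-12)

  # interneurons fire above the 5 Hz ceiling, distractors below
  us <- unit_summary(sim1$spikes, sim1$delay)
  us$kind <- sim1$truth_cells$kind[match(us$unit_id, sim1$truth_cells$unit_id)]
  expect_true(all(us$mean_rate[us$kind == "interneuron"] > 5))
  expect_true(all(us$mean_rate[us$kind == "time_cell"] < 5))
})

test_that("event coupling moves trial fields; zero coupling does not", {
  cfg0 <- generator_config(n_time_cells = 30, n_distractor_cells = 0,
                           n_interneurons = 0, trials_per_cell = 40,
                           event_coupling = 0, seed = 21)
  sim0 <- simulate_population(cfg0)
  r0 <- sim0$truth_trials |>
    dplyr::filter(!is.na(.data$mu_i)) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(r = stats::cor(.data$mu_i, .data$event_offset_s))
  expect_lt(abs(mean(r0$r)), 0.07)

  cfg1 <- generator_config(n_time_cells = 30, n_distractor_cells = 0,
                           n_interneurons = 0, trials_per_cell = 40,
                           event_coupling = 1, seed = 21)
  sim1 <- simulate_population(cfg1)
  truth <- sim1$truth_cells
  early <- truth$unit_id[truth$kind == "time_cell" & truth$M < 1]
  r1 <- sim1$truth_trials |>
    dplyr::filter(.data$unit_id %in% early) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(r = stats::cor(.data$mu_i, .data$event_offset_s))
  expect_gt(mean(r1$r), 0.3)
})
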