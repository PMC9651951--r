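test_that("trial mixture density matches hand-computed values", {
  # pure background: log(1/l) regardless of t
  expect_equal(dfield_mixture(c(0, 3, 8), 0, 4, 1, 8, log = TRUE),
               rep(log(0.125), 3))
  # pure field at its mode
  expect_equal(dfield_mixture(4, 1, 4, 0.7, 8, log = TRUE),
               -log(0.7 * sqrt(2 * pi)))
  # half-and-half at the mode: 0.5 * dnorm(0) + 0.5 / 8
  expect_equal(dfield_mixture(4, 0.5, 4, 1, 8, log = TRUE),
               log(0.5 * stats::dnorm(0) + 0.5 / 8))
  expect_equal(dfield_mixture(4, 0.5, 4, 1, 8), 0.261971, tolerance = 1e-6)
  expect_error(dfield_mixture(9, 0.5, 4, 1, 8), "outside")
  expect_error(dfield_mixture(4, 0.5, 4, -1, 8), "sigma_w")
})

test_that("log-normal field density and width summary are correct", {
  expect_equal(dlognormal_mixture(2, 0, 0, 1, 8, log = TRUE), log(1 / 8))
  # log-normal density at its median (mu = 0 -> t = 1): 1/sqrt(2 pi)
  expect_equal(dlognormal_mixture(1, 1, 0, 1, 8, log = TRUE),
               log(1 / sqrt(2 * pi)))
  expect_error(dlognormal_mixture(0, 1, 0, 1, 8), "t > 0")
  # closed form sd against Monte Carlo
  expect_equal(lognormal_sd(0, 1), sqrt((exp(1) - 1) * exp(1)),
               tolerance = 1e-12)
  set.seed(1)
  mc <- stats::sd(stats::rlnorm(1e6, 0, 1))
  expect_equal(lognormal_sd(0, 1), mc, tolerance = 0.01)
})

test_that("population log-densities match closed forms", {
  # bounded power law: alpha = 0 is uniform; alpha = 1 on [1, e] has C = 1
  expect_equal(dbpowerlaw(2, 0, 0.35, 7.2), 1 / (7.2 - 0.35))
  expect_equal(dbpowerlaw(1, 1, 1, exp(1)), 1)
  expect_equal(dbpowerlaw(2, 2, 1, 4), (1 / 4) / 0.75)
  # exponential near zero approaches its rate
  expect_equal(dpop_exponential(1e-12, 1), 1, tolerance = 1e-10)
  # Weibull closed form and its exponential special case
  expect_equal(dpop_weibull(1, 2, 1), 2 * exp(-1))
  tau <- c(0.5, 1.3, 4)
  expect_equal(dpop_weibull(tau, 1, 2, lower = 0.35, upper = 7.2),
               dpop_exponential(tau, 1 / 2, lower = 0.35, upper = 7.2))
  # truncated versions integrate to one
  for (f in list(
    function(x) dpop_exponential(x, 0.7, lower = 0.35, upper = 7.2),
    function(x) dpop_weibull(x, 1.6, 2.2, lower = 0.35, upper = 7.2))) {
    expect_equal(stats::integrate(f, 0.35, 7.2, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-6)
  }
  # the untruncated field mixture integrates to one over the real line plus
  # the background over the delay (the field term deliberately leaks mass
  # outside the delay)
  tot <- stats::integrate(function(x) 0.6 * stats::dnorm(x, 7, 1), -Inf, Inf,
                          rel.tol = 1e-10)$value + 0.4
  expect_equal(tot, 1, tolerance = 1e-8)
})

test_that("a single cell's parameters are recovered from its spikes", {
  set.seed(11)
  cell <- simulate_cell(M = 4, sigma_w = 0.5, sigma_t = 0, a1 = 1,
                        spikes_per_trial_mean = 30, n_trials = 50, delay = 8)
  spikes <- dplyr::mutate(cell$spikes, unit_id = "c1", .before = 1)
  fit <- fit_hbm(spikes, 8, c(0.35, 7.2), "main",
                 control = mcmc_control(chains = 2, warmup = 500,
                                        samples = 300, seed = 2))
  expect_equal(fit$cells$M, 4, tolerance = 0.1)
  expect_equal(fit$cells$sigma_w, 0.5, tolerance = 0.1)
  expect_gt(fit$cells$a1, 0.9)
  expect_equal(fit$trials$mu_i, rep(4, 50), tolerance = 0.15)
  # draws respect their supports
  expect_true(all(fit$population$alpha >= 0 & fit$population$alpha <= 10))
  expect_true(all(fit$cells$M >= 0.35 & fit$cells$M <= 7.2))
})

test_that("fixing the exponent pins its draws", {
  sim <- small_sim()
  tc <- sim$truth_cells$unit_id[sim$truth_cells$kind == "time_cell"]
  fit <- fit_hbm(sim$spikes, sim$delay, c(0.35, 7.2), "main", subset = tc,
                 control = mcmc_control(chains = 2, warmup = 200,
                                        samples = 100, seed = 3),
                 priors = hbm_priors(alpha_fixed = 0))
  expect_true(all(fit$population$alpha == 0))
  expect_false("alpha" %in% fit$diagnostics$parameter)
})

test_that("every variant fits and returns coherent structures", {
  sim <- small_sim()
  tc <- sim$truth_cells$unit_id[sim$truth_cells$kind == "time_cell"]
  for (v in c("lognormal_field", "trial_vary_width", "exponential_pop",
              "weibull_pop")) {
    fit <- fit_hbm(sim$spikes, sim$delay, c(0.35, 7.2), v, subset = tc,
                   control = mcmc_control(chains = 2, warmup = 300,
                                          samples = 150, seed = 4))
    expect_s3_class(fit, "hbm_fit")
    expect_equal(nrow(fit$cells), length(tc))
    expect_equal(nrow(fit$loglik), 2 * 150)
    expect_equal(ncol(fit$loglik), nrow(fit$trials))
    expect_true(all(is.finite(fit$loglik)))
    g <- glance(fit)
    expect_equal(g$variant, v)
    if (v == "exponential_pop") expect_true("beta" %in% names(fit$population))
    if (v == "weibull_pop") {
      expect_true(all(c("k", "lambda") %in% names(fit$population)))
    }
  }
  expect_error(fit_hbm(sim$spikes[0, ], sim$delay, c(0.35, 7.2)), "empty")
})

test_that("tidiers expose the fit at each level", {
  sim <- small_sim()
  tc <- sim$truth_cells$unit_id[sim$truth_cells$kind == "time_cell"]
  fit <- fit_hbm(sim$spikes, sim$delay, c(0.35, 7.2), "main", subset = tc,
                 control = mcmc_control(chains = 2, warmup = 200,
                                        samples = 100, seed = 5))
  expect_true(all(c("unit_id", "M", "sigma_w", "sigma_t", "a1") %in%
                    names(tidy(fit))))
  expect_equal(nrow(tidy(fit, "trials")), nrow(fit$trials))
  expect_true(all(c(".chain", ".draw") %in% names(tidy(fit, "population"))))
  expect_s3_class(autoplot(fit, "alpha"), "ggplot")
  expect_s3_class(autoplot(fit, "width"), "ggplot")
  expect_s3_class(autoplot(fit, "cdf"), "ggplot")
})
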