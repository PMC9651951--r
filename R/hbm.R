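#' Mixture and population log-densities
#'
#' `dfield_mixture()` is the per-spike density of the trial-level model: a
#' fraction `a1` of spikes comes from a Gaussian time field centred at `mu`
#' with sd `sigma_w`, the rest from a uniform background over the delay:
#' \deqn{p(t) = a_1 N(t | \mu, \sigma_w^2) + (1 - a_1)/l.}
#' `dlognormal_mixture()` replaces the Gaussian by a log-normal field with
#' median `exp(meanlog)` and log-scale width `sdlog`. The field terms are
#' deliberately not truncated to the delay: spikes in the tails are absorbed
#' by the uniform component.
#'
#' @param t spike time(s) in `[0, delay]` (`> 0` for the log-normal field).
#' @param a1 in-field fraction in `[0, 1]`.
#' @param mu field centre (seconds).
#' @param sigma_w within-trial field width (seconds, `> 0`).
#' @param meanlog,sdlog log-normal field parameters.
#' @param delay delay length (seconds).
#' @param log return the log density.
#' @return density (or log density) values.
#' @export
dfield_mixture <- function(t, a1, mu, sigma_w, delay, log = FALSE) {
  stopifnot(a1 >= 0, a1 <= 1, delay > 0)
  if (a1 > 0 && sigma_w <= 0) stop("sigma_w must be positive", call. = FALSE)
  if (any(t < 0 | t > delay)) {
    stop("spike time outside [0, delay]", call. = FALSE)
  }
  d <- a1 * stats::dnorm(t, mu, sigma_w) + (1 - a1) / delay
  if (log) base::log(d) else d
}

#' @rdname dfield_mixture
#' @export
dlognormal_mixture <- function(t, a1, meanlog, sdlog, delay, log = FALSE) {
  stopifnot(a1 >= 0, a1 <= 1, delay > 0, sdlog > 0)
  if (any(t <= 0)) stop("log-normal field requires t > 0", call. = FALSE)
  d <- a1 * stats::dlnorm(t, meanlog, sdlog) + (1 - a1) / delay
  if (log) base::log(d) else d
}

#' Standard deviation of a log-normal time field
#'
#' The width summary used for the log-normal field variant:
#' \eqn{\sqrt{(e^{\sigma^2} - 1) e^{2\mu + \sigma^2}}}.
#'
#' @param meanlog,sdlog log-normal parameters.
#' @return the standard deviation of the log-normal distribution.
#' @export
lognormal_sd <- function(meanlog, sdlog) {
  sqrt(expm1(sdlog^2) * exp(2 * meanlog + sdlog^2))
}

#' Population laws for time-field peaks
#'
#' Density of the peak-time distribution under the exponential and Weibull
#' alternatives, optionally renormalised to a bounded support (as used inside
#' the hierarchical fits, where peaks are restricted to the screened range).
#' With `lower = NULL` the unbounded density is returned. A Weibull with
#' `shape = 1` reduces to the exponential with `rate = 1/scale`.
#'
#' @param tau peak time(s), `> 0`.
#' @param rate exponential rate `beta` (1/seconds).
#' @param shape,scale Weibull parameters (`k`, `lambda`).
#' @param lower,upper optional truncation bounds (seconds).
#' @param log return the log density.
#' @return density (or log density) values; zero outside `[lower, upper]`
#'   when bounds are supplied.
#' @export
dpop_exponential <- function(tau, rate, lower = NULL, upper = NULL,
                             log = FALSE) {
  stopifnot(rate > 0)
  if (any(tau <= 0)) stop("tau must be positive", call. = FALSE)
  ld <- stats::dexp(tau, rate, log = TRUE)
  if (!is.null(lower)) {
    lognorm <- base::log(stats::pexp(upper, rate) - stats::pexp(lower, rate))
    ld <- ld - lognorm
    ld[tau < lower | tau > upper] <- -Inf
  }
  if (log) ld else exp(ld)
}

#' @rdname dpop_exponential
#' @export
dpop_weibull <- function(tau, shape, scale, lower = NULL, upper = NULL,
                         log = FALSE) {
  stopifnot(shape > 0, scale > 0)
  if (any(tau <= 0)) stop("tau must be positive", call. = FALSE)
  ld <- stats::dweibull(tau, shape, scale, log = TRUE)
  if (!is.null(lower)) {
    lognorm <- base::log(stats::pweibull(upper, shape, scale) -
                           stats::pweibull(lower, shape, scale))
    ld <- ld - lognorm
    ld[tau < lower | tau > upper] <- -Inf
  }
  if (log) ld else exp(ld)
}

#' MCMC settings and priors for the hierarchical fits
#'
#' The default schedule mirrors the original analysis (8 chains, 4800 warmup
#' iterations, 200 kept draws per chain); tests and examples use a reduced
#' schedule (e.g. 4 chains, 1000 warmup, 500 kept). Priors are weakly
#' informative and support-respecting: the exponent `alpha` is Uniform(0,
#' `alpha_max`); per-cell `a1` is Beta(2, 2); the width and jitter scales are
#' Half-Normal(0, 2 s). `alpha_fixed` pins the exponent (e.g. at 0 to force a
#' uniform population law).
#'
#' @param chains,warmup,samples MCMC schedule (per chain).
#' @param seed integer seed; chain seeds are derived deterministically.
#' @param sw_scale,st_scale Half-Normal scales (seconds) for `sigma_w` (or
#'   `sigma_W` / log-normal shape) and `sigma_t`.
#' @param a1_shape1,a1_shape2 Beta prior for the in-field fraction.
#' @param alpha_max upper end of the Uniform prior on the exponent.
#' @param alpha_fixed optional fixed value for the exponent.
#' @param beta_max upper end of the flat prior on the exponential rate.
#' @param k_min,k_max,lambda_min,lambda_max flat prior ranges for the Weibull
#'   shape and scale.
#' @return lists of class `mcmc_control` / `hbm_priors`.
#' @export
mcmc_control <- function(chains = 8, warmup = 4800, samples = 200, seed = 1L) {
  stopifnot(chains >= 1, warmup >= 1, samples >= 2)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 samples = as.integer(samples), seed = as.integer(seed)),
            class = "mcmc_control")
}

#' @rdname mcmc_control
#' @export
hbm_priors <- function(sw_scale = 2, st_scale = 2, a1_shape1 = 2,
                       a1_shape2 = 2, alpha_max = 10, alpha_fixed = NULL,
                       beta_max = 10, k_min = 0.1, k_max = 10,
                       lambda_min = 0.05, lambda_max = 20) {
  structure(list(sw_scale = sw_scale, st_scale = st_scale,
                 a1_shape1 = a1_shape1, a1_shape2 = a1_shape2,
                 alpha_max = alpha_max,
                 alpha_fixed = !is.null(alpha_fixed),
                 alpha_fix_value = if (is.null(alpha_fixed)) 1 else alpha_fixed,
                 beta_max = beta_max, k_min = k_min, k_max = k_max,
                 lambda_min = lambda_min, lambda_max = lambda_max),
            class = "hbm_priors")
}

variant_code <- function(variant) {
  match(variant, c("main", "lognormal_field", "trial_vary_width",
                   "exponential_pop", "weibull_pop")) - 1L
}

#' Fit a hierarchical Bayesian time-field model
#'
#' Fits one of five model variants jointly across all levels by adaptive
#' Metropolis-within-Gibbs sampling:
#' \describe{
#'   \item{main}{Gaussian field; per-trial location `mu_i ~ N(M, sigma_t^2)`;
#'     peaks `M ~ tau^-alpha` on `bounds`.}
#'   \item{lognormal_field}{log-normal field with per-trial median `mu_i`;
#'     otherwise as main.}
#'   \item{trial_vary_width}{field location fixed at `M`; per-trial width
#'     `sigma_wi ~ N(sigma_W, sigma_t^2)` (positive); otherwise as main.}
#'   \item{exponential_pop}{peaks follow an exponential law renormalised to
#'     `bounds`; otherwise as main.}
#'   \item{weibull_pop}{peaks follow a Weibull law renormalised to `bounds`;
#'     otherwise as main.}
#' }
#'
#' @param spikes tibble with `unit_id`, `trial_id`, `spike_time_s`.
#' @param delay delay length (seconds).
#' @param bounds numeric `c(lower, upper)`: support of the peak distribution
#'   (from [select_bounds()]).
#' @param variant model variant, see Details.
#' @param subset optional character vector of `unit_id`s to fit (typically
#'   from [filter_for_hbm()]).
#' @param control an [mcmc_control()].
#' @param priors an [hbm_priors()].
#' @return object of class `hbm_fit` with elements
#' \describe{
#'   \item{population}{tibble of population-level draws (`alpha`, or `beta`,
#'     or `k` and `lambda`) with chain and draw indices}
#'   \item{cells}{tibble of per-cell posterior means and sds (`M`, `sigma_w`,
#'     `sigma_t`, `a1`)}
#'   \item{trials}{tibble of per-trial posterior means (`mu_i`, or the
#'     per-trial width for the trial-vary-width variant)}
#'   \item{loglik}{draws x (cell, trial) matrix of pointwise log-likelihoods}
#'   \item{waic}{[compute_waic()] result}
#'   \item{diagnostics}{tibble of split-Rhat and bulk ESS for population
#'     parameters and per-cell peaks; `converged` flags Rhat <= 1.05}
#' }
#' @export
fit_hbm <- function(spikes, delay, bounds,
                    variant = c("main", "lognormal_field", "trial_vary_width",
                                "exponential_pop", "weibull_pop"),
                    subset = NULL, control = mcmc_control(),
                    priors = hbm_priors()) {
  variant <- match.arg(variant)
  stopifnot(inherits(control, "mcmc_control"), inherits(priors, "hbm_priors"),
            length(bounds) == 2, bounds[1] > 0, bounds[1] < bounds[2])
  if (!is.null(subset)) spikes <- spikes[spikes$unit_id %in% subset, ]
  if (nrow(spikes) == 0) stop("no spikes to fit (empty subset?)", call. = FALSE)

  spikes <- dplyr::arrange(spikes, .data$unit_id, .data$trial_id,
                           .data$spike_time_s)
  cells <- unique(spikes$unit_id)
  nc <- length(cells)
  trial_key <- dplyr::distinct(spikes, .data$unit_id, .data$trial_id)
  ntr <- nrow(trial_key)

  trial_index <- paste(spikes$unit_id, spikes$trial_id)
  tkey <- paste(trial_key$unit_id, trial_key$trial_id)
  tcount <- as.integer(table(factor(trial_index, levels = tkey)))
  toff <- c(0L, cumsum(tcount))
  cell_ntr <- as.integer(table(factor(trial_key$unit_id, levels = cells)))
  coff <- c(0L, cumsum(cell_ntr))

  vc <- variant_code(variant)
  pmin_ <- bounds[1]; pmax_ <- bounds[2]

  # data-driven initial values, jittered per chain
  trial_means <- vapply(seq_len(ntr), function(ti) {
    idx <- (toff[ti] + 1):toff[ti + 1]
    if (toff[ti + 1] > toff[ti]) stats::median(spikes$spike_time_s[idx])
    else delay / 2
  }, 0)
  M0 <- vapply(seq_len(nc), function(c) {
    stats::median(trial_means[(coff[c] + 1):coff[c + 1]])
  }, 0)
  M0 <- pmin(pmax(M0, pmin_ + 1e-3), pmax_ - 1e-3)
  st0 <- vapply(seq_len(nc), function(c) {
    s <- stats::sd(trial_means[(coff[c] + 1):coff[c + 1]])
    max(ifelse(is.na(s), 0.3, s), 0.1)
  }, 0)

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(control$seed)

  chains <- vector("list", control$chains)
  for (ch in seq_len(control$chains)) {
    init <- list(
      M = pmin(pmax(M0 * exp(stats::rnorm(nc, 0, 0.05)), pmin_ + 1e-3),
               pmax_ - 1e-3),
      sw = if (variant == "lognormal_field") {
        stats::runif(nc, 0.1, 0.4)            # log-scale shape
      } else stats::runif(nc, 0.3, 0.8),
      st = st0 * exp(stats::rnorm(nc, 0, 0.1)),
      a1 = stats::runif(nc, 0.5, 0.9),
      mu = if (variant == "trial_vary_width") {
        stats::runif(ntr, 0.3, 0.8)           # per-trial widths
      } else pmax(trial_means, 0.01),
      alpha = stats::runif(1, 0.3, 2),
      beta = stats::runif(1, 0.2, 1),
      k = stats::runif(1, 0.8, 1.5),
      lambda = stats::runif(1, 1, 4)
    )
    chain_seed <- (as.double(control$seed) * 1009 + ch * 7919) %% 2^31
    chains[[ch]] <- hbm_chain_cpp(
      spikes$spike_time_s, toff, coff, delay, pmin_, pmax_, vc,
      unclass(priors), init, control$warmup, control$samples, chain_seed
    )
  }

  pop_names <- switch(variant,
    exponential_pop = "beta",
    weibull_pop = c("k", "lambda"),
    "alpha")
  pop <- purrr::imap(chains, function(chn, ch) {
    d <- as.data.frame(chn$pop)
    names(d) <- pop_names
    d$.chain <- ch
    d$.draw <- seq_len(nrow(d))
    tibble::as_tibble(d)
  }) |> dplyr::bind_rows()

  cell_draws <- do.call(rbind, lapply(chains, `[[`, "cells"))
  mu_draws <- do.call(rbind, lapply(chains, `[[`, "mu"))
  ll_draws <- do.call(rbind, lapply(chains, `[[`, "loglik"))

  col_mean <- colMeans(cell_draws)
  col_sd <- apply(cell_draws, 2, stats::sd)
  pick <- function(stat, block) stat[(block * nc + 1):((block + 1) * nc)]
  cells_tbl <- tibble::tibble(
    unit_id = cells,
    n_trials = cell_ntr,
    M = pick(col_mean, 0), M_sd = pick(col_sd, 0),
    sigma_w = pick(col_mean, 1), sigma_w_sd = pick(col_sd, 1),
    sigma_t = pick(col_mean, 2), sigma_t_sd = pick(col_sd, 2),
    a1 = pick(col_mean, 3), a1_sd = pick(col_sd, 3)
  )
  if (variant == "lognormal_field") {
    # cell-level width summary: sd of the log-normal field at the mean peak
    cells_tbl$field_width <- lognormal_sd(log(cells_tbl$M), cells_tbl$sigma_w)
  } else {
    cells_tbl$field_width <- cells_tbl$sigma_w
  }

  trials_tbl <- trial_key
  trials_tbl$mu_i <- colMeans(mu_draws)
  trials_tbl$mu_i_sd <- apply(mu_draws, 2, stats::sd)

  # diagnostics: population params + per-cell M
  diag_scalar <- function(mat_list, name) {
    tibble::tibble(parameter = name,
                   rhat = split_rhat(mat_list),
                   ess = bulk_ess(mat_list))
  }
  diags <- list()
  for (j in seq_along(pop_names)) {
    if (pop_names[j] == "alpha" && priors$alpha_fixed) next
    diags[[length(diags) + 1]] <- diag_scalar(
      lapply(chains, function(ch) ch$pop[, j]), pop_names[j])
  }
  for (c in seq_len(nc)) {
    diags[[length(diags) + 1]] <- diag_scalar(
      lapply(chains, function(ch) ch$cells[, c]), paste0("M[", cells[c], "]"))
  }
  diagnostics <- dplyr::bind_rows(diags)
  diagnostics$converged <- diagnostics$rhat <= 1.05

  structure(list(
    variant = variant, bounds = bounds, delay = delay,
    control = control, priors = priors,
    population = pop, cells = cells_tbl, trials = trials_tbl,
    loglik = ll_draws, waic = compute_waic(ll_draws),
    diagnostics = diagnostics
  ), class = "hbm_fit")
}

#' @export
print.hbm_fit <- function(x, ...) {
  cat(sprintf("hierarchical time-field fit (variant: %s)\n", x$variant))
  cat(sprintf("  %d cells, %d trials; bounds [%g, %g] s; delay %g s\n",
              nrow(x$cells), nrow(x$trials), x$bounds[1], x$bounds[2],
              x$delay))
  cat(sprintf("  %d chains x %d draws\n", x$control$chains,
              x$control$samples))
  pop_pars <- setdiff(names(x$population), c(".chain", ".draw"))
  for (p in pop_pars) {
    d <- x$population[[p]]
    cat(sprintf("  %s: mean %.3f, 95%% CI [%.3f, %.3f]\n", p, mean(d),
                stats::quantile(d, 0.025), stats::quantile(d, 0.975)))
  }
  cat(sprintf("  WAIC %.1f (p_waic %.1f)\n", x$waic$waic, x$waic$p_waic))
  bad <- sum(!x$diagnostics$converged)
  if (bad > 0) cat(sprintf("  WARNING: %d parameters with Rhat > 1.05\n", bad))
  invisible(x)
}

# split-Rhat (potential scale reduction) over a list of per-chain vectors
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    n <- length(v) %/% 2
    list(v[1:n], v[(n + 1):(2 * n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# bulk effective sample size (Geyer initial-positive-sequence estimate)
bulk_ess <- function(chains) {
  m <- length(chains); n <- length(chains[[1]])
  ac <- sapply(chains, function(v) {
    if (stats::sd(v) == 0) return(rep(0, min(n - 1, 100)))
    a <- stats::acf(v, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
    as.numeric(a)
  })
  rho <- rowMeans(ac)
  # sum consecutive pairs while positive
  s <- 0
  for (k in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  m * n / (1 + 2 * s)
}
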