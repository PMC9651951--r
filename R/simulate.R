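#' Configuration for the time-cell spike-train simulator
#'
#' Collects every knob of the synthetic population in one list. Defaults
#' mirror the delayed-treadmill study design the package targets: an 8 s
#' delay, 131 time cells whose peaks tile `[0.35, 7.2]` s with power-law
#' exponent `alpha = 1` (logarithmic compression), within-trial field width
#' growing linearly with peak time (`sigma_w = 0.11 + 0.14 M`), across-trial
#' jitter of field location following a quadratic law
#' (`sigma_t = -0.33 + 0.84 M - 0.11 M^2`, floored at `sigma_t_floor`),
#' and a spike mixture with a uniform background.
#'
#' @param n_time_cells number of genuine time cells.
#' @param n_distractor_cells pyramidal-like units with purely uniform firing
#'   (`a1 = 0`), used to exercise the screening stage.
#' @param n_interneurons uniform-firing units at 6-10 Hz, above the pyramidal
#'   rate ceiling.
#' @param trials_per_cell trials per unit (study required `>= 20`).
#' @param delay delay length `l` in seconds.
#' @param alpha population compression exponent (`>= 0`; 1 = logarithmic).
#' @param peak_min,peak_max support of the peak distribution (seconds).
#' @param width_intercept,width_slope within-trial width law
#'   `sigma_w(M) = width_intercept + width_slope * M`.
#' @param trialvar_coeffs `c(c0, c1, c2)` of the across-trial jitter law
#'   `sigma_t(M) = c0 + c1 M + c2 M^2`.
#' @param sigma_t_floor lower clip for `sigma_t` (seconds); the fitted
#'   quadratic is negative near `M = 0`.
#' @param a1 in-field spike fraction, in `(0, 1]`.
#' @param spikes_per_trial_mean Poisson mean spike count per trial.
#' @param event_coupling gain linking the per-trial behavioural event offset
#'   to the field-location shift. The effective gain decays linearly with the
#'   cell's peak, reaching 0 at `event_coupling_zero_at` seconds, emulating
#'   the finding that early-firing cells track treadmill-entry timing.
#' @param event_coupling_zero_at peak time (seconds) at which the coupling
#'   gain reaches zero.
#' @param event_sd standard deviation (seconds) of the per-trial event offset
#'   (time from treadmill entry to beam break).
#' @param field_shape `"gaussian"` or `"lognormal"` within-trial field.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_time_cells = 131,
                             n_distractor_cells = 20,
                             n_interneurons = 8,
                             trials_per_cell = 40,
                             delay = 8,
                             alpha = 1,
                             peak_min = 0.35,
                             peak_max = 7.2,
                             width_intercept = 0.11,
                             width_slope = 0.14,
                             trialvar_coeffs = c(-0.33, 0.84, -0.11),
                             sigma_t_floor = 0.05,
                             a1 = 0.8,
                             spikes_per_trial_mean = 15,
                             event_coupling = 1,
                             event_coupling_zero_at = 2,
                             event_sd = 0.3,
                             field_shape = c("gaussian", "lognormal"),
                             seed = 1L) {
  field_shape <- match.arg(field_shape)
  stopifnot(peak_min > 0, peak_min < peak_max, peak_max <= delay,
            alpha >= 0, a1 > 0, a1 <= 1, trials_per_cell >= 1,
            spikes_per_trial_mean > 0, length(trialvar_coeffs) == 3)
  cfg <- list(
    n_time_cells = n_time_cells, n_distractor_cells = n_distractor_cells,
    n_interneurons = n_interneurons, trials_per_cell = trials_per_cell,
    delay = delay, alpha = alpha, peak_min = peak_min, peak_max = peak_max,
    width_intercept = width_intercept, width_slope = width_slope,
    trialvar_coeffs = trialvar_coeffs, sigma_t_floor = sigma_t_floor,
    a1 = a1, spikes_per_trial_mean = spikes_per_trial_mean,
    event_coupling = event_coupling,
    event_coupling_zero_at = event_coupling_zero_at,
    event_sd = event_sd, field_shape = field_shape, seed = as.integer(seed)
  )
  # width/jitter laws must stay valid over the peak support after clipping
  Mgrid <- seq(peak_min, peak_max, length.out = 64)
  if (any(cfg$width_intercept + cfg$width_slope * Mgrid <= 0)) {
    stop("width law gives non-positive sigma_w on [peak_min, peak_max].",
         call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

sigma_w_law <- function(M, config) config$width_intercept + config$width_slope * M

sigma_t_law <- function(M, config) {
  co <- config$trialvar_coeffs
  pmax(config$sigma_t_floor, co[1] + co[2] * M + co[3] * M^2)
}

# draw from N(mean, sd) truncated to [lo, hi] (the resampling convention for
# per-trial field locations and in-field spikes)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (length(mean) == 1) mean <- rep(mean, n)
  if (sd == 0) return(pmin(pmax(mean, lo), hi))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  # guard the extreme tail where plo ~ phi
  out <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
  pmin(pmax(out, lo), hi)
}

#' Simulate spike trains for a single unit
#'
#' Per trial, a field location `mu_i ~ N(M, sigma_t^2)` is drawn (resampled
#' into `[0, delay]`), the spike count is Poisson, and each spike comes from
#' the field (probability `a1`; Gaussian with sd `sigma_w` centred at `mu_i`,
#' or a log-normal with median `mu_i` when `field_shape = "lognormal"`) or
#' from the uniform background on `[0, delay]`. Field spikes falling outside
#' the delay are resampled, not clipped.
#'
#' @param M mean peak time (seconds).
#' @param sigma_w within-trial field width (seconds, `> 0` when `a1 > 0`).
#' @param sigma_t across-trial jitter of the field location (seconds, `>= 0`).
#' @param a1 in-field spike fraction in `[0, 1]`.
#' @param spikes_per_trial_mean Poisson mean count per trial.
#' @param n_trials number of trials.
#' @param delay delay length (seconds).
#' @param field_shape `"gaussian"` or `"lognormal"`.
#' @param mu_shift optional per-trial shift added to `mu_i` (length
#'   `n_trials`), used for behavioural event coupling.
#' @return list with `spikes` (tibble `trial_id`, `spike_time_s`) and
#'   `trials` (tibble `trial_id`, `mu_i`). Uses the current RNG stream.
#' @export
simulate_cell <- function(M, sigma_w, sigma_t, a1, spikes_per_trial_mean,
                          n_trials, delay, field_shape = "gaussian",
                          mu_shift = NULL) {
  if (a1 > 0 && sigma_w <= 0) {
    stop("`sigma_w` must be positive when `a1 > 0`.", call. = FALSE)
  }
  stopifnot(a1 >= 0, a1 <= 1, sigma_t >= 0, M >= 0, M <= delay)
  if (is.null(mu_shift)) mu_shift <- rep(0, n_trials)

  mu_i <- rtruncnorm(n_trials, M + mu_shift, sigma_t, 0, delay)
  counts <- stats::rpois(n_trials, spikes_per_trial_mean)

  spikes <- lapply(seq_len(n_trials), function(i) {
    m <- counts[i]
    if (m == 0) return(numeric(0))
    infield <- stats::runif(m) < a1
    t <- stats::runif(m, 0, delay)
    k <- sum(infield)
    if (k > 0) {
      if (field_shape == "lognormal") {
        sdlog <- sqrt(log1p((sigma_w / mu_i[i])^2))
        x <- stats::rlnorm(k, meanlog = log(mu_i[i]), sdlog = sdlog)
        bad <- x > delay
        while (any(bad)) {
          x[bad] <- stats::rlnorm(sum(bad), log(mu_i[i]), sdlog)
          bad <- x > delay
        }
      } else {
        x <- rtruncnorm(k, mu_i[i], sigma_w, 0, delay)
      }
      t[infield] <- x
    }
    sort(t)
  })
  list(
    spikes = tibble::tibble(
      trial_id = rep(seq_len(n_trials), vapply(spikes, length, 1L)),
      spike_time_s = unlist(spikes)
    ),
    trials = tibble::tibble(trial_id = seq_len(n_trials), mu_i = mu_i)
  )
}

#' Simulate a full population with known ground truth
#'
#' Draws time-cell peaks from the bounded power law, sets per-cell widths and
#' jitters from the configured laws, couples field locations to per-trial
#' behavioural event offsets, and adds uniform-firing distractor units and
#' fast-firing interneuron-like units. Everything is reproducible from
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return an object of class `spike_sim`: a list with
#' \describe{
#'   \item{spikes}{tibble `unit_id`, `trial_id`, `spike_time_s`}
#'   \item{events}{tibble `unit_id`, `trial_id`, `event_offset_s`}
#'   \item{truth_cells}{tibble `unit_id`, `kind`, `M`, `sigma_w`, `sigma_t`,
#'     `a1` (parameters of generated time cells; NA for distractors)}
#'   \item{truth_trials}{tibble `unit_id`, `trial_id`, `mu_i`, `event_offset_s`}
#'   \item{delay}{delay length in seconds}
#'   \item{config}{the configuration used}
#' }
#' @export
simulate_population <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)

  nt <- config$n_time_cells
  M <- sort(rbpowerlaw(nt, config$alpha, config$peak_min, config$peak_max))
  sw <- sigma_w_law(M, config)
  st <- sigma_t_law(M, config)
  gain <- config$event_coupling *
    pmax(0, 1 - M / config$event_coupling_zero_at)

  unit_ids <- c(
    sprintf("tc%03d", seq_len(nt)),
    sprintf("dc%03d", seq_len(config$n_distractor_cells)),
    sprintf("in%03d", seq_len(config$n_interneurons))
  )
  kinds <- rep(c("time_cell", "distractor", "interneuron"),
               c(nt, config$n_distractor_cells, config$n_interneurons))

  spikes_l <- vector("list", length(unit_ids))
  trials_l <- vector("list", length(unit_ids))
  for (u in seq_along(unit_ids)) {
    offs <- stats::rnorm(config$trials_per_cell, 0, config$event_sd)
    kind <- kinds[u]
    if (kind == "time_cell") {
      cell <- simulate_cell(
        M = M[u], sigma_w = sw[u], sigma_t = st[u], a1 = config$a1,
        spikes_per_trial_mean = config$spikes_per_trial_mean,
        n_trials = config$trials_per_cell, delay = config$delay,
        field_shape = config$field_shape, mu_shift = gain[u] * offs
      )
    } else {
      mean_count <- if (kind == "distractor") {
        config$spikes_per_trial_mean
      } else {
        stats::runif(1, 6, 10) * config$delay  # interneurons: 6-10 Hz
      }
      cell <- simulate_cell(
        M = config$delay / 2, sigma_w = 1, sigma_t = 0, a1 = 0,
        spikes_per_trial_mean = mean_count,
        n_trials = config$trials_per_cell, delay = config$delay
      )
      cell$trials$mu_i <- NA_real_
    }
    spikes_l[[u]] <- dplyr::mutate(cell$spikes, unit_id = unit_ids[u],
                                   .before = 1)
    trials_l[[u]] <- dplyr::mutate(cell$trials, unit_id = unit_ids[u],
                                   event_offset_s = offs, .before = 1)
  }

  truth_trials <- dplyr::bind_rows(trials_l)
  structure(list(
    spikes = dplyr::bind_rows(spikes_l),
    events = dplyr::select(truth_trials, "unit_id", "trial_id",
                           "event_offset_s"),
    truth_cells = tibble::tibble(
      unit_id = unit_ids, kind = kinds,
      M = c(M, rep(NA_real_, length(unit_ids) - nt)),
      sigma_w = c(sw, rep(NA_real_, length(unit_ids) - nt)),
      sigma_t = c(st, rep(NA_real_, length(unit_ids) - nt)),
      a1 = c(rep(config$a1, nt), rep(NA_real_, length(unit_ids) - nt))
    ),
    truth_trials = truth_trials,
    delay = config$delay,
    config = config
  ), class = "spike_sim")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
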