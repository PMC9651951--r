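#' Read and write spike-train datasets
#'
#' A dataset directory holds `spikes.csv` (`unit_id`, `trial_id`,
#' `spike_time_s`), an optional `events.csv` (`unit_id`, `trial_id`,
#' `event_offset_s`) and a `meta.yaml` sidecar carrying the delay length and
#' provenance. Ground-truth tables from the simulator (`truth_cells.csv`,
#' `truth_trials.csv`) are written alongside when available. Spike times are
#' formatted with six decimal places so rewritten files are byte-stable and
#' diffable.
#'
#' Validation on read enforces: required columns present, no missing or
#' non-finite spike times, and every spike inside `[0, delay]` (violations
#' are reported with the offending unit and trial). Duplicate
#' `(unit, trial, time)` rows are permitted: simultaneous spikes recorded on
#' different tetrode channels are not merged. A unit/trial pair listed in the
#' events file with no spikes is a legitimate empty trial.
#'
#' @param x a `spike_sim` from [simulate_population()] or a `spike_dataset`.
#' @param path directory to write to / read from.
#' @return `write_spike_dataset` returns `path` invisibly.
#'   `read_spike_dataset` returns a `spike_dataset`: list with `spikes`,
#'   `events` (or `NULL`), `delay`, `meta`.
#' @export
write_spike_dataset <- function(x, path) {
  stopifnot(inherits(x, c("spike_sim", "spike_dataset")))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  delay <- x$delay
  spikes <- validate_spikes(x$spikes, delay)

  fmt <- function(v) sprintf("%.6f", v)
  sp <- dplyr::arrange(spikes, .data$unit_id, .data$trial_id,
                       .data$spike_time_s)
  sp$spike_time_s <- fmt(sp$spike_time_s)
  readr::write_csv(sp, file.path(path, "spikes.csv"))

  if (!is.null(x$events) && nrow(x$events) > 0) {
    ev <- dplyr::arrange(x$events, .data$unit_id, .data$trial_id)
    ev$event_offset_s <- fmt(ev$event_offset_s)
    readr::write_csv(ev, file.path(path, "events.csv"))
  }
  if (!is.null(x$truth_cells)) {
    readr::write_csv(x$truth_cells, file.path(path, "truth_cells.csv"))
    readr::write_csv(x$truth_trials, file.path(path, "truth_trials.csv"))
  }
  meta <- list(delay_l = delay,
               seed = if (!is.null(x$config)) x$config$seed else NA,
               writer = "timefields")
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

#' @rdname write_spike_dataset
#' @export
read_spike_dataset <- function(path) {
  spk_file <- file.path(path, "spikes.csv")
  meta_file <- file.path(path, "meta.yaml")
  if (!file.exists(spk_file)) stop("no spikes.csv in ", path, call. = FALSE)
  if (!file.exists(meta_file)) stop("no meta.yaml in ", path, call. = FALSE)
  meta <- yaml::read_yaml(meta_file)
  if (is.null(meta$delay_l)) stop("meta.yaml lacks delay_l", call. = FALSE)
  delay <- as.numeric(meta$delay_l)

  spikes <- readr::read_csv(
    spk_file, show_col_types = FALSE,
    col_types = readr::cols(
      unit_id = readr::col_character(),
      trial_id = readr::col_integer(),
      spike_time_s = readr::col_double(),
      .default = readr::col_guess()
    )
  )
  missing_cols <- setdiff(c("unit_id", "trial_id", "spike_time_s"),
                          names(spikes))
  if (length(missing_cols) > 0) {
    stop("spikes.csv missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  spikes <- validate_spikes(spikes, delay)
  spikes <- dplyr::arrange(spikes, .data$unit_id, .data$trial_id,
                           .data$spike_time_s)

  ev_file <- file.path(path, "events.csv")
  events <- NULL
  if (file.exists(ev_file)) {
    events <- readr::read_csv(
      ev_file, show_col_types = FALSE,
      col_types = readr::cols(
        unit_id = readr::col_character(),
        trial_id = readr::col_integer(),
        event_offset_s = readr::col_double()
      )
    )
    missing_ev <- setdiff(c("unit_id", "trial_id", "event_offset_s"),
                          names(events))
    if (length(missing_ev) > 0) {
      stop("events.csv missing columns: ",
           paste(missing_ev, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(spikes = spikes, events = events, delay = delay,
                 meta = meta),
            class = "spike_dataset")
}

validate_spikes <- function(spikes, delay) {
  spikes <- tibble::as_tibble(spikes)
  bad <- !is.finite(spikes$spike_time_s)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("non-finite spike time for unit %s trial %s",
                 spikes$unit_id[i], spikes$trial_id[i]), call. = FALSE)
  }
  out <- spikes$spike_time_s < 0 | spikes$spike_time_s > delay
  if (any(out)) {
    i <- which(out)[1]
    stop(sprintf(
      "spike time %.6f outside [0, %g] for unit %s trial %s",
      spikes$spike_time_s[i], delay, spikes$unit_id[i], spikes$trial_id[i]
    ), call. = FALSE)
  }
  spikes
}

#' Per-unit summary of a spike table
#'
#' @param spikes tibble with `unit_id`, `trial_id`, `spike_time_s`.
#' @param delay delay length in seconds.
#' @return tibble with one row per unit: `n_trials` (trials with at least one
#'   spike), `n_spikes`, and `mean_rate` in Hz
#'   (`n_spikes / (n_trials * delay)`).
#' @export
unit_summary <- function(spikes, delay) {
  spikes |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      n_trials = dplyr::n_distinct(.data$trial_id),
      n_spikes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_rate = .data$n_spikes / (.data$n_trials * delay))
}
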