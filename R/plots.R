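#' Sorted normalised-rate heatmap
#'
#' The classic time-cell population figure: per-unit trial-averaged firing
#' rate, peak-normalised, with units sorted by fitted peak time, on a linear
#' or logarithmic time axis. Under logarithmic compression the ridge is
#' curved on a linear axis and straightens on a log axis.
#'
#' @param spikes tibble with `unit_id`, `trial_id`, `spike_time_s`.
#' @param delay delay length (seconds).
#' @param peaks tibble with `unit_id` and a peak column `M` used for sorting
#'   (units absent from it are dropped).
#' @param bin_width histogram bin width in seconds.
#' @param log_time plot against log time.
#' @return a ggplot object.
#' @export
plot_population_heatmap <- function(spikes, delay, peaks, bin_width = 0.1,
                                    log_time = FALSE) {
  spikes <- spikes[spikes$unit_id %in% peaks$unit_id, ]
  ord <- peaks$unit_id[order(peaks$M)]
  breaks <- seq(0, delay, by = bin_width)
  mids <- breaks[-1] - bin_width / 2
  rate <- spikes |>
    dplyr::mutate(bin = cut(.data$spike_time_s, breaks,
                            include.lowest = TRUE, labels = FALSE)) |>
    dplyr::count(.data$unit_id, .data$bin) |>
    tidyr::complete(unit_id = ord, bin = seq_along(mids),
                    fill = list(n = 0)) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::mutate(norm_rate = .data$n / max(max(.data$n), 1)) |>
    dplyr::ungroup() |>
    dplyr::mutate(time = mids[.data$bin],
                  unit = factor(.data$unit_id, levels = ord))
  p <- ggplot2::ggplot(rate, ggplot2::aes(.data$time, .data$unit,
                                          fill = .data$norm_rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "norm. rate") +
    ggplot2::labs(x = "time in delay (s)", y = "unit (sorted by peak)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Diagnostic plots for a fitted hierarchical model
#'
#' `type = "alpha"` draws the posterior of the compression exponent;
#' `"width"` the per-cell width against peak with the fitted line;
#' `"cdf"` the peak CDF on a log-time axis (straight under exponent 1).
#'
#' @param object an `hbm_fit`.
#' @param type which diagnostic to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hbm_fit <- function(object, type = c("alpha", "width", "cdf"), ...) {
  type <- match.arg(type)
  if (type == "alpha") {
    if (!"alpha" %in% names(object$population)) {
      stop("this variant has no alpha parameter", call. = FALSE)
    }
    d <- tibble::tibble(alpha = object$population$alpha)
    return(
      ggplot2::ggplot(d, ggplot2::aes(.data$alpha)) +
        ggplot2::geom_density(fill = "grey80") +
        ggplot2::geom_vline(xintercept = c(0, 1), linetype = c(1, 2)) +
        ggplot2::labs(x = "compression exponent", y = "posterior density") +
        ggplot2::theme_minimal()
    )
  }
  if (type == "width") {
    d <- object$cells
    return(
      ggplot2::ggplot(d, ggplot2::aes(.data$M, .data$field_width)) +
        ggplot2::geom_point() +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
        ggplot2::labs(x = "peak time M (s)",
                      y = "within-trial width (s)") +
        ggplot2::theme_minimal()
    )
  }
  d <- tibble::tibble(M = sort(object$cells$M))
  d$cdf <- seq_len(nrow(d)) / nrow(d)
  ggplot2::ggplot(d, ggplot2::aes(.data$M, .data$cdf)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "peak time M (s, log axis)", y = "CDF") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
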