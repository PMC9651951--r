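#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hierarchical time-field fit
#'
#' @param x an `hbm_fit`.
#' @param level `"cells"` (per-cell posterior means and sds, default),
#'   `"trials"` (per-trial field locations) or `"population"` (posterior
#'   draws of the population parameters).
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.hbm_fit <- function(x, level = c("cells", "trials", "population"), ...) {
  level <- match.arg(level)
  switch(level,
         cells = x$cells,
         trials = x$trials,
         population = x$population)
}

#' @rdname tidy.hbm_fit
#' @return `glance()`: a one-row tibble with the population posterior
#'   summary, WAIC and worst split-Rhat.
#' @exportS3Method generics::glance
glance.hbm_fit <- function(x, ...) {
  pop_pars <- setdiff(names(x$population), c(".chain", ".draw"))
  out <- tibble::tibble(
    variant = x$variant,
    n_cells = nrow(x$cells),
    n_trials = nrow(x$trials),
    waic = x$waic$waic,
    p_waic = x$waic$p_waic,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    converged = all(x$diagnostics$converged)
  )
  for (p in pop_pars) {
    d <- x$population[[p]]
    out[[paste0(p, "_mean")]] <- mean(d)
    out[[paste0(p, "_ci_lower")]] <- stats::quantile(d, 0.025, names = FALSE)
    out[[paste0(p, "_ci_upper")]] <- stats::quantile(d, 0.975, names = FALSE)
  }
  out
}

#' @rdname tidy.hbm_fit
#' @exportS3Method generics::tidy
tidy.waic <- function(x, ...) {
  tibble::tibble(waic = x$waic, lppd = x$lppd, p_waic = x$p_waic, se = x$se)
}

#' @exportS3Method generics::tidy
tidy.regression_report <- function(x, ...) x$terms

#' @exportS3Method generics::glance
glance.regression_report <- function(x, ...) {
  tibble::tibble(adj_r_squared = x$adj_r_squared,
                 best_model = x$best_model, bf_m = x$bf_m)
}

#' @exportS3Method generics::tidy
tidy.bounds_search <- function(x, ...) x$grid

#' @exportS3Method generics::glance
glance.bounds_search <- function(x, ...) {
  tibble::tibble(chosen_lower = x$chosen_lower, chosen_upper = x$chosen_upper,
                 n_excluded = x$n_excluded,
                 best_ks_p = max(x$grid$ks_p, na.rm = TRUE))
}
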