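#' Quadratic regression with BIC-approximate Bayes factors
#'
#' Ordinary least squares of `y` on intercept, linear and quadratic terms of
#' `x`, plus a Bayesian comparison of the four nested candidate models (null,
#' linear, quadratic, linear + quadratic) via the BIC approximation
#' `BF_i0 = exp((BIC_0 - BIC_i) / 2)`. `BF_M` is the posterior odds of the
#' winning model against the rest under equal prior model probabilities.
#'
#' @param y,x equal-length finite numeric vectors, `n >= 4`.
#' @param include_bayes compute the Bayes-factor table.
#' @return list of class `regression_report`: `terms` (tibble with estimate,
#'   std.error, p.value per term), `adj_r_squared`, `bayes` (tibble of BF
#'   versus null per candidate model), `best_model`, `bf_m`.
#' @export
regress_quadratic <- function(y, x, include_bayes = TRUE) {
  stopifnot(length(y) == length(x), all(is.finite(y)), all(is.finite(x)),
            length(y) >= 4)
  if (stats::sd(x) == 0) stop("`x` is constant: collinear design", call. = FALSE)
  d <- data.frame(y = y, x = x, x2 = x^2)
  fit <- stats::lm(y ~ x + x2, data = d)
  sm <- summary(fit)
  co <- stats::coef(sm)
  terms <- tibble::tibble(
    term = c("intercept", "linear", "quadratic"),
    estimate = unname(co[, 1]), std.error = unname(co[, 2]),
    p.value = unname(co[, 4])
  )
  out <- list(terms = terms, adj_r_squared = sm$adj.r.squared,
              bayes = NULL, best_model = NA_character_, bf_m = NA_real_)
  if (include_bayes) {
    models <- list(
      null = stats::lm(y ~ 1, data = d),
      linear = stats::lm(y ~ x, data = d),
      quadratic = stats::lm(y ~ x2, data = d),
      linear_quadratic = fit
    )
    bic <- vapply(models, stats::BIC, 0)
    bic <- stats::setNames(bic, names(models))
    bf0 <- exp((bic[["null"]] - bic) / 2)
    post <- bf0 / sum(bf0)
    bayes <- tibble::tibble(model = names(models), bic = bic,
                            bf_vs_null = bf0, post_prob = post)
    best <- bayes$model[which.max(bayes$post_prob)]
    p <- max(bayes$post_prob)
    m <- nrow(bayes)
    out$bayes <- bayes
    out$best_model <- best
    out$bf_m <- (p / (1 - p)) * (m - 1)  # equal prior odds
  }
  structure(out, class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("quadratic regression\n")
  print(x$terms)
  cat(sprintf("adjusted R^2 = %.3f\n", x$adj_r_squared))
  if (!is.null(x$bayes)) {
    cat(sprintf("best model by BIC-BF: %s (BF_M = %.2f)\n",
                x$best_model, x$bf_m))
  }
  invisible(x)
}

#' Sign-split chi-square test against a 50/50 split
#'
#' Goodness-of-fit chi-square (1 df) with Yates continuity correction:
#' \deqn{\chi^2 = 2 (|k - n/2| - 0.5)^2 / (n/2),}
#' clamped at zero when the count is within half a unit of an even split.
#' Used to test whether across-trial variability exceeds within-trial width
#' for more than half the population.
#'
#' @param n_greater count of cells on one side of the split.
#' @param n_total total count (`>= 1`).
#' @return tibble with `statistic`, `df`, `p.value`.
#' @export
sign_split_chi2 <- function(n_greater, n_total) {
  stopifnot(n_total >= 1, n_greater >= 0, n_greater <= n_total)
  half <- n_total / 2
  dev <- max(0, abs(n_greater - half) - 0.5)
  stat <- 2 * dev^2 / half
  tibble::tibble(statistic = stat, df = 1L,
                 p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Summarise the posterior of the compression exponent
#'
#' @param draws numeric vector of posterior draws (`>= 100`).
#' @param window interval whose posterior mass is reported (default
#'   `[0.9, 1.1]`, the neighbourhood of exact logarithmic compression).
#' @return tibble: `mean`, `sd`, `ci_lower`, `ci_upper` (equal-tailed 95%),
#'   `frac_in_window`, `sd_from_zero` (mean / sd).
#' @export
alpha_posterior_summary <- function(draws, window = c(0.9, 1.1)) {
  stopifnot(length(draws) >= 100)
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  s <- stats::sd(draws)
  tibble::tibble(
    mean = mean(draws), sd = s, ci_lower = q[1], ci_upper = q[2],
    frac_in_window = mean(draws >= window[1] & draws <= window[2]),
    sd_from_zero = if (s > 0) mean(draws) / s else Inf
  )
}

#' Linearity of the peak CDF on a log-time axis
#'
#' Under exact logarithmic compression (exponent 1) the empirical CDF of
#' peak times is a straight line against `log(peak)`. Regresses the ECDF
#' values `i/n` of the sorted peaks on `log(peak)` and reports the fit.
#'
#' @param peaks positive peak times.
#' @return tibble: `slope`, `intercept`, `r_squared`.
#' @export
cdf_log_linearity <- function(peaks) {
  stopifnot(all(peaks > 0), length(peaks) >= 3)
  x <- sort(peaks)
  cdf <- seq_along(x) / length(x)
  fit <- stats::lm(cdf ~ log(x))
  tibble::tibble(
    slope = stats::coef(fit)[[2]],
    intercept = stats::coef(fit)[[1]],
    r_squared = summary(fit)$r.squared
  )
}

#' Jeffreys-Zellner-Siow Bayes factor for a t-test
#'
#' Default-prior (Cauchy scale `sqrt(2)/2`) Bayes factor BF10 for a one- or
#' two-sample t-test, computed by numerical integration over the JZS prior
#' on effect size. For `alternative = "greater"` the BF is one-sided,
#' reweighting by the posterior probability of a positive effect
#' (approximated from the classical t posterior).
#'
#' @param x numeric sample (for one-sample: tested against mean 0).
#' @param y optional second sample (two-sample test of mean difference).
#' @param alternative `"two.sided"` or `"greater"`.
#' @param rscale Cauchy prior scale.
#' @return tibble: `bf10`, `t`, `df`, `n_eff`.
#' @export
bf_ttest <- function(x, y = NULL, alternative = c("two.sided", "greater"),
                     rscale = sqrt(2) / 2) {
  alternative <- match.arg(alternative)
  if (is.null(y)) {
    n <- length(x)
    stopifnot(n >= 2)
    t <- mean(x) / (stats::sd(x) / sqrt(n))
    df <- n - 1
    neff <- n
  } else {
    n1 <- length(x); n2 <- length(y)
    stopifnot(n1 >= 2, n2 >= 2)
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
                 (n1 + n2 - 2))
    t <- (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    neff <- n1 * n2 / (n1 + n2)
  }
  # marginal likelihood under H1: integrate over g with
  # g ~ InverseGamma(1/2, rscale^2/2) (Rouder et al. JZS form)
  h1_int <- stats::integrate(function(g) {
    (1 + neff * g)^(-1 / 2) *
      (1 + t^2 / ((1 + neff * g) * df))^(-(df + 1) / 2) *
      (rscale^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) *
      exp(-rscale^2 / (2 * g))
  }, 0, Inf, rel.tol = 1e-8)$value
  h0 <- (1 + t^2 / df)^(-(df + 1) / 2)
  bf10 <- h1_int / h0
  if (alternative == "greater") {
    post_pos <- stats::pt(t, df)  # classical approximation
    bf10 <- bf10 * post_pos / 0.5
  }
  tibble::tibble(bf10 = bf10, t = t, df = df, n_eff = neff)
}

#' Early/late split analysis of compression
#'
#' Splits cells at a peak-time threshold (default 2 s, where behavioural
#' variability settles) and tests, within each group, whether peaks are
#' uniform (one-sample KS against the uniform over the group's observed peak
#' range) and whether width still grows with peak (linear regression with
#' BIC Bayes factor). Across groups, peaks are min-max normalised to `[0, 1]`
#' and compared by a two-sample KS test.
#'
#' @param cells tibble with per-cell posterior means `M` and a width column.
#' @param width_col name of the width column (default `"sigma_w"`).
#' @param threshold split point in seconds.
#' @param min_group groups smaller than this get their tests skipped with a
#'   warning.
#' @return list of class `early_late_report`: `groups` (tibble with per-group
#'   size, KS-vs-uniform D and p, width-regression slope and BF), `two_sample`
#'   (tibble with D and p for the normalised-peak comparison), `threshold`.
#' @export
early_late_analysis <- function(cells, width_col = "sigma_w", threshold = 2,
                                min_group = 5) {
  stopifnot(all(c("M", width_col) %in% names(cells)))
  grp <- ifelse(cells$M < threshold, "early", "late")
  out_groups <- list()
  norm_peaks <- list()
  for (g in c("early", "late")) {
    idx <- grp == g
    n <- sum(idx)
    if (n < min_group) {
      warning(sprintf("%s group has %d cells; tests skipped", g, n),
              call. = FALSE)
      out_groups[[g]] <- tibble::tibble(
        group = g, n = n, ks_d = NA_real_, ks_p = NA_real_,
        width_slope = NA_real_, width_bf = NA_real_)
      next
    }
    M <- cells$M[idx]
    w <- cells[[width_col]][idx]
    ks <- suppressWarnings(
      stats::ks.test(M, "punif", min(M), max(M)))
    wr <- regress_quadratic(w, M)
    lin_bf <- wr$bayes$bf_vs_null[wr$bayes$model == "linear"]
    out_groups[[g]] <- tibble::tibble(
      group = g, n = n, ks_d = unname(ks$statistic), ks_p = ks$p.value,
      width_slope = wr$terms$estimate[wr$terms$term == "linear"],
      width_bf = lin_bf)
    norm_peaks[[g]] <- (M - min(M)) / (max(M) - min(M))
  }
  two_sample <- if (length(norm_peaks) == 2) {
    ks2 <- suppressWarnings(
      stats::ks.test(norm_peaks$early, norm_peaks$late))
    tibble::tibble(ks_d = unname(ks2$statistic), ks_p = ks2$p.value)
  } else {
    tibble::tibble(ks_d = NA_real_, ks_p = NA_real_)
  }
  structure(list(groups = dplyr::bind_rows(out_groups),
                 two_sample = two_sample, threshold = threshold),
            class = "early_late_report")
}

#' @export
print.early_late_report <- function(x, ...) {
  cat(sprintf("early/late split at %g s\n", x$threshold))
  print(x$groups)
  cat("normalised two-sample KS:\n")
  print(x$two_sample)
  invisible(x)
}

#' Correlation of trial-level field locations with behavioural event timing
#'
#' For each cell, the Pearson correlation between the per-trial field
#' location (posterior mean `mu_i`) and the per-trial behavioural event
#' offset. Reports a one-sided JZS Bayes factor that the mean correlation
#' exceeds zero, and an early-versus-late one-sided comparison (early
#' cells expected to track event timing more strongly).
#'
#' @param trials tibble with `unit_id`, `trial_id`, `mu_i`.
#' @param events tibble with `unit_id`, `trial_id`, `event_offset_s`.
#' @param cells tibble with `unit_id`, `M` (per-cell posterior mean peaks).
#' @param threshold early/late split in seconds.
#' @param min_trials cells with fewer event trials are excluded with a
#'   warning.
#' @return list of class `event_correlation_report`: `per_cell` (tibble
#'   `unit_id`, `M`, `r`, `n`), `bf_positive` (one-sample, one-sided),
#'   `bf_early_gt_late` (two-sample, one-sided; `NA` if a group is too
#'   small), `n_excluded`.
#' @export
event_correlation_analysis <- function(trials, events, cells, threshold = 2,
                                       min_trials = 5) {
  d <- dplyr::inner_join(trials, events, by = c("unit_id", "trial_id")) |>
    dplyr::inner_join(dplyr::select(cells, "unit_id", "M"), by = "unit_id")
  per_cell <- d |>
    dplyr::group_by(.data$unit_id, .data$M) |>
    dplyr::summarise(
      n = dplyr::n(),
      const = stats::sd(.data$event_offset_s) == 0 |
        stats::sd(.data$mu_i) == 0,
      r = if (dplyr::n() >= min_trials &&
              stats::sd(.data$event_offset_s) > 0 &&
              stats::sd(.data$mu_i) > 0) {
        stats::cor(.data$mu_i, .data$event_offset_s)
      } else NA_real_,
      .groups = "drop"
    )
  n_excl <- sum(is.na(per_cell$r))
  if (n_excl > 0) {
    warning(sprintf(
      "%d cells excluded (fewer than %d event trials or constant values)",
      n_excl, min_trials), call. = FALSE)
  }
  ok <- per_cell[!is.na(per_cell$r), ]
  bf_pos <- if (nrow(ok) >= 2) bf_ttest(ok$r, alternative = "greater")
            else NULL
  early <- ok$r[ok$M < threshold]
  late <- ok$r[ok$M >= threshold]
  bf_el <- if (length(early) >= 2 && length(late) >= 2) {
    bf_ttest(early, late, alternative = "greater")
  } else NULL
  structure(list(
    per_cell = dplyr::select(ok, "unit_id", "M", "r", "n"),
    bf_positive = bf_pos, bf_early_gt_late = bf_el,
    n_excluded = n_excl, threshold = threshold
  ), class = "event_correlation_report")
}

#' @export
print.event_correlation_report <- function(x, ...) {
  cat(sprintf("event-timing correlations for %d cells (%d excluded)\n",
              nrow(x$per_cell), x$n_excluded))
  cat(sprintf("mean r = %.3f\n", mean(x$per_cell$r)))
  if (!is.null(x$bf_positive)) {
    cat(sprintf("BF10 (mean r > 0) = %.2f\n", x$bf_positive$bf10))
  }
  if (!is.null(x$bf_early_gt_late)) {
    cat(sprintf("BF10 (early > late) = %.2f\n", x$bf_early_gt_late$bf10))
  }
  invisible(x)
}

#' Population report for a fitted hierarchical model
#'
#' Bundles the downstream statistics computed from posterior means: the
#' width-versus-peak and jitter-versus-peak quadratic regressions, the
#' sign-split chi-square (jitter exceeding width), the exponent posterior
#' summary, the CDF-log-linearity diagnostic, the early/late split, and
#' (when events are supplied) the event-timing correlation analysis.
#'
#' @param fit an `hbm_fit`.
#' @param events optional events tibble (`unit_id`, `trial_id`,
#'   `event_offset_s`).
#' @param threshold early/late split point (seconds).
#' @return list of class `population_report`.
#' @export
population_report <- function(fit, events = NULL, threshold = 2) {
  stopifnot(inherits(fit, "hbm_fit"))
  cells <- fit$cells
  width_reg <- regress_quadratic(cells$field_width, cells$M)
  jitter_reg <- regress_quadratic(cells$sigma_t, cells$M)
  n_gt <- sum(cells$sigma_t > cells$field_width)
  sign_split <- sign_split_chi2(n_gt, nrow(cells))
  alpha_sum <- if ("alpha" %in% names(fit$population)) {
    alpha_posterior_summary(fit$population$alpha)
  } else NULL
  early_late <- early_late_analysis(cells, width_col = "field_width",
                                    threshold = threshold)
  evt <- if (!is.null(events)) {
    event_correlation_analysis(fit$trials, events, cells, threshold)
  } else NULL
  structure(list(
    variant = fit$variant,
    width_regression = width_reg,
    jitter_regression = jitter_reg,
    sign_split = sign_split, n_jitter_gt_width = n_gt, n_cells = nrow(cells),
    alpha_summary = alpha_sum,
    cdf_linearity = cdf_log_linearity(cells$M),
    early_late = early_late,
    event_correlation = evt
  ), class = "population_report")
}

#' @export
print.population_report <- function(x, ...) {
  cat(sprintf("population report (%s variant, %d cells)\n", x$variant,
              x$n_cells))
  cat("\nwidth ~ peak:\n"); print(x$width_regression)
  cat("\njitter ~ peak:\n"); print(x$jitter_regression)
  cat(sprintf("\njitter > width for %d/%d cells: chi2(1) = %.1f, p = %.2g\n",
              x$n_jitter_gt_width, x$n_cells, x$sign_split$statistic,
              x$sign_split$p.value))
  if (!is.null(x$alpha_summary)) {
    a <- x$alpha_summary
    cat(sprintf(
      "\nexponent posterior: mean %.2f, 95%% CI [%.2f, %.2f], %.0f%% in [0.9, 1.1]\n",
      a$mean, a$ci_lower, a$ci_upper, 100 * a$frac_in_window))
  }
  cat(sprintf("CDF-vs-log-peak R^2 = %.3f\n", x$cdf_linearity$r_squared))
  invisible(x)
}
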