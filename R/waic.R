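#' Widely Applicable Information Criterion
#'
#' Computes WAIC on the deviance scale from a draws-by-points matrix of
#' pointwise log-likelihoods: `WAIC = -2 (lppd - p_waic)` with
#' `lppd = sum_j log mean_s exp(loglik[s, j])` and the variance-based penalty
#' `p_waic = sum_j var_s(loglik[s, j])`. Lower is better. The pointwise unit
#' here is the (cell, trial) log-likelihood, the exchangeable replication
#' unit of the hierarchical models.
#'
#' @param loglik numeric matrix, draws in rows, points in columns.
#' @return list of class `waic`: `waic`, `lppd`, `p_waic`, `elpd` (pointwise
#'   contributions tibble), `se` (standard error of WAIC from the pointwise
#'   spread).
#' @export
compute_waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2) stop("need at least 2 draws", call. = FALSE)
  if (!all(is.finite(loglik))) stop("non-finite log-likelihoods", call. = FALSE)
  S <- nrow(loglik)
  # log mean exp per column, stable
  mx <- apply(loglik, 2, max)
  lppd_j <- mx + log(colMeans(exp(sweep(loglik, 2, mx))))
  p_j <- apply(loglik, 2, stats::var)
  elpd_j <- lppd_j - p_j
  n <- ncol(loglik)
  structure(list(
    waic = -2 * sum(elpd_j),
    lppd = sum(lppd_j),
    p_waic = sum(p_j),
    elpd = tibble::tibble(point = seq_len(n), lppd = lppd_j, p_waic = p_j,
                          elpd = elpd_j),
    se = 2 * sqrt(n * stats::var(elpd_j))
  ), class = "waic")
}

#' @export
print.waic <- function(x, ...) {
  cat(sprintf("WAIC %.2f (SE %.2f); lppd %.2f, p_waic %.2f, %d points\n",
              x$waic, x$se, x$lppd, x$p_waic, nrow(x$elpd)))
  invisible(x)
}

#' Compare fitted models by WAIC
#'
#' @param ... named `hbm_fit` or `waic` objects.
#' @return tibble sorted by WAIC (best first) with pairwise differences from
#'   the best model and the standard error of each difference (computed from
#'   the paired pointwise contributions).
#' @export
compare_waic <- function(...) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ws <- lapply(fits, function(f) if (inherits(f, "hbm_fit")) f$waic else f)
  tbl <- tibble::tibble(
    model = names(ws),
    waic = unname(vapply(ws, `[[`, 0, "waic")),
    p_waic = unname(vapply(ws, `[[`, 0, "p_waic")),
    se = unname(vapply(ws, `[[`, 0, "se"))
  )
  tbl <- dplyr::arrange(tbl, .data$waic)
  best <- tbl$model[1]
  tbl$d_waic <- tbl$waic - tbl$waic[1]
  tbl$d_se <- unname(vapply(tbl$model, function(mn) {
    if (mn == best) return(0)
    a <- ws[[mn]]$elpd$elpd; b <- ws[[best]]$elpd$elpd
    if (length(a) != length(b)) return(NA_real_)
    2 * sqrt(length(a) * stats::var(a - b))
  }, 0))
  tbl
}
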