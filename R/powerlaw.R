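#' Bounded power-law distribution
#'
#' Density, distribution function, quantile function and random generation for
#' the bounded (truncated) power law with density proportional to
#' \eqn{\tau^{-\alpha}} on \eqn{[lower, upper]}. The normaliser is
#' \eqn{C = (upper^{1-\alpha} - lower^{1-\alpha})/(1-\alpha)} for
#' \eqn{\alpha \neq 1} and \eqn{C = \log(upper/lower)} at \eqn{\alpha = 1};
#' both branches are evaluated through `expm1()` so the density and CDF are
#' continuous through \eqn{\alpha = 1} to machine precision.
#'
#' At \eqn{\alpha = 0} the distribution reduces to the uniform on
#' \eqn{[lower, upper]}; \eqn{\alpha = 1} corresponds to peaks tiling the
#' logarithmic time axis (Weber-Fechner compression).
#'
#' @param x,q vector of quantiles (seconds).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param alpha compression exponent, `>= 0`.
#' @param lower,upper support bounds (seconds); `0 < lower < upper`.
#' @param log,log.p logical; return log density / log probability.
#' @return `dbpowerlaw` the density, `pbpowerlaw` the CDF, `qbpowerlaw`
#'   quantiles, `rbpowerlaw` random draws. Values outside the support have
#'   density 0 (`-Inf` on the log scale).
#' @examples
#' pbpowerlaw(2, alpha = 2, lower = 1, upper = 4)  # 2/3
#' qbpowerlaw(0.5, alpha = 1, lower = 1, upper = exp(2))  # e
#' @export
dbpowerlaw <- function(x, alpha, lower, upper, log = FALSE) {
  check_bpl_params(alpha, lower, upper)
  ld <- -alpha * base::log(x) - bpl_log_norm(alpha, lower, upper)
  ld[x < lower | x > upper] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname dbpowerlaw
#' @export
pbpowerlaw <- function(q, alpha, lower, upper, log.p = FALSE) {
  check_bpl_params(alpha, lower, upper)
  om <- 1 - alpha
  r_all <- base::log(upper / lower)
  q <- pmin(pmax(q, lower), upper)
  if (abs(om) < 1e-12) {
    p <- base::log(q / lower) / r_all
  } else {
    p <- expm1(om * base::log(q / lower)) / expm1(om * r_all)
  }
  p <- pmin(pmax(p, 0), 1)
  if (log.p) base::log(p) else p
}

#' @rdname dbpowerlaw
#' @export
qbpowerlaw <- function(p, alpha, lower, upper) {
  check_bpl_params(alpha, lower, upper)
  stopifnot(all(p >= 0 & p <= 1))
  om <- 1 - alpha
  if (abs(om) < 1e-12) {
    lower * (upper / lower)^p
  } else {
    lower * (1 + p * expm1(om * base::log(upper / lower)))^(1 / om)
  }
}

#' @rdname dbpowerlaw
#' @export
rbpowerlaw <- function(n, alpha, lower, upper) {
  qbpowerlaw(stats::runif(n), alpha, lower, upper)
}

# log C(alpha), stable through alpha = 1
bpl_log_norm <- function(alpha, lower, upper) {
  om <- 1 - alpha
  r <- base::log(upper / lower)
  if (abs(om) < 1e-12) return(base::log(r))
  om * base::log(lower) + base::log(expm1(om * r) / om)
}

check_bpl_params <- function(alpha, lower, upper) {
  if (!is.finite(alpha) || alpha < 0) {
    stop("`alpha` must be a finite non-negative number.", call. = FALSE)
  }
  if (lower <= 0) {
    stop("`lower` must be positive: the power law is undefined at 0.",
         call. = FALSE)
  }
  if (upper <= lower) stop("`upper` must exceed `lower`.", call. = FALSE)
  invisible(TRUE)
}

#' Logarithmically spaced time-field peak sequence
#'
#' Peak times of an idealised logarithmically compressed population: the n-th
#' cell peaks at \eqn{t_n = t_0 b^n}, so adjacent peaks keep a constant ratio
#' `base` and the spacing between neighbours grows as \eqn{(b-1) t_n}.
#'
#' @param t0 peak time of the earliest cell (seconds, `> 0`).
#' @param base logarithm base `b > 1` controlling the compression.
#' @param n_peaks number of peaks to return (`>= 1`).
#' @return numeric vector `t0 * base^(0:(n_peaks-1))`.
#' @examples
#' peak_sequence(t0 = 1, base = 2, n_peaks = 4)  # 1 2 4 8
#' @export
peak_sequence <- function(t0, base, n_peaks) {
  if (!is.finite(t0) || t0 <= 0) stop("`t0` must be positive.", call. = FALSE)
  if (!is.finite(base) || base <= 1) stop("`base` must exceed 1.", call. = FALSE)
  if (n_peaks < 1) stop("`n_peaks` must be at least 1.", call. = FALSE)
  t0 * base^(seq_len(n_peaks) - 1)
}
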