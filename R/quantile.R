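#' Sample quantile by the check-loss midpoint rule
#'
#' The tau-quantile of a sample is any value minimising the asymmetric
#' check loss `sum(rho_tau(x - q))`. When `n * tau` is an integer the
#' minimiser is the whole interval between the order statistics
#' `x_(n tau)` and `x_(n tau + 1)`; this function returns the midpoint of
#' that interval, and the unique minimising order statistic otherwise.
#' This one convention is used for every quantile in the package
#' (percentiles of speed populations, the fast-threshold calibration, and
#' the quantile group contrast), so estimates are mutually consistent.
#'
#' @param x Numeric vector (non-empty).
#' @param tau Quantile levels in (0, 1).
#' @return Numeric vector of quantiles, one per `tau`.
#' @export
check_quantile <- function(x, tau) {
  if (!length(x)) stop("empty sample", call. = FALSE)
  if (any(tau <= 0 | tau >= 1))
    stop("tau must lie strictly inside (0, 1)", call. = FALSE)
  xs <- sort(x)
  n <- length(xs)
  vapply(tau, function(t) {
    j <- n * t
    if (abs(j - round(j)) < 1e-9) {
      j <- as.integer(round(j))
      if (j >= n) return(xs[n])
      (xs[j] + xs[j + 1]) / 2
    } else {
      xs[ceiling(j)]
    }
  }, numeric(1))
}
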