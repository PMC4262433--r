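#' Fit exponential growth and derive the doubling time
#'
#' Ordinary least squares on `log(density) ~ time`: under exponential growth
#' with multiplicative noise the log-density is linear in time with slope
#' equal to the specific growth rate mu, and the population doubling time is
#' Td = ln(2)/mu. The fit is invariant to rescaling all densities.
#'
#' @param curve data frame with columns `time_h` and `density_cells_per_ml`
#'   (the growth schema), or two numeric vectors via `time_h`/`density`.
#' @param drop_stationary if `TRUE`, points after the density maximum are
#'   excluded before fitting (late stationary-phase samples flatten the
#'   log-linear relation); default uses all points.
#' @return object of class `doubling_time`: `mu` (per hour), `td` (hours),
#'   `sigma` (residual standard error of the log fit), `n` points used.
#' @examples
#' g <- data.frame(time_h = c(0, 12, 24), density_cells_per_ml = c(1, 2, 4) * 1e6)
#' fit_exponential_growth(g)$td
#' @export
fit_exponential_growth <- function(curve, drop_stationary = FALSE) {
  if (!all(c("time_h", "density_cells_per_ml") %in% names(curve)))
    stop("growth curve needs columns time_h, density_cells_per_ml")
  t <- curve$time_h
  d <- curve$density_cells_per_ml
  if (any(d <= 0)) stop("densities must be > 0")
  if (drop_stationary) {
    keep <- seq_len(which.max(d))
    t <- t[keep]; d <- d[keep]
  }
  if (length(t) < 3L) stop("need at least 3 points to fit growth")
  fit <- stats::lm(log(d) ~ t)
  mu <- unname(stats::coef(fit)[2])
  if (mu <= 0) stop("non-growing population: fitted growth rate <= 0")
  # residual SE computed directly: summary.lm() warns on noise-free fits
  sigma <- sqrt(sum(stats::residuals(fit)^2) / (length(t) - 2L))
  out <- list(mu = mu, td = log(2) / mu, sigma = sigma, n = length(t))
  class(out) <- "doubling_time"
  out
}

#' @export
print.doubling_time <- function(x, ...) {
  cat(sprintf("doubling time %.3g h (mu = %.4g /h, residual SE %.3g, n = %d)\n",
              x$td, x$mu, x$sigma, x$n))
  invisible(x)
}

#' Number of population doublings elapsed
#'
#' @param dt a [fit_exponential_growth()] result (or a doubling time in
#'   hours).
#' @param t time in hours.
#' @return t / Td, dimensionless.
#' @export
doublings_elapsed <- function(dt, t) {
  td <- if (inherits(dt, "doubling_time")) dt$td else dt
  if (td <= 0) stop("doubling time must be > 0")
  t / td
}
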