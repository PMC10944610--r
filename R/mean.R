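#' Estimate the cross-subject mean function
#'
#' Pools all observations and estimates the population mean curve on the
#' grid, used to center the data before covariance estimation ("subtracting
#' averages over all subjects"). Two estimators are available:
#' \describe{
#'   \item{\code{"pspline"} (default)}{a penalized cubic B-spline fit to the
#'     pooled scatter, second-order difference penalty, smoothing parameter by
#'     GCV over a log-spaced search.}
#'   \item{\code{"pointwise"}}{per-day cross-sectional means, with interior
#'     gaps filled by linear interpolation. Grid points outside the observed
#'     day range cannot be interpolated and raise an error.}
#' }
#'
#' @param ads an uncentered \code{"fpcr_data"} object.
#' @param grid a \code{"time_grid"} covering all observation times.
#' @param method \code{"pspline"} or \code{"pointwise"}.
#' @param knots number of interior knots for the P-spline fit.
#' @param lambda optional fixed smoothing parameter (skips the GCV search).
#' @return An object of class \code{"mean_function"}: list with \code{grid},
#'   \code{values}, \code{method} and \code{smoothing_lambda}.
#' @export
estimate_mean <- function(ads, grid = time_grid(),
                          method = c("pspline", "pointwise"),
                          knots = 35L, lambda = NULL) {
  stopifnot(inherits(ads, "fpcr_data"))
  if (isTRUE(ads$centered)) stop("dataset is already centered; mean not identifiable")
  method <- match.arg(method)
  grid <- as_time_grid(grid)
  x <- as.numeric(ads$obs$time)
  y <- ads$obs$value
  if (method == "pointwise") {
    mu_obs <- tapply(y, x, mean)
    tx <- as.numeric(names(mu_obs))
    outside <- grid$points < min(tx) | grid$points > max(tx)
    if (any(outside)) {
      stop(sprintf("pointwise mean: %d grid point(s) outside the observed day range have no neighbors to interpolate",
                   sum(outside)))
    }
    values <- stats::approx(tx, as.numeric(mu_obs), xout = grid$points)$y
    lam <- 0
  } else {
    fit <- pspline_1d(x, y, range = range(grid$points), knots = knots,
                      xout = grid$points, lambda = lambda)
    values <- fit$fitted
    lam <- fit$lambda
  }
  if (any(!is.finite(values))) stop("mean estimate is not finite on the grid")
  structure(list(grid = grid, values = values, method = method,
                 smoothing_lambda = lam),
            class = "mean_function")
}

#' @export
print.mean_function <- function(x, ...) {
  cat(sprintf("mean_function (%s): %d grid points, range [%.3g, %.3g], lambda %.3g\n",
              x$method, length(x$values), min(x$values), max(x$values),
              x$smoothing_lambda))
  invisible(x)
}
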