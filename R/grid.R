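#' Evaluation grid with trapezoid quadrature weights
#'
#' Defines the common grid on which mean, covariance, eigenfunctions and
#' coefficient function are represented. The default is the 91-day daily
#' window \code{-90, ..., 0}, with day 0 the outcome date. Integrals over the
#' window are approximated by the trapezoid rule, which is exact for
#' piecewise-linear integrands; on the default grid the weights are
#' \code{(0.5, 1, ..., 1, 0.5)} and sum to 90 (the window width).
#'
#' @param points strictly increasing numeric vector of grid times. The default
#'   \code{-90:0} indexes days relative to the outcome date.
#' @return An object of class \code{"time_grid"}: a list with \code{points}
#'   and trapezoid \code{weights}.
#' @examples
#' g <- time_grid()
#' sum(g$weights)  # 90, the window width
#' @export
time_grid <- function(points = -90:0) {
  points <- as.numeric(points)
  if (length(points) < 2L) stop("a time grid needs at least 2 points")
  if (any(!is.finite(points)) || any(diff(points) <= 0)) {
    stop("grid points must be finite and strictly increasing")
  }
  m <- length(points)
  h <- diff(points)
  weights <- c(h[1] / 2, (h[-1] + h[-(m - 1L)]) / 2, h[m - 1L] / 2)
  structure(list(points = points, weights = weights), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: %d points on [%g, %g], trapezoid weights (sum %g)\n",
              length(x$points), min(x$points), max(x$points), sum(x$weights)))
  invisible(x)
}

as_time_grid <- function(x) {
  if (inherits(x, "time_grid")) return(x)
  time_grid(x)
}

## quadrature inner product <f, g> = sum w * f * g on the grid
grid_inner <- function(grid, f, g = f) {
  sum(grid$weights * f * g)
}

## integral of f over the grid window
grid_integral <- function(grid, f) {
  sum(grid$weights * f)
}

## evaluate columns of a grid-sampled matrix at arbitrary times by linear
## interpolation; errors if any time falls outside the grid
grid_interp <- function(grid, values, at) {
  if (any(at < min(grid$points) - 1e-8) || any(at > max(grid$points) + 1e-8)) {
    stop("observation times fall outside the grid window")
  }
  values <- as.matrix(values)
  out <- vapply(seq_len(ncol(values)), function(j) {
    stats::approx(grid$points, values[, j], xout = at, rule = 2)$y
  }, numeric(length(at)))
  matrix(out, nrow = length(at))
}
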