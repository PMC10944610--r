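#' Estimate the smoothed covariance surface and measurement-error variance
#'
#' For sparse irregular data the covariance function G(s, t) of the latent
#' process is estimated from raw cross-products of centered observations
#' pooled across subjects. Off-diagonal products y_is * y_it (s != t) are
#' unbiased for G(s, t); same-day products are inflated by the
#' measurement-error variance and are excluded from the surface fit. The
#' cross-products are binned onto the grid (times are daily indices, so
#' binning is exact), and the binned means are smoothed by a tensor-product
#' penalized B-spline (second-order difference penalty, one smoothing
#' parameter shared by both margins, chosen by GCV over a log-spaced search).
#' The measurement-error variance is the average gap between the smoothed raw
#' diagonal and the fitted surface diagonal over the middle 60% of the window
#' (boundary days are excluded because spline fits are least stable there),
#' floored at zero.
#'
#' \code{method = "empirical"} is a bypass for dense complete data: it
#' returns the unsmoothed sample covariance of the n x m data matrix with
#' noise variance 0 (every subject must be observed at every grid point).
#'
#' @param ads a centered \code{"fpcr_data"} object.
#' @param grid a \code{"time_grid"}.
#' @param knots interior knots per margin for the tensor-product fit
#'   (default 35).
#' @param method \code{"pspline"} (default) or \code{"empirical"}.
#' @param lambda optional fixed smoothing parameter.
#' @return An object of class \code{"cov_model"}: list with \code{grid},
#'   \code{surface} (symmetric m x m matrix), \code{noise_variance},
#'   \code{knots}, \code{smoothing_lambda} and \code{method}.
#' @export
estimate_covariance <- function(ads, grid = time_grid(), knots = 35L,
                                method = c("pspline", "empirical"),
                                lambda = NULL) {
  stopifnot(inherits(ads, "fpcr_data"))
  if (!isTRUE(ads$centered)) stop("dataset must be centered before covariance estimation")
  method <- match.arg(method)
  grid <- as_time_grid(grid)
  pts <- grid$points
  m <- length(pts)

  if (method == "empirical") {
    Y <- dense_matrix(ads, pts)
    surface <- stats::cov(Y)
    surface <- (surface + t(surface)) / 2
    return(structure(list(grid = grid, surface = surface, noise_variance = 0,
                          knots = knots, smoothing_lambda = 0,
                          method = method),
                     class = "cov_model"))
  }

  if (knots < 4L) stop("configuration error: knots must be at least 4")
  idx <- match_grid(ads$obs$time, pts)
  SS <- matrix(0, m, m)
  NN <- matrix(0, m, m)
  split_idx <- split(seq_len(nrow(ads$obs)), ads$obs$subject_id)
  any_pair <- FALSE
  for (rows in split_idx) {
    k <- idx[rows]
    y <- ads$obs$value[rows]
    if (length(k) >= 2L) any_pair <- TRUE
    SS[k, k] <- SS[k, k] + outer(y, y)
    NN[k, k] <- NN[k, k] + 1
  }
  if (!any_pair) stop("covariance estimation needs at least one subject with >= 2 observations")

  Zbar <- matrix(0, m, m)
  pos <- NN > 0
  Zbar[pos] <- SS[pos] / NN[pos]
  Woff <- NN
  diag(Woff) <- 0
  fit <- pspline_2d(Zbar, Woff, pts, knots = knots, lambda = lambda)
  surface <- fit$surface

  ## noise variance from the diagonal deviation over the central subwindow
  dN <- diag(NN)
  dsm <- pspline_1d(pts[dN > 0], diag(Zbar)[dN > 0], w = dN[dN > 0],
                    range = range(pts), knots = knots, xout = pts)$fitted
  central <- seq(from = ceiling(m * 0.2), to = floor(m * 0.8))
  noise_variance <- max(0, mean(dsm[central] - diag(surface)[central]))

  structure(list(grid = grid, surface = surface,
                 noise_variance = noise_variance, knots = knots,
                 smoothing_lambda = fit$lambda, method = method),
            class = "cov_model")
}

## observation times must sit on the grid for binning; daily data do
match_grid <- function(times, pts) {
  idx <- match(round(as.numeric(times), 8), round(pts, 8))
  if (anyNA(idx)) {
    ## snap off-grid times to the nearest grid point
    idx <- vapply(as.numeric(times), function(t) which.min(abs(pts - t)), 1L)
  }
  idx
}

## n x m matrix of a dense complete dataset; errors when incomplete
dense_matrix <- function(ads, pts) {
  m <- length(pts)
  counts <- table(ads$obs$subject_id)
  if (any(counts != m)) {
    stop("empirical covariance requires every subject observed at every grid point")
  }
  idx <- match_grid(ads$obs$time, pts)
  Y <- matrix(NA_real_, length(ads$subjects), m,
              dimnames = list(ads$subjects, NULL))
  Y[cbind(match(ads$obs$subject_id, ads$subjects), idx)] <- ads$obs$value
  if (anyNA(Y)) stop("empirical covariance requires complete data on the grid")
  Y
}

#' @export
print.cov_model <- function(x, ...) {
  cat(sprintf("cov_model (%s): %d x %d surface, noise variance %.4g, lambda %.3g\n",
              x$method, nrow(x$surface), ncol(x$surface), x$noise_variance,
              x$smoothing_lambda))
  invisible(x)
}
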