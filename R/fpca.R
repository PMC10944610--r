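#' Sparse functional principal component analysis
#'
#' Fits the full sparse-fPCA pipeline to an analysis dataset: estimate the
#' cross-subject mean, center, smooth the covariance surface from pooled raw
#' cross-products, eigendecompose under the grid quadrature, truncate at the
#' requested proportion of variance explained, and estimate per-subject
#' scores. Individual smooth trajectories with pointwise confidence bands are
#' available through [trajectories()] / [fitted()].
#'
#' @param data an \code{"fpcr_data"} object (see [analysis_dataset()]), or a
#'   long-format data.frame with columns \code{subject_id}, \code{time},
#'   \code{value} (then treated as already aligned and deduplicated).
#' @param grid a \code{"time_grid"}; default daily grid \code{-90:0}.
#' @param knots interior spline knots per margin for mean and covariance
#'   smoothing (default 35).
#' @param pve proportion-of-variance threshold for choosing the number of
#'   components (default 0.95).
#' @param npc optional fixed number of components, overriding \code{pve}.
#' @param mean_method mean estimator, \code{"pspline"} or \code{"pointwise"}.
#' @param cov_method covariance estimator, \code{"pspline"} or
#'   \code{"empirical"} (dense complete data only).
#' @param score_method \code{"ce"} (conditional expectation) or
#'   \code{"projection"} (dense complete data only).
#' @param lambda_mean,lambda_cov optional fixed smoothing parameters.
#' @return An object of class \code{"fpca_sparse"} with elements \code{mean},
#'   \code{cov}, \code{eigen} (full positive eigensystem), \code{basis}
#'   (truncated), \code{scores} (a \code{"score_set"}), \code{noise_variance},
#'   \code{pve_table}, \code{p}, \code{n} and the (centered) \code{data}.
#' @examples
#' study <- simulate_study(default_study_config(n = 40, seed = 7))
#' fit <- fpca_sparse(study$data, knots = 12)
#' fit
#' head(scree_table(fit))
#' @export
fpca_sparse <- function(data, grid = time_grid(), knots = 35L, pve = 0.95,
                        npc = NULL,
                        mean_method = c("pspline", "pointwise"),
                        cov_method = c("pspline", "empirical"),
                        score_method = c("ce", "projection"),
                        lambda_mean = NULL, lambda_cov = NULL) {
  mean_method <- match.arg(mean_method)
  cov_method <- match.arg(cov_method)
  score_method <- match.arg(score_method)
  grid <- as_time_grid(grid)
  ads <- as_fpcr_data(data)

  if (isTRUE(ads$centered)) {
    mu <- ads$mean_reference
  } else {
    mu <- estimate_mean(ads, grid, method = mean_method, knots = knots,
                        lambda = lambda_mean)
    ads <- center_ild(ads, mu)
  }
  cv <- estimate_covariance(ads, grid, knots = knots, method = cov_method,
                            lambda = lambda_cov)
  eig <- eigendecompose_cov(cv)
  p <- if (!is.null(npc)) min(npc, length(eig$values)) else select_ncomp(eig, pve)$p
  basis <- truncate_basis(eig, p)
  sc <- estimate_scores(ads, basis, noise_variance = cv$noise_variance,
                        method = score_method)
  structure(list(mean = mu, cov = cv, eigen = eig, basis = basis,
                 scores = sc, noise_variance = cv$noise_variance,
                 pve_table = scree_table(eig), p = p, pve = pve,
                 n = ads$n, knots = knots, data = ads,
                 call = match.call()),
            class = "fpca_sparse")
}

## accept fpcr_data, ild, or a bare long data.frame (with optional outcomes)
as_fpcr_data <- function(data, outcomes = NULL) {
  if (inherits(data, "fpcr_data")) return(data)
  ds <- if (inherits(data, "ild")) data else as_ild(data)
  if (is.null(outcomes)) {
    ## predictors only: fabricate an all-missing outcome column per subject
    outcomes <- data.frame(subject_id = ds$subjects, outcome = NA_real_,
                           stringsAsFactors = FALSE)
    out <- structure(list(obs = ds$obs, outcomes = outcomes,
                          subjects = ds$subjects, n = ds$n, centered = FALSE,
                          mean_reference = NULL,
                          exclusions = list(no_outcome = 0, no_predictor = 0,
                                            n_enrolled = ds$n),
                          report = ds$report),
                     class = "fpcr_data")
    return(out)
  }
  analysis_dataset(ds, outcomes)
}

#' Per-subject recovered trajectories
#'
#' @param object a fitted \code{"fpca_sparse"} model.
#' @param subjects subjects to reconstruct (default all).
#' @param level confidence level of the pointwise band.
#' @param centered if \code{TRUE}, return trajectories on the centered scale
#'   (mean not added back).
#' @return A long data.frame \code{(subject_id, time, fitted, se, lower,
#'   upper)} stacking all requested subjects.
#' @export
trajectories <- function(object, subjects = NULL, level = 0.95,
                         centered = FALSE) {
  stopifnot(inherits(object, "fpca_sparse"))
  if (is.null(subjects)) subjects <- object$scores$subjects
  mu <- if (centered) NULL else object$mean
  do.call(rbind, lapply(subjects, recover_trajectory, scores = object$scores,
                        basis = object$basis, mean_fn = mu, level = level))
}

#' @export
fitted.fpca_sparse <- function(object, ...) {
  tr <- trajectories(object)
  m <- length(object$basis$grid$points)
  matrix(tr$fitted, ncol = m, byrow = TRUE,
         dimnames = list(object$scores$subjects, object$basis$grid$points))
}

#' @export
print.fpca_sparse <- function(x, ...) {
  cat("Sparse functional PCA\n")
  cat(sprintf("  %d subjects, %d observations, grid [%g, %g] (%d points)\n",
              x$n, nrow(x$data$obs), min(x$basis$grid$points),
              max(x$basis$grid$points), length(x$basis$grid$points)))
  cat(sprintf("  %d component(s) at pve >= %.2f (achieved %.4f); noise variance %.4g\n",
              x$p, x$pve, x$basis$pve, x$noise_variance))
  cat("  eigenvalues:", paste(signif(x$basis$values, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fpca_sparse <- function(object, ...) {
  structure(list(fit = object, scree = object$pve_table,
                 score_sd = apply(object$scores$scores, 2, stats::sd)),
            class = "summary.fpca_sparse")
}

#' @export
print.summary.fpca_sparse <- function(x, ...) {
  print(x$fit)
  cat("\nScree table (leading components):\n")
  print(utils::head(x$scree, 8), row.names = FALSE)
  cat("\nScore standard deviations:",
      paste(signif(x$score_sd, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Plot method for sparse fPCA fits
#'
#' \code{which = "scree"} draws the scree plot (variance share per
#' component); \code{which = "trajectories"} overlays recovered trajectories
#' and 95% bands on the observed points for a few subjects;
#' \code{which = "eigenfunctions"} draws the retained eigenfunctions.
#'
#' @param x a fitted \code{"fpca_sparse"} model.
#' @param which one of \code{"scree"}, \code{"trajectories"},
#'   \code{"eigenfunctions"}.
#' @param subjects subjects for the trajectory panels (default: first 2).
#' @param ... passed to the underlying base-graphics calls.
#' @export
plot.fpca_sparse <- function(x, which = c("scree", "trajectories",
                                          "eigenfunctions"),
                             subjects = NULL, ...) {
  which <- match.arg(which)
  if (which == "scree") {
    st <- x$pve_table
    graphics::plot(st$component, st$proportion, type = "b", pch = 19,
                   xlab = "Component", ylab = "Proportion of variance",
                   main = "Scree plot", ...)
  } else if (which == "eigenfunctions") {
    graphics::matplot(x$basis$grid$points, x$basis$functions, type = "l",
                      lty = 1, xlab = "Day", ylab = "Eigenfunction",
                      main = "Functional principal components", ...)
    graphics::legend("topleft", legend = paste0("pc", seq_len(x$p)),
                     col = seq_len(x$p), lty = 1, bty = "n")
  } else {
    if (is.null(subjects)) subjects <- utils::head(x$scores$subjects, 2L)
    op <- graphics::par(mfrow = c(1, length(subjects)))
    on.exit(graphics::par(op))
    for (s in subjects) {
      tr <- recover_trajectory(s, x$scores, x$basis, x$mean)
      rows <- x$data$obs$subject_id == s
      mu_at <- grid_interp(x$mean$grid, x$mean$values, x$data$obs$time[rows])[, 1]
      yobs <- x$data$obs$value[rows] + if (isTRUE(x$data$centered)) mu_at else 0
      graphics::plot(tr$time, tr$fitted, type = "l",
                     ylim = range(c(yobs, tr$lower, tr$upper)),
                     xlab = "Day", ylab = "Value", main = paste("Subject", s), ...)
      graphics::lines(tr$time, tr$lower, lty = 2)
      graphics::lines(tr$time, tr$upper, lty = 2)
      graphics::points(x$data$obs$time[rows], yobs, pch = 19, cex = 0.5)
    }
  }
  invisible(x)
}
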