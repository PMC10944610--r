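#' Estimate subject-level principal component scores
#'
#' For sparse noisy data the best linear predictor of subject i's scores
#' given its observations (the conditional expectation under joint normality)
#' is \deqn{\hat\zeta_i = \Lambda \Phi_i' (\Phi_i \Lambda \Phi_i' +
#' \sigma_x^2 I)^{-1} y_i,} where \eqn{\Phi_i} holds the eigenfunctions
#' evaluated at the subject's observation times, \eqn{\Lambda} the eigenvalue
#' diagonal and \eqn{\sigma_x^2} the measurement-error variance. The
#' conditional score covariance \eqn{\Lambda - \Lambda \Phi_i'(\Phi_i \Lambda
#' \Phi_i' + \sigma_x^2 I)^{-1} \Phi_i \Lambda} is stored per subject and
#' feeds the trajectory confidence bands. \code{method = "projection"}
#' instead computes quadrature projections \eqn{\int y_i(t)\upsilon_j(t) dt}
#' and is exact for dense complete data.
#'
#' @param ads a centered \code{"fpcr_data"} object.
#' @param basis an \code{"fpca_basis"} (truncated eigensystem).
#' @param noise_variance measurement-error variance \eqn{\sigma_x^2};
#'   defaults to the value carried by the basis.
#' @param method \code{"ce"} (conditional expectation, default) or
#'   \code{"projection"} (dense complete data only).
#' @return An object of class \code{"score_set"}: list with \code{subjects},
#'   \code{scores} (n x p matrix) and \code{covariances} (per-subject p x p
#'   conditional covariances).
#' @export
estimate_scores <- function(ads, basis, noise_variance = basis$noise_variance,
                            method = c("ce", "projection")) {
  stopifnot(inherits(ads, "fpcr_data"), inherits(basis, "fpca_basis"))
  if (!isTRUE(ads$centered)) stop("scores are estimated from centered data")
  method <- match.arg(method)
  p <- basis$p
  lam <- basis$values
  grid <- basis$grid
  subjects <- ads$subjects
  scores <- matrix(0, length(subjects), p,
                   dimnames = list(subjects, paste0("pc", seq_len(p))))
  covs <- vector("list", length(subjects))
  names(covs) <- subjects
  rows_by_subj <- split(seq_len(nrow(ads$obs)), ads$obs$subject_id)

  if (method == "projection") {
    Y <- dense_matrix(ads, grid$points)
    Y <- Y[subjects, , drop = FALSE]
    PhiW <- basis$functions * grid$weights
    scores[, ] <- Y %*% PhiW
    ## score noise from measurement error propagated through the projection
    Vproj <- noise_variance * crossprod(PhiW)
    Vproj <- (Vproj + t(Vproj)) / 2
    for (i in seq_along(subjects)) covs[[i]] <- Vproj
  } else {
    Lam <- diag(lam, p)
    for (i in seq_along(subjects)) {
      rows <- rows_by_subj[[subjects[i]]]
      if (is.null(rows) || !length(rows)) {
        stop(sprintf("subject '%s' has no observations", subjects[i]))
      }
      Phi <- grid_interp(grid, basis$functions, ads$obs$time[rows])
      y <- ads$obs$value[rows]
      M <- Phi %*% Lam %*% t(Phi) + diag(noise_variance, length(y))
      sol <- tryCatch(solve(M, cbind(y, Phi %*% Lam)), error = function(e) NULL)
      if (is.null(sol) || !all(is.finite(sol))) {
        warning(sprintf("singular score system for subject '%s'; ridge-stabilized",
                        subjects[i]))
        M <- M + diag(1e-8 * mean(diag(M)), length(y))
        sol <- solve(M, cbind(y, Phi %*% Lam))
      }
      LP <- Lam %*% t(Phi)
      scores[i, ] <- LP %*% sol[, 1L]
      Ci <- Lam - LP %*% sol[, -1L, drop = FALSE]
      covs[[i]] <- (Ci + t(Ci)) / 2
    }
  }
  structure(list(subjects = subjects, scores = scores, covariances = covs,
                 method = method),
            class = "score_set")
}

#' Recover a subject's smooth trajectory with pointwise confidence band
#'
#' Reconstructs \eqn{\hat X_i(t) = \hat\mu(t) + \sum_j \hat\zeta_{ij}
#' \hat\upsilon_j(t)} on the grid. The pointwise standard error is
#' \eqn{\sqrt{\upsilon(t)' C_i \upsilon(t)}} with \eqn{C_i} the subject's
#' conditional score covariance, and the band is fitted \eqn{\pm} z * se.
#'
#' @param subject_id subject to reconstruct.
#' @param scores a \code{"score_set"}.
#' @param basis an \code{"fpca_basis"}.
#' @param mean_fn a \code{"mean_function"} (the centering reference); pass a
#'   zero mean to stay on the centered scale.
#' @param level confidence level for the band (default 0.95).
#' @return A data.frame with columns \code{subject_id}, \code{time},
#'   \code{fitted}, \code{se}, \code{lower}, \code{upper}.
#' @export
recover_trajectory <- function(subject_id, scores, basis, mean_fn,
                               level = 0.95) {
  stopifnot(inherits(scores, "score_set"), inherits(basis, "fpca_basis"))
  i <- match(as.character(subject_id), scores$subjects)
  if (is.na(i)) stop(sprintf("unknown subject '%s'", subject_id))
  mu <- if (inherits(mean_fn, "mean_function")) mean_fn$values else rep(0, length(basis$grid$points))
  fitted <- mu + as.numeric(basis$functions %*% scores$scores[i, ])
  Ci <- scores$covariances[[i]]
  se <- sqrt(pmax(rowSums((basis$functions %*% Ci) * basis$functions), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(subject_id = as.character(subject_id), time = basis$grid$points,
             fitted = fitted, se = se,
             lower = fitted - z * se, upper = fitted + z * se,
             stringsAsFactors = FALSE)
}
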