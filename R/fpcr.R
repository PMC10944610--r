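#' Functional principal component regression
#'
#' Fits the scalar-on-function model \eqn{Y_i = \alpha + \int X_i(t)\beta(t)
#' dt + \epsilon_i} by the two-stage recipe: sparse fPCA reduces each
#' subject's longitudinal predictor to a few principal component scores, and
#' the outcome is regressed on those scores by ordinary least squares,
#' \eqn{Y_i = \alpha + \sum_j \zeta_{ij}\beta_j + \epsilon_i}. The
#' time-varying coefficient function is reconstructed from the component
#' coefficients as \eqn{\hat\beta(t) = \sum_j \hat\beta_j
#' \hat\upsilon_j(t)} (see [coefficient_function()]).
#'
#' @param data an \code{"fpcr_data"} object holding predictors and outcomes,
#'   or a long-format predictor data.frame combined with \code{outcomes}.
#' @param outcomes optional per-subject outcome data.frame when \code{data}
#'   is a bare long table.
#' @param fpca an optional pre-fitted \code{"fpca_sparse"} model to reuse;
#'   when supplied the fPCA stage is skipped.
#' @inheritParams fpca_sparse
#' @param ... further arguments passed to [fpca_sparse()].
#' @return An object of class \code{"fpcr"}: list with \code{alpha},
#'   \code{betas}, \code{coef_covariance} ((p+1) x (p+1) OLS covariance),
#'   \code{residual_variance}, \code{r2}, \code{r2_adjusted},
#'   \code{f_pvalue}, \code{fitted_values}, \code{residuals}, \code{n},
#'   \code{p}, the stage-1 \code{fpca} fit and the underlying \code{lm} fit.
#' @examples
#' study <- simulate_study(default_study_config(n = 40, seed = 7))
#' fit <- fpcr(study$data, knots = 12)
#' summary(fit)
#' @export
fpcr <- function(data, outcomes = NULL, fpca = NULL, pve = 0.95,
                 knots = 35L, ...) {
  ads <- as_fpcr_data(data, outcomes)
  if (any(!is.finite(ads$outcomes$outcome))) {
    stop("every subject needs a finite outcome; apply analysis_dataset() first")
  }
  if (is.null(fpca)) {
    fpca <- fpca_sparse(ads, pve = pve, knots = knots, ...)
  }
  stopifnot(inherits(fpca, "fpca_sparse"))
  y <- ads$outcomes$outcome[match(fpca$scores$subjects, ads$outcomes$subject_id)]
  fit <- fit_scores_ols(fpca$scores$scores, y)
  structure(c(fit,
              list(fpca = fpca, subjects = fpca$scores$subjects,
                   outcomes = y, call = match.call())),
            class = "fpcr")
}

## OLS of y on [1, scores]; the regression stage shared by fpcr() and the CV
fit_scores_ols <- function(scores, y) {
  scores <- as.matrix(scores)
  n <- length(y)
  p <- ncol(scores)
  if (n <= p + 1L) {
    stop(sprintf("insufficient data: n = %d subjects cannot identify %d coefficients",
                 n, p + 1L))
  }
  df <- data.frame(y = y, scores)
  names(df) <- c("y", colnames(scores))
  lmfit <- stats::lm(y ~ ., data = df)
  if (any(is.na(stats::coef(lmfit)))) {
    bad <- names(stats::coef(lmfit))[is.na(stats::coef(lmfit))]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(lmfit)
  cf <- stats::coef(lmfit)
  fstat <- sm$fstatistic
  f_pvalue <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  r2 <- sm$r.squared
  r2_adj <- sm$adj.r.squared
  tss <- sum((y - mean(y))^2)
  if (tss <= 1e-12 * n * (1 + mean(y)^2)) {
    # constant outcome: no variance to explain
    r2 <- 0
    r2_adj <- 1 - (n - 1) / (n - p - 1)
    f_pvalue <- NA_real_
  }
  list(alpha = unname(cf[1L]), betas = unname(cf[-1L]),
       coef_covariance = stats::vcov(lmfit),
       residual_variance = sm$sigma^2,
       r2 = r2, r2_adjusted = r2_adj,
       f_pvalue = f_pvalue,
       fitted_values = stats::setNames(stats::fitted(lmfit), rownames(scores)),
       residuals = stats::setNames(stats::residuals(lmfit), rownames(scores)),
       n = n, p = p, lm = lmfit)
}

#' Reconstruct the time-varying coefficient function
#'
#' Maps the component coefficients back to the functional scale,
#' \eqn{\hat\beta(t) = \sum_j \hat\beta_j \hat\upsilon_j(t)}, with pointwise
#' standard errors \eqn{\sqrt{\upsilon(t)' \mathrm{Cov}(\hat\beta)
#' \upsilon(t)}} from the OLS covariance of the component coefficients. The
#' band conditions on the estimated eigenfunctions (the usual two-stage
#' convention; stage-1 uncertainty is not propagated).
#'
#' @param fit a fitted \code{"fpcr"} model.
#' @param basis optional \code{"fpca_basis"}; defaults to the fit's own.
#' @param level confidence level of the pointwise band (default 0.95).
#' @return An object of class \code{"coef_function"}: a data.frame with
#'   columns \code{time}, \code{value}, \code{se}, \code{lower},
#'   \code{upper}.
#' @export
coefficient_function <- function(fit, basis = NULL, level = 0.95) {
  stopifnot(inherits(fit, "fpcr"))
  if (is.null(basis)) basis <- fit$fpca$basis
  if (basis$p != fit$p) stop("basis and fit have different numbers of components")
  Phi <- basis$functions
  value <- as.numeric(Phi %*% fit$betas)
  Vb <- fit$coef_covariance[-1L, -1L, drop = FALSE]
  se <- sqrt(pmax(rowSums((Phi %*% Vb) * Phi), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(data.frame(time = basis$grid$points, value = value, se = se,
                       lower = value - z * se, upper = value + z * se),
            class = c("coef_function", "data.frame"))
}

#' @export
coef.fpcr <- function(object, ...) {
  stats::setNames(c(object$alpha, object$betas),
                  c("(Intercept)", paste0("pc", seq_len(object$p))))
}

#' @export
residuals.fpcr <- function(object, ...) object$residuals

#' Predict outcomes from an FPCR fit
#'
#' @param object a fitted \code{"fpcr"} model.
#' @param newdata optional new data: a \code{"score_set"}, a numeric score
#'   matrix with \code{p} columns, or a long-format predictor dataset (scored
#'   against the fitted basis after centering with the fitted mean). Default:
#'   training-set fitted values.
#' @param ... unused.
#' @return A named numeric vector of predicted outcomes.
#' @export
predict.fpcr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  scores <- score_input(object, newdata)
  if (ncol(scores) != object$p) {
    stop(sprintf("newdata has %d score column(s); the fit uses %d",
                 ncol(scores), object$p))
  }
  stats::setNames(as.numeric(object$alpha + scores %*% object$betas),
                  rownames(scores))
}

score_input <- function(object, newdata) {
  if (inherits(newdata, "score_set")) return(newdata$scores)
  if (is.matrix(newdata) || is.data.frame(newdata)) {
    nd <- as.matrix(newdata)
    if (is.numeric(nd)) return(nd)
  }
  ads <- as_fpcr_data(newdata)
  if (!isTRUE(ads$centered)) ads <- center_ild(ads, object$fpca$mean)
  estimate_scores(ads, object$fpca$basis,
                  noise_variance = object$fpca$noise_variance,
                  method = object$fpca$scores$method)$scores
}

#' @export
print.fpcr <- function(x, ...) {
  cat("Functional principal component regression\n")
  cat(sprintf("  n = %d subjects, p = %d component(s) (pve %.4f)\n",
              x$n, x$p, x$fpca$basis$pve))
  cat(sprintf("  alpha = %.4g; beta = %s\n", x$alpha,
              paste(signif(x$betas, 4), collapse = ", ")))
  cat(sprintf("  R2 = %.4f, adjusted R2 = %.4f, F-test p = %.3g\n",
              x$r2, x$r2_adjusted, x$f_pvalue))
  invisible(x)
}

#' @export
summary.fpcr <- function(object, ...) {
  se <- sqrt(diag(object$coef_covariance))
  est <- c(object$alpha, object$betas)
  tab <- cbind(Estimate = est, `Std. Error` = se, `t value` = est / se,
               `Pr(>|t|)` = 2 * stats::pt(abs(est / se),
                                          df = object$n - object$p - 1L,
                                          lower.tail = FALSE))
  rownames(tab) <- c("(Intercept)", paste0("pc", seq_len(object$p)))
  structure(list(fit = object, coefficients = tab), class = "summary.fpcr")
}

#' @export
print.summary.fpcr <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\nResidual variance: %.4g on %d degrees of freedom\n",
              x$fit$residual_variance, x$fit$n - x$fit$p - 1L))
  invisible(x)
}

#' Plot method for FPCR fits: the estimated coefficient function
#'
#' Draws \eqn{\hat\beta(t)} with its pointwise confidence band.
#'
#' @param x a fitted \code{"fpcr"} model.
#' @param level band level.
#' @param ... passed to \code{plot}.
#' @export
plot.fpcr <- function(x, level = 0.95, ...) {
  cf <- coefficient_function(x, level = level)
  graphics::plot(cf$time, cf$value, type = "n",
                 ylim = range(c(cf$lower, cf$upper)),
                 xlab = "Day", ylab = expression(hat(beta)(t)),
                 main = "Coefficient function", ...)
  graphics::polygon(c(cf$time, rev(cf$time)), c(cf$lower, rev(cf$upper)),
                    col = "grey85", border = NA)
  graphics::lines(cf$time, cf$value, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
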