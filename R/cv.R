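#' Leave-one-subject-out cross-validation for FPCR
#'
#' Each subject is predicted from a model trained on the remaining n - 1
#' subjects. Two refit scopes are available:
#' \describe{
#'   \item{\code{"full"} (default)}{mean, covariance, eigenbasis and
#'     regression are all re-estimated per fold (no information leaks from
#'     the held-out subject); the truncation order is fixed at the full-data
#'     choice so folds are comparable in dimension.}
#'   \item{\code{"scores_only"}}{the fPCA stage (basis and scores) is fixed
#'     from the full data and only the score regression is refit per fold;
#'     fast, and equivalent to plain leave-one-out OLS on the score matrix.}
#' }
#' Held-out subjects are scored against the fold's basis (after centering
#' with the fold's mean) and predicted from the fold's regression.
#'
#' @param data an \code{"fpcr_data"} object with outcomes.
#' @param refit \code{"full"} or \code{"scores_only"}.
#' @param pve,knots,npc,... settings forwarded to [fpca_sparse()].
#' @return An object of class \code{"fpcr_cv"}: list with \code{table}
#'   (subject_id, actual, predicted), \code{mse}, \code{spearman_rho},
#'   \code{folds} and \code{skipped} (folds abandoned on degenerate fits).
#' @examples
#' study <- simulate_study(default_study_config(n = 30, seed = 3))
#' cv <- loso_cv(study$data, refit = "scores_only", knots = 10)
#' cv$mse
#' @export
loso_cv <- function(data, refit = c("full", "scores_only"), pve = 0.95,
                    knots = 35L, npc = NULL, ...) {
  refit <- match.arg(refit)
  ads <- as_fpcr_data(data)
  if (ads$n < 3L) stop("leave-one-subject-out CV needs at least 3 subjects")
  full <- fpca_sparse(ads, pve = pve, knots = knots, npc = npc, ...)
  p <- full$p
  y_all <- ads$outcomes$outcome[match(full$scores$subjects,
                                      ads$outcomes$subject_id)]
  subjects <- full$scores$subjects
  pred <- rep(NA_real_, length(subjects))
  skipped <- character(0)

  if (refit == "scores_only") {
    S <- full$scores$scores
    for (i in seq_along(subjects)) {
      fit <- fit_scores_ols(S[-i, , drop = FALSE], y_all[-i])
      pred[i] <- fit$alpha + sum(S[i, ] * fit$betas)
    }
  } else {
    raw <- if (isTRUE(ads$centered)) uncenter_ild(ads) else ads
    for (i in seq_along(subjects)) {
      keep <- raw$obs$subject_id != subjects[i]
      train <- raw
      train$obs <- raw$obs[keep, , drop = FALSE]
      train$outcomes <- raw$outcomes[raw$outcomes$subject_id != subjects[i], ,
                                     drop = FALSE]
      train$subjects <- setdiff(raw$subjects, subjects[i])
      train$n <- length(train$subjects)
      fold <- tryCatch(
        fpca_sparse(train, knots = knots, npc = p, ...),
        error = function(e) {
          warning(sprintf("fold for subject '%s' skipped: %s",
                          subjects[i], conditionMessage(e)))
          NULL
        })
      if (is.null(fold)) { skipped <- c(skipped, subjects[i]); next }
      reg <- fit_scores_ols(fold$scores$scores,
                            train$outcomes$outcome[match(fold$scores$subjects,
                                                         train$outcomes$subject_id)])
      held <- raw
      held$obs <- raw$obs[!keep, , drop = FALSE]
      held$outcomes <- raw$outcomes[raw$outcomes$subject_id == subjects[i], ,
                                    drop = FALSE]
      held$subjects <- subjects[i]
      held$n <- 1L
      held <- center_ild(held, fold$mean)
      zi <- estimate_scores(held, fold$basis,
                            noise_variance = fold$noise_variance,
                            method = fold$scores$method)$scores
      pred[i] <- reg$alpha + sum(zi[1L, ] * reg$betas)
    }
  }

  ok <- !is.na(pred)
  tab <- data.frame(subject_id = subjects[ok], actual = y_all[ok],
                    predicted = pred[ok], stringsAsFactors = FALSE)
  structure(list(table = tab,
                 mse = mean((tab$actual - tab$predicted)^2),
                 spearman_rho = spearman_rho(tab$actual, tab$predicted),
                 folds = sum(ok), skipped = skipped, refit = refit, p = p),
            class = "fpcr_cv")
}

#' Spearman's rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive mean ranks).
#'
#' @param actual,predicted numeric vectors of equal length (>= 3).
#' @return The rank correlation in \[-1, 1\]; \code{NaN} with a warning when
#'   either vector has zero rank variance.
#' @export
spearman_rho <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("vectors must have equal length")
  if (length(actual) < 3L) stop("rank correlation needs at least 3 pairs")
  ra <- rank(actual, ties.method = "average")
  rp <- rank(predicted, ties.method = "average")
  if (stats::sd(ra) == 0 || stats::sd(rp) == 0) {
    warning("zero rank variance; Spearman correlation undefined")
    return(NaN)
  }
  stats::cor(ra, rp)
}

#' @export
print.fpcr_cv <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out CV (%s refit, p = %d)\n", x$refit, x$p))
  cat(sprintf("  folds = %d%s\n", x$folds,
              if (length(x$skipped)) sprintf(" (%d skipped)", length(x$skipped)) else ""))
  cat(sprintf("  MSE = %.4f, Spearman rho = %.4f\n", x$mse, x$spearman_rho))
  invisible(x)
}

#' Predicted-versus-actual plot for a cross-validation result
#'
#' Scatter of held-out predictions against observed outcomes with the
#' 45-degree equality line.
#'
#' @param x an \code{"fpcr_cv"} object.
#' @param ... passed to \code{plot}.
#' @export
plot.fpcr_cv <- function(x, ...) {
  rng <- range(c(x$table$actual, x$table$predicted))
  graphics::plot(x$table$actual, x$table$predicted, pch = 19,
                 xlim = rng, ylim = rng,
                 xlab = "Actual outcome", ylab = "Predicted outcome",
                 main = "Leave-one-subject-out predictions", ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}
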