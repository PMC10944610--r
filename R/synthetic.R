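#' Orthonormal function system on a grid
#'
#' Builds the first \code{p} members of a smooth family (polynomials or a
#' Fourier system) and Gram-Schmidt orthonormalizes them under the grid
#' quadrature, so they can serve as ground-truth eigenfunctions for
#' simulation. Deterministic; signs follow the package convention
#' (nonnegative integral, tie broken at the window end).
#'
#' @param grid a \code{"time_grid"}.
#' @param family \code{"polynomial"} or \code{"fourier"}.
#' @param p number of functions (at most the grid size).
#' @return An m x p matrix, quadrature-orthonormal columns.
#' @export
orthonormal_basis <- function(grid, family = c("polynomial", "fourier"), p) {
  family <- match.arg(family)
  grid <- as_time_grid(grid)
  t <- grid$points
  m <- length(t)
  if (p < 1L || p > m) stop(sprintf("p must be between 1 and %d", m))
  x <- (t - min(t)) / (max(t) - min(t))   # in [0, 1]
  raw <- switch(family,
    polynomial = vapply(seq_len(p), function(j) (2 * x - 1)^(j - 1L),
                        numeric(m)),
    fourier = vapply(seq_len(p), function(j) {
      if (j == 1L) rep(1, m)
      else if (j %% 2L == 0L) sin(2 * pi * (j %/% 2L) * x)
      else cos(2 * pi * (j %/% 2L) * x)
    }, numeric(m)))
  raw <- matrix(raw, nrow = m)
  out <- matrix(0, m, p)
  for (j in seq_len(p)) {
    v <- raw[, j]
    if (j > 1L) {
      proj <- vapply(seq_len(j - 1L), function(k) grid_inner(grid, v, out[, k]),
                     numeric(1))
      v <- v - out[, seq_len(j - 1L), drop = FALSE] %*% proj
    }
    nrm <- sqrt(grid_inner(grid, v))
    if (nrm < 1e-10) stop("family is rank-deficient on this grid; reduce p")
    v <- as.numeric(v) / nrm
    s <- grid_integral(grid, v)
    if (abs(s) <= 1e-10) s <- v[m]
    if (s < 0) v <- -v
    out[, j] <- v
  }
  out
}

#' Configuration for a synthetic longitudinal study
#'
#' Describes the generative model used by [simulate_study()]: per subject,
#' scores \eqn{\zeta_{ij} \sim N(0, \lambda_j)} weight orthonormal components
#' around a smooth mean, a random subset of days is observed, observations
#' carry Gaussian measurement noise, and the scalar outcome is
#' \eqn{Y_i = \alpha + \sum_j \zeta_{ij} \beta_j + N(0, \sigma^2)}.
#'
#' @param n number of subjects.
#' @param grid a \code{"time_grid"}; default daily \code{-90:0}.
#' @param mean_fun function of time giving the population mean curve.
#' @param eigenvalues positive nonincreasing score variances
#'   \eqn{\lambda_j}.
#' @param basis_family family passed to [orthonormal_basis()], or an
#'   m x p matrix of quadrature-orthonormal functions.
#' @param predictor_noise_sd measurement-error standard deviation
#'   \eqn{\sigma_x}.
#' @param sampling list: \code{type = "bernoulli"} with \code{prob} (each day
#'   observed independently) or \code{type = "fixed"} with \code{count}
#'   (uniform without replacement).
#' @param alpha true intercept.
#' @param beta_weights true component coefficients \eqn{\beta_j}; either this
#'   or \code{beta_fun} must be given.
#' @param beta_fun alternatively, a coefficient function of time to be
#'   quadrature-projected onto the basis (the off-basis remainder is
#'   reported).
#' @param outcome_noise_sd outcome error standard deviation \eqn{\sigma}.
#' @param seed integer seed; all randomness flows from it.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n, grid = time_grid(), mean_fun = function(t) 0 * t,
                       eigenvalues, basis_family = "polynomial",
                       predictor_noise_sd = 0,
                       sampling = list(type = "bernoulli", prob = 0.5),
                       alpha = 0, beta_weights = NULL, beta_fun = NULL,
                       outcome_noise_sd = 0, seed = 1L) {
  grid <- as_time_grid(grid)
  if (n < 1L) stop("n must be at least 1")
  ev <- as.numeric(eigenvalues)
  if (!length(ev) || any(ev <= 0) || is.unsorted(rev(ev))) {
    stop("eigenvalues must be positive and nonincreasing")
  }
  if (is.null(beta_weights) && is.null(beta_fun)) {
    stop("supply beta_weights or beta_fun")
  }
  if (identical(sampling$type, "bernoulli")) {
    if (!(sampling$prob > 0 && sampling$prob <= 1)) {
      stop("sampling probability must be in (0, 1]")
    }
  } else if (identical(sampling$type, "fixed")) {
    if (sampling$count < 1L || sampling$count > length(grid$points)) {
      stop("fixed sampling count must be between 1 and the grid size")
    }
  } else stop("sampling$type must be 'bernoulli' or 'fixed'")
  basis <- if (is.matrix(basis_family)) basis_family else
    orthonormal_basis(grid, basis_family, length(ev))
  if (nrow(basis) != length(grid$points) || ncol(basis) != length(ev)) {
    stop("basis must be grid-size x length(eigenvalues)")
  }
  structure(list(n = as.integer(n), grid = grid, mean_fun = mean_fun,
                 eigenvalues = ev, basis = basis,
                 predictor_noise_sd = predictor_noise_sd,
                 sampling = sampling, alpha = alpha,
                 beta_weights = beta_weights, beta_fun = beta_fun,
                 outcome_noise_sd = outcome_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## resolve beta: component weights plus any off-basis remainder of beta_fun
resolve_beta <- function(config) {
  if (!is.null(config$beta_weights)) {
    bw <- as.numeric(config$beta_weights)
    if (length(bw) != length(config$eigenvalues)) {
      stop("beta_weights must match the number of components")
    }
    return(list(weights = bw, off_basis_norm = 0))
  }
  bt <- config$beta_fun(config$grid$points)
  w <- vapply(seq_len(ncol(config$basis)), function(j) {
    grid_inner(config$grid, bt, config$basis[, j])
  }, numeric(1))
  resid <- bt - as.numeric(config$basis %*% w)
  list(weights = w, off_basis_norm = sqrt(grid_inner(config$grid, resid)))
}

#' Generate a synthetic longitudinal study with known ground truth
#'
#' Draws a full study from a [sim_config()]: sparse noisy long-format
#' observations of each subject's smooth trajectory plus one scalar outcome
#' per subject. Subjects are generated sequentially from a single seeded
#' stream with a fixed per-subject draw order, so the first k subjects are
#' identical across runs regardless of \code{n}. Subjects whose day draw
#' comes up empty are given their single most favourable day so every subject
#' has at least one observation.
#'
#' @param config a \code{"sim_config"}.
#' @return An object of class \code{"sim_study"}: list with \code{data} (an
#'   uncentered \code{"fpcr_data"} ready for [fpcr()]) and \code{truth}
#'   (mean values, basis, eigenvalues, the n x p score matrix, \code{beta_t}
#'   on the grid, \code{beta_weights}, \code{alpha}, \code{r2_theoretical},
#'   and the off-basis remainder norm when \code{beta_fun} was projected).
#' @examples
#' study <- simulate_study(default_study_config(n = 20, seed = 1))
#' study$data
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  t <- grid$points
  m <- length(t)
  p <- length(config$eigenvalues)
  mu <- config$mean_fun(t)
  beta <- resolve_beta(config)
  sdl <- sqrt(config$eigenvalues)

  set.seed(config$seed)
  obs_list <- vector("list", config$n)
  scores <- matrix(0, config$n, p)
  outcome <- numeric(config$n)
  ids <- sprintf("S%03d", seq_len(config$n))
  for (i in seq_len(config$n)) {
    zeta <- stats::rnorm(p) * sdl
    if (identical(config$sampling$type, "bernoulli")) {
      u <- stats::runif(m)
      days <- which(u < config$sampling$prob)
      if (!length(days)) days <- which.min(u)
    } else {
      days <- sort(sample.int(m, config$sampling$count))
    }
    traj <- mu + as.numeric(config$basis %*% zeta)
    noise <- if (config$predictor_noise_sd > 0) {
      stats::rnorm(length(days), 0, config$predictor_noise_sd)
    } else rep(0, length(days))
    eps <- if (config$outcome_noise_sd > 0) {
      stats::rnorm(1, 0, config$outcome_noise_sd)
    } else 0
    obs_list[[i]] <- data.frame(subject_id = ids[i], time = t[days],
                                value = traj[days] + noise,
                                label = "before-breakfast",
                                stringsAsFactors = FALSE)
    scores[i, ] <- zeta
    outcome[i] <- config$alpha + sum(zeta * beta$weights) + eps
  }
  obs <- do.call(rbind, obs_list)
  outcomes <- data.frame(subject_id = ids, outcome = outcome,
                         stringsAsFactors = FALSE)
  data <- analysis_dataset(new_ild(obs), outcomes)
  truth <- list(mean = mu, eigenfunctions = config$basis,
                eigenvalues = config$eigenvalues,
                scores = scores, beta_weights = beta$weights,
                beta_t = as.numeric(config$basis %*% beta$weights),
                beta_off_basis_norm = beta$off_basis_norm,
                alpha = config$alpha,
                r2_theoretical = theoretical_r2(config))
  structure(list(data = data, truth = truth, config = config),
            class = "sim_study")
}

#' Theoretical coefficient of determination of a simulation configuration
#'
#' Under the generative model the outcome variance splits into signal
#' \eqn{\sum_j \beta_j^2 \lambda_j} and noise \eqn{\sigma^2}, so the
#' population R-squared is \eqn{\sum\beta_j^2\lambda_j /
#' (\sum\beta_j^2\lambda_j + \sigma^2)}.
#'
#' @param config a \code{"sim_config"}.
#' @return The theoretical R-squared in \[0, 1\].
#' @export
theoretical_r2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  beta <- resolve_beta(config)
  signal <- sum(beta$weights^2 * config$eigenvalues)
  noise <- config$outcome_noise_sd^2
  if (signal == 0 && noise == 0) {
    stop("all-zero signal with zero outcome noise: R2 undefined")
  }
  signal / (signal + noise)
}

#' Default glucose-to-HbA1c style study preset
#'
#' A documented preset emulating a daily self-monitoring design: a 91-day
#' window (days -90..0), two dominant smooth components (orthonormalized
#' constant and linear trend) with score variances 400 and 50 (glucose
#' mg/dL scale, between-subject SDs of 20 and ~7), measurement noise SD 5
#' mg/dL, each day observed independently with probability 0.5 (median ~46
#' of 91 days observed), intercept 7.5 on the HbA1c (%) scale, component
#' coefficients (0.035, 0.02) giving a slightly increasing coefficient
#' function, and outcome noise SD 0.6. The eigenvalue and noise scales are a
#' plausible invention for demonstration and testing, not a reconstruction of
#' any particular cohort; the theoretical R-squared of the preset is 0.586.
#'
#' @param n number of subjects (default 46, a typical small mHealth cohort).
#' @param seed integer seed.
#' @return A \code{"sim_config"}.
#' @export
default_study_config <- function(n = 46L, seed = 1L) {
  sim_config(
    n = n,
    grid = time_grid(-90:0),
    mean_fun = function(t) 130 + 0.05 * (t + 45) + 8 * sin(pi * (t + 90) / 91),
    eigenvalues = c(400, 50),
    basis_family = "polynomial",
    predictor_noise_sd = 5,
    sampling = list(type = "bernoulli", prob = 0.5),
    alpha = 7.5,
    beta_weights = c(0.035, 0.02),
    outcome_noise_sd = 0.6,
    seed = seed
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: n = %d, %d component(s), lambda = %s\n",
              x$n, length(x$eigenvalues),
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  cat(sprintf("  predictor noise sd %.3g, outcome noise sd %.3g, sampling %s, seed %d\n",
              x$predictor_noise_sd, x$outcome_noise_sd,
              if (identical(x$sampling$type, "bernoulli"))
                sprintf("Bernoulli(%.2f)", x$sampling$prob)
              else sprintf("fixed(%d)", x$sampling$count),
              x$seed))
  invisible(x)
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: %d subjects, %d observations, theoretical R2 %.3f\n",
              x$data$n, nrow(x$data$obs), x$truth$r2_theoretical))
  invisible(x)
}
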