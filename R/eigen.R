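#' Eigendecompose a covariance model into functional principal components
#'
#' Solves the discretized eigenproblem under the grid quadrature: with W the
#' diagonal matrix of quadrature weights, the symmetric problem
#' \eqn{W^{1/2} G W^{1/2} u = \lambda u} is solved and eigenvectors are mapped
#' back to functions \eqn{\upsilon = W^{-1/2} u}, which are orthonormal in the
#' quadrature inner product. Eigenvalues at or below a relative ridge
#' tolerance of the leading one are discarded (truncation keeps the retained
#' system orthonormal). Each eigenfunction's sign is fixed so its integral
#' over the window is nonnegative; when that integral is numerically zero the
#' value at the window end (day 0) is made nonnegative.
#'
#' @param cov a \code{"cov_model"} object (the surface must be symmetric).
#' @param tol relative eigenvalue tolerance below which components are
#'   discarded.
#' @return An object of class \code{"fpca_eigen"}: list with \code{grid},
#'   \code{values} (positive, nonincreasing), \code{functions} (m x K matrix,
#'   one column per component) and \code{noise_variance} carried over.
#' @export
eigendecompose_cov <- function(cov, tol = 1e-10) {
  stopifnot(inherits(cov, "cov_model"))
  G <- cov$surface
  if (max(abs(G - t(G))) > 1e-8) stop("covariance surface is not symmetric")
  grid <- cov$grid
  sw <- sqrt(grid$weights)
  A <- G * (sw %o% sw)
  A <- (A + t(A)) / 2
  es <- eigen(A, symmetric = TRUE)
  keep <- es$values > tol * max(es$values[1], 0)
  if (!any(keep)) stop("covariance surface has no positive eigenvalues")
  values <- es$values[keep]
  fns <- es$vectors[, keep, drop = FALSE] / sw
  for (j in seq_len(ncol(fns))) {
    s <- grid_integral(grid, fns[, j])
    if (abs(s) <= 1e-10) s <- fns[nrow(fns), j]
    if (s < 0) fns[, j] <- -fns[, j]
  }
  structure(list(grid = grid, values = values, functions = fns,
                 noise_variance = cov$noise_variance),
            class = "fpca_eigen")
}

#' Choose the number of components by proportion of variance explained
#'
#' Returns the smallest k whose cumulative eigenvalue share reaches the
#' threshold, together with the scree table.
#'
#' @param eigenvalues positive, nonincreasing eigenvalues (or an
#'   \code{"fpca_eigen"} object).
#' @param pve_threshold required cumulative proportion of variance explained,
#'   in (0, 1]; default 0.95.
#' @return A list with \code{p} (the truncation order) and \code{table} (the
#'   scree table, see [scree_table()]).
#' @export
select_ncomp <- function(eigenvalues, pve_threshold = 0.95) {
  if (inherits(eigenvalues, "fpca_eigen")) eigenvalues <- eigenvalues$values
  if (!length(eigenvalues)) stop("no eigenvalues supplied")
  if (any(eigenvalues <= 0)) stop("eigenvalues must be positive")
  if (!(pve_threshold > 0 && pve_threshold <= 1)) {
    stop("pve_threshold must be in (0, 1]")
  }
  cum <- cumsum(eigenvalues) / sum(eigenvalues)
  p <- which(cum >= pve_threshold - 1e-12)[1L]
  list(p = p, table = scree_table(eigenvalues))
}

#' Scree table of eigenvalues and variance shares
#'
#' @param x positive eigenvalues, an \code{"fpca_eigen"} object or a fitted
#'   \code{"fpca_sparse"} model.
#' @return A data.frame with columns \code{component}, \code{eigenvalue},
#'   \code{proportion} and \code{cumulative}; proportions sum to 1 over all
#'   positive components.
#' @export
scree_table <- function(x) {
  ev <- if (inherits(x, "fpca_eigen")) x$values
        else if (inherits(x, "fpca_sparse")) x$eigen$values
        else as.numeric(x)
  if (!length(ev) || any(ev <= 0)) stop("scree table needs positive eigenvalues")
  data.frame(component = seq_along(ev), eigenvalue = ev,
             proportion = ev / sum(ev), cumulative = cumsum(ev) / sum(ev))
}

## truncate a full eigensystem to its leading p components
truncate_basis <- function(eig, p) {
  stopifnot(inherits(eig, "fpca_eigen"), p >= 1L, p <= length(eig$values))
  structure(list(grid = eig$grid, values = eig$values[seq_len(p)],
                 functions = eig$functions[, seq_len(p), drop = FALSE],
                 p = p, pve = (cumsum(eig$values) / sum(eig$values))[p],
                 noise_variance = eig$noise_variance),
            class = "fpca_basis")
}
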