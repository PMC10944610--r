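## Penalized B-spline (P-spline) smoothers used by the mean and covariance
## estimators: cubic B-splines on equally spaced knots, second-order
## difference penalty, smoothing parameter chosen by GCV over a log-spaced
## lambda grid. The 2-D (tensor-product) fit works on cell-binned data and
## uses the Demmler-Reinsch reparameterisation so the whole lambda scan costs
## one Cholesky + one symmetric eigendecomposition.

## cubic B-spline design matrix with `knots` equally spaced interior knots
## on `range`; basis dimension is knots + 4
bspline_basis <- function(x, range, knots) {
  if (knots < 4L) stop("configuration error: at least 4 knots are required")
  degree <- 3L
  inner <- seq(range[1], range[2], length.out = knots + 2L)
  ext <- c(rep(inner[1], degree), inner, rep(inner[length(inner)], degree))
  x <- pmin(pmax(x, range[1]), range[2])
  splines::splineDesign(ext, x, ord = degree + 1L)
}

diff_penalty <- function(q, order = 2L) {
  D <- diff(diag(q), differences = order)
  crossprod(D)
}

default_loglambda <- function() seq(-4, 9, length.out = 40)

## EDF inflation in the GCV score. Raw cross-products (and, less so, pooled
## observations) are correlated within subject, which plain GCV -- derived
## under independent errors -- answers by undersmoothing; inflating the
## effective degrees of freedom is the standard guard.
gcv_gamma <- 1.4

## Parsimony tie-break on the 2-D lambda scan: among candidates whose GCV
## lies within a small tolerance of the minimum, take the largest lambda.
## Binned cross-products are so noisy and so correlated within subject that
## their GCV curve is nearly flat in lambda and its argmin is arbitrary;
## genuine covariance structure makes GCV rise steeply when oversmoothed, so
## the rule only bites on flat curves (same rationale as the
## one-standard-error rule in cross-validated model selection). The 1-D
## pooled-scatter mean fit has far better signal-to-noise and uses the plain
## GCV minimum.
gcv_flat_tol <- 0.01

pick_flattest <- function(fits) {
  gcvs <- vapply(fits, `[[`, numeric(1), "gcv")
  ok <- which(gcvs <= min(gcvs) * (1 + gcv_flat_tol))
  fits[[max(ok)]]
}

## 1-D penalized-spline scatterplot smoother.
## x, y, w: data (w >= 0); returns fitted values at `xout`.
pspline_1d <- function(x, y, w = NULL, range = range(x), knots = 35L,
                       xout = x, lambda = NULL,
                       loglambda = default_loglambda()) {
  if (is.null(w)) w <- rep(1, length(x))
  keep <- w > 0
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  B <- bspline_basis(x, range, knots)
  q <- ncol(B)
  P <- diff_penalty(q)
  Bw <- B * sqrt(w)
  C <- crossprod(Bw)
  rhs <- crossprod(B, w * y)
  eps <- 1e-8 * mean(diag(C))
  R <- chol(C + eps * diag(q))
  Rinv <- backsolve(R, diag(q))
  S <- crossprod(Rinv, P %*% Rinv)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  U <- es$vectors
  sv <- pmax(es$values, 0)
  a0 <- crossprod(U, crossprod(Rinv, rhs))
  yWy <- sum(w * y^2)
  n_eff <- length(y)
  pick <- function(lam) {
    d <- 1 / (1 + lam * sv)
    b <- Rinv %*% (U %*% (d * a0))
    rss <- max(yWy - 2 * sum(b * rhs) + sum(b * (C %*% b)), 0)
    edf <- sum(d)
    list(lambda = lam, coef = b, edf = edf,
         gcv = n_eff * rss / (n_eff - gcv_gamma * edf)^2)
  }
  if (!is.null(lambda)) {
    best <- pick(lambda)
  } else {
    fits <- lapply(10^loglambda, pick)
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "gcv"))]]
  }
  Bout <- bspline_basis(xout, range, knots)
  list(fitted = as.numeric(Bout %*% best$coef), lambda = best$lambda,
       edf = best$edf, coef = best$coef, range = range, knots = knots)
}

## 2-D tensor-product penalized-spline fit to cell-binned data on a square
## grid. Z and W are m x m matrices of cell means and cell weights (counts);
## cells with W == 0 are ignored. The penalty is
## lambda * (P (x) I + I (x) P): a single smoothing parameter shared by both
## margins, which keeps the fitted surface exchangeable in (s, t).
pspline_2d <- function(Z, W, points, knots = 35L, lambda = NULL,
                       loglambda = default_loglambda()) {
  m <- length(points)
  stopifnot(all(dim(Z) == c(m, m)), all(dim(W) == c(m, m)))
  rng <- range(points)
  B <- bspline_basis(points, rng, knots)
  q <- ncol(B)
  ## GLAM-style normal equations: with coefficient theta[a, b] flattened
  ## a-fastest, C[(a,b),(a',b')] = sum_st W_st B_sa B_sa' B_tb B_tb'
  Brow <- B[, rep(seq_len(q), each = q)] * B[, rep(seq_len(q), times = q)]
  M <- crossprod(Brow, W %*% Brow)        # [(a,a'), (b,b')] blocks
  dim(M) <- c(q, q, q, q)                 # dims (a', a, b', b)
  C <- aperm(M, c(2, 4, 1, 3))            # dims (a, b, a', b')
  dim(C) <- c(q * q, q * q)
  C <- (C + t(C)) / 2
  Zw <- W * Z
  Zw[W == 0] <- 0
  rhs <- as.vector(crossprod(B, Zw %*% B))  # [a, b], a-fastest
  P1 <- diff_penalty(q)
  Iq <- diag(q)
  P <- kronecker(P1, Iq) + kronecker(Iq, P1)
  eps <- 1e-8 * mean(diag(C))
  R <- chol(C + eps * diag(q * q))
  Rinv <- backsolve(R, diag(q * q))
  S <- crossprod(Rinv, P %*% Rinv)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  U <- es$vectors
  sv <- pmax(es$values, 0)
  a0 <- crossprod(U, crossprod(Rinv, rhs))
  zWz <- sum(W * Z^2, na.rm = TRUE)
  n_eff <- sum(W > 0)
  pick <- function(lam) {
    d <- 1 / (1 + lam * sv)
    b <- Rinv %*% (U %*% (d * a0))
    rss <- max(zWz - 2 * sum(b * rhs) + sum(b * (C %*% b)), 0)
    edf <- sum(d)
    list(lambda = lam, coef = b, edf = edf,
         gcv = n_eff * rss / (n_eff - gcv_gamma * edf)^2)
  }
  if (!is.null(lambda)) {
    best <- pick(lambda)
  } else {
    best <- pick_flattest(lapply(10^loglambda, pick))
  }
  Theta <- matrix(best$coef, q, q)
  surface <- B %*% Theta %*% t(B)
  surface <- (surface + t(surface)) / 2
  list(surface = surface, lambda = best$lambda, edf = best$edf)
}
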