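# shared fixtures and small independent oracles used across test files

# tiny long-format table with labels
tiny_long <- function() {
  data.frame(
    subject_id = c("A", "A", "A", "B", "B", "B"),
    time = c(-5, -3, 0, -10, -3, 0),
    value = c(100, 110, 120, 90, 95, 105),
    label = c("before-breakfast", "after-dinner", "before-breakfast",
              "before-breakfast", "before-breakfast", "after-dinner"),
    stringsAsFactors = FALSE
  )
}

# analysis dataset straight from a long table + outcomes
tiny_ads <- function(df = tiny_long(), outcome = c(A = 7, B = 8)) {
  outcomes <- data.frame(subject_id = names(outcome), outcome = unname(outcome),
                         stringsAsFactors = FALSE)
  analysis_dataset(as_ild(df), outcomes)
}

# a small, fast simulated study (short grid, small knots downstream)
quick_config <- function(n = 25, seed = 1, grid = time_grid(-20:0),
                         eigenvalues = c(9, 2), noise = 0.5,
                         prob = 0.7, beta = c(0.4, 0.2), sigma = 0.3) {
  sim_config(n = n, grid = grid,
             mean_fun = function(t) 10 + 0.1 * t,
             eigenvalues = eigenvalues, basis_family = "polynomial",
             predictor_noise_sd = noise,
             sampling = list(type = "bernoulli", prob = prob),
             alpha = 2, beta_weights = beta, outcome_noise_sd = sigma,
             seed = seed)
}

# dense, noiseless rank-2 study on the full 91-day grid
dense_noiseless_config <- function(n = 30, seed = 1) {
  sim_config(n = n, grid = time_grid(-90:0),
             mean_fun = function(t) 130 + 0.05 * (t + 45),
             eigenvalues = c(400, 50), basis_family = "polynomial",
             predictor_noise_sd = 0,
             sampling = list(type = "bernoulli", prob = 1),
             alpha = 7.5, beta_weights = c(0.035, 0.02),
             outcome_noise_sd = 0, seed = seed)
}

# quadrature inner product, independent of the package internals
quad_ip <- function(grid, f, g) {
  w <- grid$weights
  sum(w * f * g)
}

# align the sign of estimated basis columns (and anything keyed to them)
# to a reference basis
sign_align <- function(est, ref, grid) {
  s <- vapply(seq_len(ncol(est)), function(j) {
    sign(quad_ip(grid, est[, j], ref[, j]))
  }, numeric(1))
  s[s == 0] <- 1
  sweep(est, 2, s, `*`)
}

# independent normal-equations OLS oracle
ols_oracle <- function(X, y) {
  Xd <- cbind(1, X)
  as.numeric(solve(t(Xd) %*% Xd, t(Xd) %*% y))
}
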