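# Independent oracles used across the suite.

# Matrix exponential via eigendecomposition (K2P rate matrices are
# diagonalisable with real spectrum).
expm_oracle <- function(M) {
  e <- eigen(M)
  out <- Re(e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors))
  dimnames(out) <- dimnames(M)
  out
}

# Dense-grid brute-force minimax: for each slope the optimal intercept is the
# Chebyshev centre of the residuals, so the deviation is half the residual
# range divided by the slope.  The slope grid is refined iteratively because
# the objective typically has a kink at its minimiser.
brute_force_dev <- function(g, t0, t1, n_t = 4001, n_a = 2001) {
  ts <- seq(t0, t1, length.out = n_t)
  gv <- g(ts)
  A <- (gv[n_t] - gv[1]) / (t1 - t0)
  h <- function(a) {
    r <- gv - a * ts
    (max(r) - min(r)) / (2 * a)
  }
  lo <- A / 5
  hi <- 5 * A
  for (pass in 1:4) {
    a_grid <- seq(lo, hi, length.out = n_a)
    vals <- vapply(a_grid, h, numeric(1))
    i <- which.min(vals)
    step <- a_grid[2] - a_grid[1]
    lo <- max(A / 5, a_grid[i] - 2 * step)
    hi <- min(5 * A, a_grid[i] + 2 * step)
  }
  min(vals)
}

# Dense grid-search maximiser of the fixed-ratio trinomial log-likelihood.
grid_ml_t <- function(pa_hat, pb_hat, R, t_max = 20, n = 400001) {
  ts <- seq(1e-8, t_max, length.out = n)
  beta <- 1 / (2 * (R + 1)); alpha <- R / (R + 1)
  qa <- (1 + exp(-4 * beta * ts) - 2 * exp(-2 * (alpha + beta) * ts)) / 4
  qb <- (1 - exp(-4 * beta * ts)) / 4
  ll <- pa_hat * log(pmax(qa, 1e-300)) + 2 * pb_hat * log(pmax(2 * qb, 1e-300)) +
    (1 - pa_hat - 2 * pb_hat) * log(pmax(1 - qa - 2 * qb, 1e-300))
  ts[which.max(ll)]
}

# Random binary unrooted tree with exponential edge lengths (via ape).
random_tree <- function(n, mean_len = 0.3) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::rexp(length(tr$edge.length), 1 / mean_len)
  tr
}
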