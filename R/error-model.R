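# First-order (delta-method) standard deviations of the SR estimators, and
# their empirical (Monte-Carlo) validation oracle.
#
# Derivation sketch: per site, the mismatch class is trinomial with
# probabilities (p_alpha, 2 p_beta, rest), so Var(p_alpha_hat) =
# p_alpha(1-p_alpha)/k, Var(p_beta_hat) = p_beta(1-2 p_beta)/(2k),
# Cov = -p_alpha p_beta / k.  Propagating through the estimator gradients
# gives the closed forms below; both scale exactly as 1/sqrt(k).

# numeric (vectorised) cores ------------------------------------------------

var_k2p_ <- function(R, t, k) {
  u <- exp(2 * t / (R + 1))       # = exp(4 beta t)
  ((u^2 - 1) + 4 * (u - 1) + 2 * (exp(4 * R * t / (R + 1)) * (u + 1) - 2)) / (16 * k)
}

sigma_k2p_ <- function(R, t, k) sqrt(var_k2p_(R, t, k))

p_total_ <- function(R, t) {
  0.75 - 0.25 * exp(-2 * t / (R + 1)) - 0.5 * exp(-(2 * R + 1) * t / (R + 1))
}

var_jc_ <- function(R, t, k) {
  p <- p_total_(R, t)
  p * (1 - p) / (k * (1 - 4 * p / 3)^2)
}

sigma_jc_ <- function(R, t, k) sqrt(var_jc_(R, t, k))

# Delta method for the transversion-only distance: d = -(1/4) log(1-4 p_beta),
# Var(p_beta_hat) = p_beta (1 - 2 p_beta) / (2k).
var_tv_ <- function(R, t, k) {
  pb <- (1 - exp(-2 * t / (R + 1))) / 4
  pb * (1 - 2 * pb) / (2 * k * (1 - 4 * pb)^2)
}

sigma_tv_ <- function(R, t, k) sqrt(var_tv_(R, t, k))

noise_estimate <- function(sd, k, source) {
  structure(list(sd = sd, k = k, source = source), class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("noise estimate: sd = %g (k = %g, %s)\n", x$sd, x$k, x$source))
  if (!is.null(x$n_saturated) && x$n_saturated > 0)
    cat(sprintf("  saturated replicates dropped: %d of %d\n", x$n_saturated, x$reps))
  invisible(x)
}

#' Delta-method standard deviation of the K2P distance estimator
#'
#' First-order approximation of the standard deviation of [delta_k2p()]
#' applied to statistics estimated from `k` aligned sites at model
#' parameters `(R, t)`:
#' \deqn{\sigma(\Delta_{K2P}) \approx \sqrt{\frac{(e^{4t/(R+1)}-1)
#'   + 4(e^{2t/(R+1)}-1) + 2\big(e^{4Rt/(R+1)}(e^{2t/(R+1)}+1)-2\big)}{16k}}.}
#' The grouping is the one obtained by propagating the trinomial covariance
#' of the mismatch counts through the estimator gradient; it is validated
#' against Monte-Carlo in the package tests.
#'
#' @inheritParams k2p_params
#' @param k Sequence length (sites).
#' @return A `noise_estimate` with fields `sd`, `k`, `source = "analytic"`.
#' @export
sigma_k2p <- function(R, t, k) {
  check_ratio(R)
  if (any(t < 0) || any(k < 1)) stop_invalid("need t >= 0 and k >= 1")
  noise_estimate(sigma_k2p_(R, t, k), k, "analytic")
}

#' Delta-method standard deviation of the Jukes-Cantor distance estimator
#'
#' \deqn{\sigma(\Delta_{JC}) \approx
#'   \sqrt{\frac{p(1-p)}{k\,(1-\tfrac43 p)^2}}, \qquad
#'   p = p_\alpha + 2p_\beta = \tfrac34 - \tfrac14 e^{-2t/(R+1)}
#'       - \tfrac12 e^{-(2R+1)t/(R+1)}.}
#'
#' @inheritParams sigma_k2p
#' @return A `noise_estimate`.
#' @export
sigma_jc <- function(R, t, k) {
  check_ratio(R)
  if (any(t < 0) || any(k < 1)) stop_invalid("need t >= 0 and k >= 1")
  p <- p_total_(R, t)
  if (any(p >= 0.75)) stop_saturation("saturated: p >= 3/4", which = "jc")
  noise_estimate(sigma_jc_(R, t, k), k, "analytic")
}

#' Noise of an affine-additive surrogate
#'
#' The closest affine-additive function `a t + b` to a non-additive SR
#' function is estimated through the additive [delta_k2p()] estimator, so
#' its standard deviation is the K2P one scaled by the slope:
#' `sigma(Delta*) = a * sigma(Delta_K2P)`.
#'
#' @param fit An affine fit with field `a` (e.g. from
#'   [linear_interpolation()] or [deviation_from_additivity()]`$fit`).
#' @param sd_k2p A `noise_estimate` for the K2P distance (or a bare number).
#' @return A `noise_estimate` with the scaled sd.
#' @export
sigma_affine <- function(fit, sd_k2p) {
  a <- if (is.list(fit)) fit$a else fit
  if (!is.numeric(a) || a <= 0) stop_invalid("affine slope 'a' must be positive")
  sd <- if (inherits(sd_k2p, "noise_estimate")) sd_k2p$sd else sd_k2p
  k <- if (inherits(sd_k2p, "noise_estimate")) sd_k2p$k else NA_real_
  noise_estimate(a * sd, k, "analytic")
}

#' Monte-Carlo standard deviation of an SR estimator
#'
#' Simulates `reps` two-leaf alignments of `k` sites at separation `t` under
#' the homogeneous K2P sub-model with ti-tv ratio `R`, applies the SR
#' function to the estimated pair statistics of each replicate, and returns
#' the sample standard deviation.  Saturated replicates are dropped (capping
#' would bias the SD) and counted; more than 10% dropped attaches an
#' unreliable-estimate warning flag to the result.
#'
#' @param delta An [sr_function()] or SR name.
#' @inheritParams sigma_k2p
#' @param reps Number of replicates (`>= 100`).
#' @param seed Optional seed for reproducibility.
#' @return A `noise_estimate` with `source = "monte_carlo"` and extra fields
#'   `reps`, `n_saturated`, `unreliable`.
#' @export
empirical_sigma <- function(delta, R, t, k, reps = 1000, seed = NULL) {
  sr <- sr_function(delta)
  check_ratio(R)
  if (reps < 100) stop_invalid("'reps' must be at least 100")
  k <- as.integer(k)
  with_seed(seed, {
    vals <- numeric(0)
    chunk <- max(1L, min(reps, as.integer(ceiling(2e6 / k))))
    done <- 0L
    while (done < reps) {
      m <- min(chunk, reps - done)
      a <- sample.int(4L, k * m, replace = TRUE)
      b <- evolve_states(a, t, R)
      differ <- a != b
      same_class <- (a <= 2L) == (b <= 2L)
      n_ti <- colSums(matrix(differ & same_class, nrow = k))
      n_tv <- colSums(matrix(differ & !same_class, nrow = k))
      vals <- c(vals, sr_dist_vec(sr, n_ti / k, n_tv / (2 * k)))
      done <- done + m
    }
    n_sat <- sum(!is.finite(vals))
    out <- noise_estimate(stats::sd(vals[is.finite(vals)]), k, "monte_carlo")
    out$reps <- reps
    out$n_saturated <- n_sat
    out$unreliable <- n_sat > 0.1 * reps
    if (out$unreliable)
      warning(sprintf("more than 10%% of replicates saturated (%d of %d); SD estimate unreliable",
                      n_sat, reps))
    out
  })
}
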