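# Substitution-rate (SR) functions: maps from transition statistics to a
# scalar evolutionary distance.  Each public function signals a typed
# saturation error outside its domain; the vectorised internal variants
# (dist_*_vec) return NaN instead and are used by the simulation drivers,
# which apply a cap policy.

as_probs <- function(p_alpha, p_beta) {
  if (inherits(p_alpha, "transition_probs") || inherits(p_alpha, "pair_stats")) {
    pr <- p_alpha
    if (inherits(pr, "pair_stats"))
      return(list(p_alpha = pr$p_alpha_hat, p_beta = pr$p_beta_hat))
    return(list(p_alpha = pr$p_alpha, p_beta = pr$p_beta))
  }
  list(p_alpha = p_alpha, p_beta = p_beta)
}

#' K2P distance
#'
#' The additive SR function of the K2P model,
#' \deqn{\Delta_{K2P} = -\tfrac12 \ln(1 - 2p_\beta - 2p_\alpha)
#'       - \tfrac14 \ln(1 - 4p_\beta),}
#' which on exact transition probabilities equals the evolutionary time `t`.
#'
#' @param p_alpha Transition-type probability (or a `transition_probs` /
#'   `pair_stats` object, in which case `p_beta` is ignored).
#' @param p_beta Per-target transversion-type probability.
#' @return Distance in time units.
#' @export
delta_k2p <- function(p_alpha, p_beta = NULL) {
  pr <- as_probs(p_alpha, p_beta)
  w1 <- 1 - 2 * pr$p_beta - 2 * pr$p_alpha
  w2 <- 1 - 4 * pr$p_beta
  if (any(w1 <= 0))
    stop_saturation("saturated: 1 - 2 p_beta - 2 p_alpha <= 0", which = "ti")
  if (any(w2 <= 0))
    stop_saturation("saturated: 1 - 4 p_beta <= 0", which = "tv")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Jukes-Cantor distance
#'
#' \deqn{\Delta_{JC} = -\tfrac34 \ln(1 - \tfrac43 (p_\alpha + 2p_\beta)).}
#' Additive only in the Jukes-Cantor sub-model (`R = 1/2`); under other
#' homogeneous K2P sub-models it is concave in `t` and therefore deviates
#' from additivity (see [deviation_from_additivity()]).
#'
#' @inheritParams delta_k2p
#' @return Distance in time units.
#' @export
delta_jc <- function(p_alpha, p_beta = NULL) {
  pr <- as_probs(p_alpha, p_beta)
  p <- pr$p_alpha + 2 * pr$p_beta
  if (any(p >= 0.75))
    stop_saturation("saturated: p_alpha + 2 p_beta >= 3/4", which = "jc")
  -0.75 * log1p(-4 * p / 3)
}

#' Transversion-only distance
#'
#' \deqn{\Delta_{tv} = -\tfrac14 \ln(1 - 4 p_\beta),}
#' which on exact probabilities equals `beta t = t / (2(R+1))`.  Robust to
#' transition saturation, at the price of using fewer informative sites.
#'
#' @inheritParams delta_k2p
#' @return Distance in time units (an affine rescaling of `t` at fixed `R`).
#' @export
delta_tv <- function(p_alpha, p_beta = NULL) {
  pr <- as_probs(p_alpha, p_beta)
  w2 <- 1 - 4 * pr$p_beta
  if (any(w2 <= 0))
    stop_saturation("saturated: 1 - 4 p_beta <= 0", which = "tv")
  -0.25 * log(w2)
}

#' Fixed-ratio maximum-likelihood distance
#'
#' Maximum-likelihood estimate of the evolutionary time `t` from observed
#' pair statistics, assuming the homogeneous K2P sub-model with known ti-tv
#' ratio `R`.  Maximises the per-site trinomial log-likelihood
#' `p_alpha_hat log p_alpha(t) + 2 p_beta_hat log(2 p_beta(t)) + (rest) log(1
#' - p_alpha(t) - 2 p_beta(t))` over `t` in `(0, t_max]` by 1-D bounded
#' search.  When the observed statistics lie exactly on the model curve for
#' this `R`, the estimate coincides with [delta_k2p()].
#'
#' @param stats A `pair_stats` object, or a list with `p_alpha_hat`,
#'   `p_beta_hat`.
#' @param R The assumed ti-tv ratio (`>= 1/2`).
#' @param t_max Upper search bound (default 20).
#' @param tol Absolute tolerance of the optimiser (default 1e-9).
#' @return The ML distance in time units (0 for identical sequences).
#' @export
delta_r_ml <- function(stats, R, t_max = 20, tol = 1e-9) {
  check_ratio(R)
  if (inherits(stats, "transition_probs"))
    stats <- list(p_alpha_hat = stats$p_alpha, p_beta_hat = stats$p_beta)
  pa <- stats$p_alpha_hat
  pb <- stats$p_beta_hat
  if (is.null(pa) || is.null(pb) || pa < 0 || pb < 0 || pa + 2 * pb > 1)
    stop_invalid("invalid pair statistics")
  if (pa == 0 && pb == 0) return(0)
  f_same <- 1 - pa - 2 * pb
  ll <- function(t) {
    pr <- transition_probs(R, t)
    qa <- max(pr$p_alpha, 1e-300)
    qb <- max(pr$p_beta, 1e-300)
    qs <- max(1 - pr$p_alpha - 2 * pr$p_beta, 1e-300)
    pa * log(qa) + 2 * pb * log(2 * qb) + f_same * log(qs)
  }
  opt <- stats::optimize(ll, c(1e-8, t_max), maximum = TRUE, tol = tol)
  opt$maximum
}

#' Jukes-Cantor distance as a function of time under K2P
#'
#' The closed form of `delta_jc` composed with the exact transition
#' probabilities of the homogeneous K2P sub-model with ti-tv ratio `R`:
#' \deqn{\Delta_{JC}(R,t) = \frac{3t}{2(R+1)}
#'   - \tfrac34 \ln\!\Big(\tfrac13 (1 + 2 e^{-\rho t})\Big), \qquad
#'   \rho = \frac{2R-1}{R+1}.}
#' At `R = 1/2` this reduces to `t`.
#'
#' @inheritParams k2p_params
#' @return Distance in time units.
#' @export
delta_jc_time <- function(R, t) {
  check_ratio(R)
  rho <- (2 * R - 1) / (R + 1)
  3 * t / (2 * (R + 1)) - 0.75 * log((1 + 2 * exp(-rho * t)) / 3)
}

#' Derivatives of the time-parameterised Jukes-Cantor distance
#'
#' Closed-form first, second and third derivatives of [delta_jc_time()] with
#' respect to `t`.  With `rho = (2R-1)/(R+1)` and `x = exp(-rho t)`:
#' order 1 is `3/(2(R+1)) + (3/2) rho x / (1+2x)` (positive); order 2 is
#' `-(3/2) rho^2 x / (1+2x)^2` (negative for `R > 1/2`, with global minimum
#' `-(3/16) rho^2` at `t = ln(2)/rho`); order 3 is
#' `(3/2) rho^3 x (1-2x) / (1+2x)^3`.
#'
#' @inheritParams k2p_params
#' @param order Derivative order, 1, 2 or 3.
#' @return The derivative value (vectorised over `t`).
#' @export
delta_jc_derivative <- function(R, t, order = 1) {
  check_ratio(R)
  if (!order %in% c(1, 2, 3)) stop_invalid("'order' must be 1, 2 or 3")
  rho <- (2 * R - 1) / (R + 1)
  x <- exp(-rho * t)
  switch(order,
    3 / (2 * (R + 1)) + 1.5 * rho * x / (1 + 2 * x),
    -1.5 * rho^2 * x / (1 + 2 * x)^2,
    1.5 * rho^3 * x * (1 - 2 * x) / (1 + 2 * x)^3
  )
}

#' LogDet distance from a pairwise joint count matrix
#'
#' Computes `-(1/4) log det` of the doubly-normalised divergence matrix: the
#' joint relative frequency matrix `F` is rescaled by the inverse square
#' roots of its row and column sums, i.e. the returned value is
#' `-(1/4) (log det F - (1/2) sum_i (log f_i. + log f_.i))`.  This symmetric
#' normalisation follows the common distance-matrix implementations; the
#' identity divergence gives 0.
#'
#' @param joint_counts 4x4 matrix of per-site joint state counts for an
#'   aligned pair (rows: first sequence, columns: second).
#' @return LogDet distance.
#' @section Errors: a non-positive determinant signals a saturation error.
#' @export
delta_logdet <- function(joint_counts) {
  if (!is.matrix(joint_counts) || !all(dim(joint_counts) == c(4L, 4L)))
    stop_invalid("'joint_counts' must be a 4x4 matrix")
  if (any(joint_counts < 0) || sum(joint_counts) <= 0)
    stop_invalid("'joint_counts' must be non-negative with positive total")
  F <- joint_counts / sum(joint_counts)
  d <- det(F)
  rs <- rowSums(F)
  cs <- colSums(F)
  if (d <= 0 || any(rs <= 0) || any(cs <= 0))
    stop_saturation("saturated: non-positive determinant of the divergence matrix",
                    which = "logdet")
  -0.25 * (log(d) - 0.5 * sum(log(rs) + log(cs)))
}

# ---- vectorised internal variants (NaN on saturation) -------------------

dist_k2p_vec <- function(pa, pb) {
  w1 <- 1 - 2 * pa - 2 * pb
  w2 <- 1 - 4 * pb
  ok <- w1 > 0 & w2 > 0
  out <- rep(NaN, length(w1))
  out[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  out
}

dist_jc_vec <- function(pa, pb) {
  p <- pa + 2 * pb
  ok <- p < 0.75
  out <- rep(NaN, length(p))
  out[ok] <- -0.75 * log1p(-4 * p[ok] / 3)
  out
}

dist_tv_vec <- function(pa, pb) {
  w2 <- 1 - 4 * pb
  ok <- w2 > 0
  out <- rep(NaN, length(w2))
  out[ok] <- -0.25 * log(w2[ok])
  out
}

# ---- the sr_function container ------------------------------------------

#' SR functions addressable by name
#'
#' Builds an SR-function object bundling the map from transition statistics
#' (`value_from_probs`), its composition with the exact K2P transition
#' probabilities (`value_from_time(R, t)`), and, where available, the
#' first-order (delta-method) standard deviation of its estimator
#' (`sigma(R, t, k)`).
#'
#' Recognised names: `"k2p"`, `"jc"`, `"tv"`, and `"r-ml:<R>"` (fixed-ratio
#' ML, e.g. `"r-ml:2"`).  The LogDet distance operates on joint count
#' matrices rather than on `(p_alpha, p_beta)` and is therefore exposed only
#' through [delta_logdet()] and [distance_matrix()].
#'
#' @param name SR function name.
#' @return An object of class `sr_function` with fields `name`,
#'   `value_from_probs(p_alpha, p_beta)`, `value_from_time(R, t)`,
#'   `sigma(R, t, k)` (or `NULL`), and `additive` (flag: affine-additive in
#'   every homogeneous K2P sub-model).
#' @examples
#' jc <- sr_function("jc")
#' jc$value_from_time(10, 1.4)
#' @export
sr_function <- function(name) {
  if (inherits(name, "sr_function")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  if (grepl("^r-ml:", name)) {
    R0 <- suppressWarnings(as.numeric(sub("^r-ml:", "", name)))
    if (is.na(R0)) stop_invalid("malformed SR name; expected 'r-ml:<R>'")
    check_ratio(R0)
    obj <- list(
      name = name,
      value_from_probs = function(p_alpha, p_beta = NULL) {
        pr <- as_probs(p_alpha, p_beta)
        delta_r_ml(list(p_alpha_hat = pr$p_alpha, p_beta_hat = pr$p_beta), R0)
      },
      value_from_time = function(R, t)
        vapply(t, function(ti) {
          pr <- transition_probs(R, ti)
          delta_r_ml(list(p_alpha_hat = pr$p_alpha, p_beta_hat = pr$p_beta), R0)
        }, numeric(1)),
      sigma = NULL,
      additive = TRUE
    )
    return(structure(obj, class = "sr_function"))
  }
  obj <- switch(name,
    k2p = list(
      name = "k2p",
      value_from_probs = delta_k2p,
      value_from_time = function(R, t) t + 0 * check_ratio(R),
      sigma = function(R, t, k) sigma_k2p_(R, t, k),
      additive = TRUE
    ),
    jc = list(
      name = "jc",
      value_from_probs = delta_jc,
      value_from_time = delta_jc_time,
      sigma = function(R, t, k) sigma_jc_(R, t, k),
      additive = FALSE
    ),
    tv = list(
      name = "tv",
      value_from_probs = delta_tv,
      value_from_time = function(R, t) t / (2 * (R + 1)),
      sigma = function(R, t, k) sigma_tv_(R, t, k),
      additive = TRUE
    ),
    stop_invalid(sprintf("unknown SR function '%s'", name))
  )
  structure(obj, class = "sr_function")
}

#' @export
print.sr_function <- function(x, ...) {
  cat(sprintf("SR function '%s' (%s)\n", x$name,
              if (x$additive) "affine-additive under K2P" else "non-additive under K2P"))
  invisible(x)
}

# Vectorised distance on estimated statistics, NaN on saturation.
sr_dist_vec <- function(sr, pa, pb) {
  switch(sr$name,
    k2p = dist_k2p_vec(pa, pb),
    jc = dist_jc_vec(pa, pb),
    tv = dist_tv_vec(pa, pb),
    # fixed-ratio ML: bounded optimisation per entry
    vapply(seq_along(pa), function(i)
      sr$value_from_probs(pa[i], pb[i]), numeric(1))
  )
}
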