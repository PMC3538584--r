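# Deviation from additivity: linear interpolation, the minimax measure, its
# interpolation-error upper bound, and consistency checks derived from it.
#
# In a homogeneous model an SR function reduces to a univariate function of
# the evolutionary time t; it is affine-additive iff it equals a t + b with
# a > 0.  The deviation from additivity of Delta over [t0, t1] is
#     dev(Delta, [t0,t1]) = inf_{a>0, b} max_t |Delta(t) - a t - b| / a,
# the slope normalisation putting the measure in time units so it can be
# compared to internal edge lengths (half the minimal internal edge length
# guarantees consistency of robust distance methods).

# Coerce an SR specification to a univariate function of t.
as_time_function <- function(delta, R = NULL) {
  if (is.function(delta)) return(delta)
  sr <- sr_function(delta)
  if (is.null(R)) stop_invalid("'R' is required when 'delta' is an SR function")
  check_ratio(R)
  function(t) sr$value_from_time(R, t)
}

check_interval <- function(t0, t1) {
  if (!is.numeric(t0) || !is.numeric(t1) || length(t0) != 1L || length(t1) != 1L ||
      is.na(t0) || is.na(t1) || t0 < 0 || t0 >= t1)
    stop_invalid("need an interval 0 <= t0 < t1")
  invisible(NULL)
}

#' Linear interpolation of an SR function over an interval
#'
#' The chord through the endpoint values: slope
#' `A = (Delta(t1) - Delta(t0)) / (t1 - t0)` and intercept
#' `B = (t1 Delta(t0) - t0 Delta(t1)) / (t1 - t0)`.
#'
#' @param delta An [sr_function()] (or name), or a plain function of `t`.
#' @param t0,t1 Interval bounds, `0 <= t0 < t1`.
#' @param R Ti-tv ratio, required when `delta` is an SR function.
#' @return A list of class `affine_fit` with fields `a` (slope) and `b`
#'   (intercept).
#' @export
linear_interpolation <- function(delta, t0, t1, R = NULL) {
  check_interval(t0, t1)
  g <- as_time_function(delta, R)
  y0 <- g(t0)
  y1 <- g(t1)
  structure(list(a = (y1 - y0) / (t1 - t0),
                 b = (t1 * y0 - t0 * y1) / (t1 - t0)),
            class = "affine_fit")
}

#' @export
print.affine_fit <- function(x, ...) {
  cat(sprintf("affine fit: a = %g, b = %g\n", x$a, x$b))
  invisible(x)
}

# Maximum of |g(t) - (a t + b)| over [t0, t1]: grid scan plus local
# refinement around the grid extrema.
max_abs_gap <- function(g, a, b, t0, t1, n_grid = 2001L) {
  ts <- seq(t0, t1, length.out = n_grid)
  gap <- g(ts) - a * ts - b
  refine <- function(idx, sign) {
    lo <- ts[max(1L, idx - 1L)]
    hi <- ts[min(n_grid, idx + 1L)]
    if (lo == hi) return(list(value = sign * gap[idx], t = ts[idx]))
    opt <- stats::optimize(function(t) g(t) - a * t - b, c(lo, hi),
                           maximum = sign > 0, tol = 1e-12)
    if (sign > 0) list(value = opt$objective, t = opt$maximum)
    else list(value = -opt$objective, t = opt$minimum)
  }
  up <- refine(which.max(gap), +1)
  dn <- refine(which.min(gap), -1)
  list(psi_max = up$value, t_max = up$t, psi_min = -dn$value, t_min = dn$t)
}

#' Deviation from additivity of an SR function
#'
#' Minimises `(1/a) max_t |Delta(t) - a t - b|` over slopes `a > 0` and
#' intercepts `b` on the interval `[t0, t1]`.  When `Delta` does not cross
#' its linear interpolation inside the interval -- in particular when it is
#' concave or convex, detected by a sign-constant second difference on a
#' 512-point grid -- the minimiser is available in closed form: the optimal
#' slope is the interpolation slope `A`, the optimal intercept is
#' `B + X/2` with `X = max_t |Delta(t) - A t - B|`, and the deviation is
#' `X / (2A)`.  Otherwise a nested numeric minimax is used: for fixed `a`
#' the optimal `b` is the Chebyshev centre of the residuals, and the outer
#' 1-D minimisation of `psi(a)/a` runs over `a` in `[A/10, 10A]` (tolerance
#' 1e-8), with a dense slope scan as a cross-check against non-unimodal
#' behaviour.
#'
#' @inheritParams linear_interpolation
#' @return A list of class `deviation_result`: `fit` (`affine_fit` with the
#'   minimising `a*`, `b*`), `dev` (deviation in time units), `argmax_t`
#'   (location of the maximal gap) and `method`
#'   (`"closed_form"` or `"numeric"`).
#' @examples
#' deviation_from_additivity("jc", 0.8, 2, R = 10)
#' @export
deviation_from_additivity <- function(delta, t0, t1, R = NULL) {
  check_interval(t0, t1)
  g <- as_time_function(delta, R)
  ts <- seq(t0, t1, length.out = 513L)
  vals <- g(ts)
  if (any(!is.finite(vals))) stop_invalid("'delta' must be finite on the interval")
  if (any(diff(vals) <= 0))
    stop_invalid("'delta' must be strictly increasing on the interval")
  fit0 <- linear_interpolation(g, t0, t1)
  A <- fit0$a
  B <- fit0$b
  d2 <- diff(vals, differences = 2L)
  tol <- 1e-10 * max(abs(vals))
  one_sided <- all(d2 <= tol) || all(d2 >= -tol)
  if (one_sided) {
    gp <- max_abs_gap(g, A, B, t0, t1)
    X <- max(gp$psi_max, -gp$psi_min)   # one of the two is ~0
    argmax_t <- if (gp$psi_max >= -gp$psi_min) gp$t_max else gp$t_min
    b_star <- B + (gp$psi_max + gp$psi_min) / 2
    return(structure(list(
      fit = structure(list(a = A, b = b_star), class = "affine_fit"),
      dev = X / (2 * A), argmax_t = argmax_t, method = "closed_form"
    ), class = "deviation_result"))
  }
  # general numeric minimax
  psi <- function(a) {
    gp <- max_abs_gap(g, a, 0, t0, t1)
    list(half_range = (gp$psi_max - gp$psi_min) / 2,
         b = (gp$psi_max + gp$psi_min) / 2,
         t_at = if (gp$psi_max >= -gp$psi_min) gp$t_max else gp$t_min)
  }
  h <- function(a) psi(a)$half_range / a
  opt <- stats::optimize(h, c(A / 10, 10 * A), tol = 1e-8)
  a_grid <- seq(A / 10, 10 * A, length.out = 401L)
  h_grid <- vapply(a_grid, h, numeric(1))
  a_best <- a_grid[which.min(h_grid)]
  if (min(h_grid) < opt$objective) {
    opt2 <- stats::optimize(h, c(max(A / 10, a_best * 0.9), min(10 * A, a_best * 1.1)),
                            tol = 1e-8)
    if (opt2$objective < opt$objective) opt <- opt2
  }
  ps <- psi(opt$minimum)
  structure(list(
    fit = structure(list(a = opt$minimum, b = ps$b), class = "affine_fit"),
    dev = opt$objective, argmax_t = ps$t_at, method = "numeric"
  ), class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  cat(sprintf("deviation from additivity: %g time units (%s)\n", x$dev, x$method))
  cat(sprintf("  best affine fit: a = %g, b = %g; max gap at t = %g\n",
              x$fit$a, x$fit$b, x$argmax_t))
  invisible(x)
}

#' Interpolation-error upper bound on the deviation from additivity
#'
#' For a twice continuously differentiable SR function the deviation from
#' additivity over `[t0, t1]` is bounded by
#' `(t1 - t0)^2 F / (16 A)`, where `A` is the interpolation slope and
#' `F = max_t |Delta''(t)|` on the interval.  For the Jukes-Cantor distance
#' under K2P, `|Delta''|` is evaluated in closed form (its maximiser is
#' `t = ln(2)/rho` if interior to the interval, an endpoint otherwise).
#'
#' @inheritParams linear_interpolation
#' @return The bound, in time units.
#' @export
deviation_bound <- function(delta, t0, t1, R = NULL) {
  check_interval(t0, t1)
  is_jc <- !is.function(delta) && sr_function(delta)$name == "jc"
  g <- as_time_function(delta, R)
  A <- linear_interpolation(g, t0, t1)$a
  if (is_jc) {
    rho <- (2 * R - 1) / (R + 1)
    if (rho == 0) return(0)
    t_star <- log(2) / rho
    cand <- c(t0, t1, if (t_star > t0 && t_star < t1) t_star)
    F <- max(abs(delta_jc_derivative(R, cand, order = 2)))
  } else {
    ts <- seq(t0, t1, length.out = 1025L)
    h <- (t1 - t0) / 1024
    d2 <- abs(diff(g(ts), differences = 2L) / h^2)
    F <- max(d2)
  }
  (t1 - t0)^2 * F / (16 * A)
}

#' Consistency guarantee for a tree and SR function
#'
#' Computes the inter-leaf time range `[t0, t1]` and the minimal edge time
#' `t_min` of a model tree (from its true edge lengths), the deviation from
#' additivity of the SR function over that range, and returns whether the
#' sufficient condition `dev < t_min / 2` for consistent reconstruction by
#' robust distance methods holds.
#'
#' @param tree A `phylo` tree with positive edge times and at least 4 leaves.
#' @param delta An [sr_function()] or name.
#' @param R Ti-tv ratio of the generating homogeneous K2P sub-model.
#' @return A list with `verdict` (`"guaranteed_consistent"` or
#'   `"not_guaranteed"`), `dev`, `t_min`, `t0`, `t1` and the deviation `fit`.
#' @export
consistency_check <- function(tree, delta, R) {
  if (!inherits(tree, "phylo")) stop_invalid("'tree' must be a 'phylo' object")
  if (length(tree$tip.label) < 4L)
    stop_invalid("need at least 4 leaves (no internal edge to resolve)")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop_invalid("'tree' must have positive edge times")
  pt <- ape::cophenetic.phylo(tree)
  times <- pt[lower.tri(pt)]
  t0 <- min(times)
  t1 <- max(times)
  t_min <- min(tree$edge.length)
  res <- deviation_from_additivity(delta, t0, t1, R = R)
  list(
    verdict = if (res$dev < t_min / 2) "guaranteed_consistent" else "not_guaranteed",
    dev = res$dev, t_min = t_min, t0 = t0, t1 = t1, fit = res$fit
  )
}

#' Minimal internal-edge time guaranteeing JC consistency
#'
#' For trees generated under homogeneous K2P sub-models with ti-tv ratio up
#' to `R_max` and inter-leaf times within `[t0, t1]`, returns
#' `2 * dev(Delta_JC(R_max, .), [t0, t1])`: any tree whose internal edges
#' all exceed this threshold is reconstructed consistently with the
#' Jukes-Cantor distance.  The threshold is monotone in `R_max` because the
#' deviation of the JC distance grows with the ti-tv ratio.
#'
#' @param R_max Largest ti-tv ratio of the collection (`>= 1/2`).
#' @param t0,t1 Inter-leaf time range.
#' @return The internal-edge time threshold.
#' @export
consistency_region <- function(R_max, t0, t1) {
  check_ratio(R_max)
  if (R_max == 0.5) return(0)
  2 * deviation_from_additivity("jc", t0, t1, R = R_max)$dev
}
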