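# Reproducible experiment drivers: deviation/noise profiles, quartet series
# (accuracy + Fisher criterion), and tree-scale series (NJ + RF).

#' Deviation and noise profile of the JC distance
#'
#' Tabulates, over a time grid on `[t0, t1]` at ti-tv ratio `R`: the JC
#' distance `Delta_JC(R, t)`, its linear interpolation `Delta_int = A t + B`,
#' the closest affine-additive function `Delta* = Delta_int + X/2` (with `X`
#' the maximal gap to the interpolation), and the one-standard-deviation
#' stochastic margins of `Delta_JC` and `Delta*` at sequence length `k`
#' (`sigma(Delta*) = A sigma(Delta_K2P)`).
#'
#' @param R Ti-tv ratio.
#' @param t0,t1 Interval of inter-leaf times.
#' @param k Sequence length for the noise margins.
#' @param n_grid Number of grid points.
#' @return A data frame with columns `t, jc, interp, star, jc_lo, jc_hi,
#'   star_lo, star_hi`; attributes `A`, `B`, `X`, `dev` carry the fit.
#' @export
run_deviation_profile <- function(R, t0, t1, k = 500, n_grid = 201) {
  check_ratio(R)
  check_interval(t0, t1)
  fit <- linear_interpolation("jc", t0, t1, R = R)
  res <- deviation_from_additivity("jc", t0, t1, R = R)
  X <- res$dev * 2 * fit$a
  ts <- seq(t0, t1, length.out = n_grid)
  jc <- delta_jc_time(R, ts)
  interp <- fit$a * ts + fit$b
  star <- interp + X / 2
  s_jc <- sigma_jc_(R, ts, k)
  s_star <- fit$a * sigma_k2p_(R, ts, k)
  out <- data.frame(t = ts, jc = jc, interp = interp, star = star,
                    jc_lo = jc - s_jc, jc_hi = jc + s_jc,
                    star_lo = star - s_star, star_hi = star + s_star)
  attr(out, "A") <- fit$a
  attr(out, "B") <- fit$b
  attr(out, "X") <- X
  attr(out, "dev") <- res$dev
  out
}

#' Quartet series: accuracy, Fisher criterion, SEP/NOISE
#'
#' Runs a series of type-A/B quartets, varying either the short edge `t_s`
#' (with `t_l` fixed) or the long edge `t_l` (with `t_s` fixed).  Per grid
#' point and SR function it reports the Fisher criterion (12|34 vs 13|24),
#' its SEP and NOISE components, and, when `reps > 0`, the Monte-Carlo
#' four-point accuracy (the simulated replicates are shared across SR
#' functions).
#'
#' @param qtype `"A"` or `"B"`.
#' @param R Ti-tv ratio.
#' @param t_i Internal edge time.
#' @param t_s,t_l Short/long external edge times; exactly one of the two may
#'   be a vector (the grid).
#' @param k Sequence length.
#' @param reps Replicates per grid point (0 skips the simulation).
#' @param srs Character vector of SR names.
#' @param seed Optional base seed (one sub-seed drawn per grid point).
#' @return A data frame with one row per (grid point, SR function):
#'   `t_s, t_l, ratio` (`t_l/t_s`), `sr, fc, sep, noise, accuracy, tie_rate,
#'   n_saturated`.
#' @export
run_quartet_series <- function(qtype = "B", R = 5, t_i = 0.2,
                               t_s = seq(0.2, 1, by = 0.01), t_l = 1.0,
                               k = 1000, reps = 0, srs = c("jc", "k2p"),
                               seed = NULL) {
  if (length(t_s) > 1L && length(t_l) > 1L)
    stop_invalid("only one of 't_s', 't_l' may be a grid")
  if (length(t_s) == 0L || length(t_l) == 0L)
    return(data.frame(t_s = numeric(0), t_l = numeric(0), ratio = numeric(0),
                      sr = character(0), fc = numeric(0), sep = numeric(0),
                      noise = numeric(0), accuracy = numeric(0),
                      tie_rate = numeric(0), n_saturated = numeric(0)))
  grid <- data.frame(t_s = t_s, t_l = t_l)
  sub_seeds <- if (is.null(seed)) rep(list(NULL), nrow(grid))
               else with_seed(seed, as.list(sample.int(.Machine$integer.max, nrow(grid))))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    q <- quartet_model(qtype, t_i = t_i, t_s = grid$t_s[i], t_l = grid$t_l[i], R = R)
    fcs <- lapply(srs, function(s) fisher_criterion(q, s, k))
    acc <- tie <- sat <- rep(NA_real_, length(srs))
    if (reps > 0) {
      sim <- quartet_accuracy_batch(q, as.list(srs), k, reps, seed = sub_seeds[[i]])
      acc <- sim$accuracy
      tie <- sim$tie_rate
      sat <- sim$n_saturated
    }
    data.frame(t_s = grid$t_s[i], t_l = grid$t_l[i],
               ratio = grid$t_l[i] / grid$t_s[i], sr = srs,
               fc = vapply(fcs, `[[`, 0, "fc"),
               sep = vapply(fcs, `[[`, 0, "sep"),
               noise = vapply(fcs, `[[`, 0, "noise"),
               accuracy = as.numeric(acc), tie_rate = as.numeric(tie),
               n_saturated = as.numeric(sat))
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(qtype = qtype, R = R, t_i = t_i, k = k,
                              reps = reps, seed = seed)
  out
}

# Vectorised simulation of `reps` alignments along `tree`; returns per-pair
# mismatch counts (n_pairs x reps matrices) and the pair index.
simulate_tree_counts <- function(tree, R, k, reps) {
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  n <- k * reps
  states <- vector("list", ntip + tree$Nnode)
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  states[[root]] <- sample.int(4L, n, replace = TRUE)
  remaining <- seq_len(nrow(edge))
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) !is.null(states[[edge[i, 1L]]]), logical(1))]
    for (i in ready)
      states[[edge[i, 2L]]] <- evolve_states(states[[edge[i, 1L]]],
                                             tree$edge.length[i], R)
    remaining <- setdiff(remaining, ready)
  }
  pairs <- utils::combn(ntip, 2L)
  np <- ncol(pairs)
  n_ti <- matrix(0, np, reps)
  n_tv <- matrix(0, np, reps)
  for (p in seq_len(np)) {
    a <- states[[pairs[1L, p]]]
    b <- states[[pairs[2L, p]]]
    differ <- a != b
    same_class <- (a <= 2L) == (b <= 2L)
    n_ti[p, ] <- colSums(matrix(differ & same_class, nrow = k))
    n_tv[p, ] <- colSums(matrix(differ & !same_class, nrow = k))
  }
  list(n_ti = n_ti, n_tv = n_tv, pairs = pairs)
}

#' Tree-scale series: NJ reconstruction accuracy across diameters
#'
#' For each target diameter, rescales `tree`, simulates `reps` alignments of
#' `k` sites under the homogeneous K2P sub-model with ti-tv ratio `R`,
#' estimates a distance matrix per SR function (cap policy applied per
#' replicate), reconstructs with neighbor joining, and records the mean
#' normalized Robinson-Foulds distance to the true topology.
#'
#' @param tree A `phylo` model tree (e.g. [caterpillar_tree()]).
#' @param diameters Numeric vector of target diameters.
#' @param R Ti-tv ratio.
#' @param k Sequence length.
#' @param reps Replicates per diameter (shared across SR functions).
#' @param srs Character vector of SR names.
#' @param seed Optional base seed (one sub-seed per diameter).
#' @param chunk Replicates per vectorised simulation block.
#' @return A data frame with one row per (diameter, SR function):
#'   `diameter, sr, mean_nrf, n_saturated, reps`.
#' @export
run_tree_series <- function(tree, diameters, R = 2, k = 500, reps = 100,
                            srs = c("jc", "k2p", "tv"), seed = NULL,
                            chunk = NULL) {
  if (!inherits(tree, "phylo")) stop_invalid("'tree' must be a 'phylo' object")
  ntip <- length(tree$tip.label)
  if (ntip < 4L) stop_invalid("need at least 4 leaves")
  k <- as.integer(k)
  reps <- as.integer(reps)
  if (is.null(chunk)) chunk <- max(1L, min(reps, as.integer(ceiling(2e6 / k))))
  labels <- tree$tip.label
  sr_objs <- lapply(srs, sr_function)
  sub_seeds <- if (is.null(seed)) rep(list(NULL), length(diameters))
               else with_seed(seed, as.list(sample.int(.Machine$integer.max, length(diameters))))
  rows <- lapply(seq_along(diameters), function(si) {
    scaled <- scale_tree_to_diameter(tree, diameters[si])
    true_keys <- tree_splits(scaled)
    max_rf <- 2 * (ntip - 3)
    nrf_sum <- stats::setNames(numeric(length(srs)), srs)
    sat <- nrf_sum
    with_seed(sub_seeds[[si]], {
      done <- 0L
      while (done < reps) {
        m <- min(chunk, reps - done)
        cnt <- simulate_tree_counts(scaled, R, k, m)
        pa <- cnt$n_ti / k
        pb <- cnt$n_tv / (2 * k)
        for (j in seq_along(sr_objs)) {
          Dall <- matrix(sr_dist_vec(sr_objs[[j]], pa, pb), nrow = nrow(pa))
          capped <- apply_cap(Dall)
          sat[j] <- sat[j] + capped$n_saturated
          for (r in seq_len(m)) {
            Dm <- matrix(0, ntip, ntip)
            Dm[t(cnt$pairs)] <- capped$D[, r]
            Dm <- Dm + t(Dm)
            keys <- nj_splits(Dm, labels)
            rf <- length(setdiff(keys, true_keys)) + length(setdiff(true_keys, keys))
            nrf_sum[j] <- nrf_sum[j] + rf / max_rf
          }
        }
        done <- done + m
      }
    })
    data.frame(diameter = diameters[si], sr = srs,
               mean_nrf = as.numeric(nrf_sum) / reps,
               n_saturated = as.numeric(sat), reps = reps)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(R = R, k = k, reps = reps, seed = seed)
  out
}

#' Interpolated zero crossing of a curve
#'
#' Locates the point where `y` changes sign along increasing `x`, by linear
#' interpolation between the bracketing grid points.  When several sign
#' changes exist (as can happen with Monte-Carlo noise), the bracket whose
#' endpoints are farthest from zero -- the most clearly resolved crossing --
#' is used.
#'
#' @param x Increasing numeric vector.
#' @param y Numeric vector of the same length.
#' @return The interpolated crossing location, or `NA` if `y` never changes
#'   sign.
#' @export
find_crossing <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (is.unsorted(x)) {
    o <- order(x)
    x <- x[o]
    y <- y[o]
  }
  s <- sign(y)
  idx <- which(s[-length(s)] * s[-1L] < 0)
  exact <- which(y == 0)
  if (!length(idx)) {
    if (length(exact)) return(x[exact[1L]])
    return(NA_real_)
  }
  if (length(idx) > 1L) {
    strength <- vapply(idx, function(i) min(abs(y[i]), abs(y[i + 1L])), numeric(1))
    idx <- idx[which.max(strength)]
  }
  i <- idx[1L]
  x[i] + (x[i + 1L] - x[i]) * y[i] / (y[i] - y[i + 1L])
}
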