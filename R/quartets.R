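# Quartet analysis: type-A/B quartet models, exact expected distances, the
# four-point method, the Fisher-criterion separability predictor with its
# SEP/NOISE decomposition, and Monte-Carlo quartet accuracy.
#
# Both quartet types have true split (12|34), internal edge time t_i, two
# short external edges t_s and two long ones t_l.  Type A ("Farris zone")
# puts both short edges on one side of the split; type B ("Felsenstein
# zone") puts a short and a long edge on each side.

PAIR_NAMES <- c("12", "13", "14", "23", "24", "34")
SPLITS <- c("12|34", "13|24", "14|23")

#' Quartet model specification
#'
#' @param qtype `"A"` or `"B"`.
#' @param t_i Internal edge time (> 0).
#' @param t_s Short external edge time (> 0).
#' @param t_l Long external edge time (`>= t_s`).
#' @param R Ti-tv ratio of the homogeneous K2P sub-model.
#' @return An object of class `quartet_model`.
#' @examples
#' quartet_model("B", t_i = 0.2, t_s = 0.25, t_l = 1, R = 5)
#' @export
quartet_model <- function(qtype = c("A", "B"), t_i, t_s, t_l, R) {
  qtype <- match.arg(qtype)
  check_ratio(R)
  if (any(c(t_i, t_s, t_l) <= 0)) stop_invalid("all edge times must be positive")
  if (t_s > t_l) stop_invalid("'t_s' must not exceed 't_l'")
  structure(list(qtype = qtype, t_i = t_i, t_s = t_s, t_l = t_l, R = R),
            class = "quartet_model")
}

#' @export
print.quartet_model <- function(x, ...) {
  cat(sprintf("type-%s K2P quartet: t_i = %g, t_s = %g, t_l = %g, R = %g (true split 12|34)\n",
              x$qtype, x$t_i, x$t_s, x$t_l, x$R))
  invisible(x)
}

#' Exact inter-leaf path times of a quartet
#'
#' Type A: `d12 = 2 t_s`, `d34 = 2 t_l`, all cross pairs
#' `t_s + t_i + t_l`.  Type B: `d12 = d34 = t_s + t_l`,
#' `d13 = 2 t_s + t_i`, `d24 = 2 t_l + t_i`, `d14 = d23 = t_s + t_l + t_i`.
#' For both types the additive four-point sums satisfy
#' `(d12 + d34) + 2 t_i = d13 + d24 = d14 + d23`.
#'
#' @param q A [quartet_model()].
#' @return Named numeric vector with entries `12, 13, 14, 23, 24, 34`
#'   (time units).
#' @export
exact_distances <- function(q) {
  stopifnot(inherits(q, "quartet_model"))
  with(q, {
    d <- if (qtype == "A")
      c(2 * t_s, t_s + t_i + t_l, t_s + t_i + t_l,
        t_s + t_i + t_l, t_s + t_i + t_l, 2 * t_l)
    else
      c(t_s + t_l, 2 * t_s + t_i, t_s + t_l + t_i,
        t_s + t_l + t_i, 2 * t_l + t_i, t_s + t_l)
    names(d) <- PAIR_NAMES
    d
  })
}

#' Four-point method split resolution
#'
#' Partitions the six pairwise distances into the three sums
#' `d12 + d34`, `d13 + d24`, `d14 + d23` and returns the split with the
#' strictly minimal sum.  Exact ties are broken uniformly at random (under
#' `tie_seed` when given); tie frequencies are an attribute of the drivers'
#' outputs, not of this function.
#'
#' @param d Named numeric vector with entries `12, 13, 14, 23, 24, 34`, or a
#'   4x4 symmetric matrix.  All six values must be finite: callers are
#'   responsible for applying the saturation cap policy first.
#' @param tie_seed Optional seed used only for tie-breaking.
#' @return One of `"12|34"`, `"13|24"`, `"14|23"`.
#' @export
four_point_method <- function(d, tie_seed = NULL) {
  if (is.matrix(d)) {
    if (!all(dim(d) == c(4L, 4L))) stop_invalid("distance matrix must be 4x4")
    d <- c(d[1, 2], d[1, 3], d[1, 4], d[2, 3], d[2, 4], d[3, 4])
    names(d) <- PAIR_NAMES
  }
  d <- d[PAIR_NAMES]
  if (any(is.na(d)) || any(!is.finite(d)))
    stop_invalid("all six distances must be finite (apply the cap policy first)")
  s <- c(d["12"] + d["34"], d["13"] + d["24"], d["14"] + d["23"])
  winners <- which(s == min(s))
  if (length(winners) == 1L) return(SPLITS[winners])
  with_seed(tie_seed, SPLITS[winners[sample.int(length(winners), 1L)]])
}

split_pairs <- function(split) {
  switch(split,
    "12|34" = c("12", "34"),
    "13|24" = c("13", "24"),
    "14|23" = c("14", "23"),
    stop_invalid("unknown split")
  )
}

#' Fisher criterion for quartet split separability
#'
#' Measures the effective separation between the distance sum of the true
#' split (12|34) and that of a competing split under an SR function:
#' `FC = |mu1 - mu2| / sqrt(sigma1^2 + sigma2^2)`.  The expectation of each
#' sum applies the SR function to the exact path times of its two pairs; the
#' variance of each sum adds the two delta-method variances of the involved
#' distance estimates (correlation between sums induced by shared external
#' edges is deliberately ignored, which is the standard independent
#' approximation).  FC crossings between two SR functions do not depend on
#' `k`, since both noises scale as `1/sqrt(k)`.
#'
#' @param q A [quartet_model()].
#' @param delta An [sr_function()] or name with an analytic `sigma`
#'   (`"jc"`, `"k2p"`, `"tv"`).
#' @param k Sequence length used in the variance approximation.
#' @param alt_split The competing split, `"13|24"` (default) or `"14|23"`.
#' @return A list of class `fc_result`: `sep` (`|mu1 - mu2|`), `noise`
#'   (`sqrt(sigma1^2 + sigma2^2)`), `fc = sep/noise`, `split_pair`, `sr`.
#' @export
fisher_criterion <- function(q, delta, k, alt_split = "13|24") {
  stopifnot(inherits(q, "quartet_model"))
  if (!alt_split %in% SPLITS[-1L])
    stop_invalid("'alt_split' must differ from the true split (12|34)")
  sr <- sr_function(delta)
  if (is.null(sr$sigma))
    stop_invalid(sprintf("no analytic noise model for SR function '%s'", sr$name))
  d <- exact_distances(q)
  p1 <- split_pairs("12|34")
  p2 <- split_pairs(alt_split)
  mu <- function(pp) sum(sr$value_from_time(q$R, d[pp]))
  v <- function(pp) sum(sr$sigma(q$R, d[pp], k)^2)
  sep <- abs(mu(p1) - mu(p2))
  noise <- sqrt(v(p1) + v(p2))
  structure(list(sep = sep, noise = noise, fc = sep / noise,
                 split_pair = c("12|34", alt_split), sr = sr$name),
            class = "fc_result")
}

#' @export
print.fc_result <- function(x, ...) {
  cat(sprintf("Fisher criterion (%s, %s vs %s): FC = %g (SEP = %g, NOISE = %g)\n",
              x$sr, x$split_pair[1], x$split_pair[2], x$fc, x$sep, x$noise))
  invisible(x)
}

#' SEP / NOISE / FC ratios between two SR functions
#'
#' Compares two SR functions on the (12|34) versus (13|24) separation:
#' `FC(D1)/FC(D2) = (SEP(D1)/SEP(D2)) / (NOISE(D1)/NOISE(D2))`, teasing the
#' systematic bias (SEP) apart from the stochastic noise (NOISE).
#'
#' @param q A [quartet_model()].
#' @param delta1,delta2 SR functions (objects or names).
#' @param k Sequence length.
#' @return A list with `sep_ratio`, `noise_ratio`, `fc_ratio`.
#' @export
sep_noise_ratios <- function(q, delta1, delta2, k) {
  f1 <- fisher_criterion(q, delta1, k)
  f2 <- fisher_criterion(q, delta2, k)
  list(sep_ratio = f1$sep / f2$sep,
       noise_ratio = f1$noise / f2$noise,
       fc_ratio = f1$fc / f2$fc)
}

#' Quartet model as a phylo tree
#'
#' Materialises the quartet geometry as an unrooted `phylo` tree with tips
#' `t1 ... t4` (true split `t1,t2 | t3,t4`), e.g. for [consistency_check()]
#' or [simulate_alignment()].
#'
#' @param q A [quartet_model()].
#' @return An unrooted `phylo` tree.
#' @export
quartet_tree <- function(q) {
  stopifnot(inherits(q, "quartet_model"))
  nwk <- if (q$qtype == "A")
    sprintf("((t1:%.12g,t2:%.12g):%.12g,t3:%.12g,t4:%.12g);",
            q$t_s, q$t_s, q$t_i, q$t_l, q$t_l)
  else
    sprintf("((t1:%.12g,t2:%.12g):%.12g,t3:%.12g,t4:%.12g);",
            q$t_s, q$t_l, q$t_i, q$t_s, q$t_l)
  read_newick(nwk)
}

# ---- Monte-Carlo quartet accuracy ---------------------------------------

# Vectorised simulation of `reps` quartet alignments; returns the six
# mismatch-count matrices.  Leaves 1,3 carry the short edges and 2,4 the
# long ones in type B; in type A leaves 1,2 are short and 3,4 long.
simulate_quartet_counts <- function(q, k, reps) {
  n <- k * reps
  A <- sample.int(4L, n, replace = TRUE)
  B <- evolve_states(A, q$t_i, q$R)
  leaves <- if (q$qtype == "A")
    list(evolve_states(A, q$t_s, q$R), evolve_states(A, q$t_s, q$R),
         evolve_states(B, q$t_l, q$R), evolve_states(B, q$t_l, q$R))
  else
    list(evolve_states(A, q$t_s, q$R), evolve_states(A, q$t_l, q$R),
         evolve_states(B, q$t_s, q$R), evolve_states(B, q$t_l, q$R))
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  n_ti <- matrix(0, 6, reps)
  n_tv <- matrix(0, 6, reps)
  for (i in seq_along(pairs)) {
    a <- leaves[[pairs[[i]][1]]]
    b <- leaves[[pairs[[i]][2]]]
    differ <- a != b
    same_class <- (a <= 2L) == (b <= 2L)
    n_ti[i, ] <- colSums(matrix(differ & same_class, nrow = k))
    n_tv[i, ] <- colSums(matrix(differ & !same_class, nrow = k))
  }
  list(n_ti = n_ti, n_tv = n_tv)
}

# Cap policy applied column-wise to a 6 x reps (or m x reps) distance
# matrix: each non-finite entry becomes twice the largest finite distance in
# the same replicate's matrix, or 5.0 if none is finite.
apply_cap <- function(D, cap_default = 5) {
  bad <- !is.finite(D)
  if (!any(bad)) return(list(D = D, n_saturated = 0L))
  tmp <- D
  tmp[bad] <- -Inf
  cm <- do.call(pmax, lapply(seq_len(nrow(D)), function(i) tmp[i, ]))
  cap <- ifelse(is.finite(cm), 2 * cm, cap_default)
  D[bad] <- cap[col(D)[bad]]
  list(D = D, n_saturated = sum(bad))
}

# FPM on the 6 x reps distance matrix; returns per-replicate counts of
# correct resolutions (ties resolved uniformly at random) and tie count.
fpm_batch <- function(D) {
  s1 <- D[1, ] + D[6, ]
  s2 <- D[2, ] + D[5, ]
  s3 <- D[3, ] + D[4, ]
  m23 <- pmin(s2, s3)
  correct <- s1 < m23
  tied <- s1 == m23
  if (any(tied)) {
    idx <- which(tied)
    nmin <- 1L + (s2[idx] == s1[idx]) + (s3[idx] == s1[idx])
    correct[idx] <- stats::runif(length(idx)) < 1 / nmin
  }
  list(n_correct = sum(correct), n_ties = sum(tied))
}

# Shared engine: accuracy of several SR functions on the same simulated
# replicates (the counts are reused across SR functions).
quartet_accuracy_batch <- function(q, srs, k, reps, seed = NULL, chunk = NULL) {
  srs <- lapply(srs, sr_function)
  k <- as.integer(k)
  reps <- as.integer(reps)
  if (is.null(chunk)) chunk <- max(1L, min(reps, as.integer(ceiling(5e6 / k))))
  with_seed(seed, {
    acc <- stats::setNames(numeric(length(srs)), vapply(srs, `[[`, "", "name"))
    ties <- sat <- acc
    done <- 0L
    while (done < reps) {
      m <- min(chunk, reps - done)
      cnt <- simulate_quartet_counts(q, k, m)
      pa <- cnt$n_ti / k
      pb <- cnt$n_tv / (2 * k)
      for (j in seq_along(srs)) {
        D <- matrix(sr_dist_vec(srs[[j]], pa, pb), nrow = 6L)
        capped <- apply_cap(D)
        res <- fpm_batch(capped$D)
        acc[j] <- acc[j] + res$n_correct
        ties[j] <- ties[j] + res$n_ties
        sat[j] <- sat[j] + capped$n_saturated
      }
      done <- done + m
    }
    list(accuracy = acc / reps, tie_rate = ties / reps,
         n_saturated = sat, reps = reps)
  })
}

#' Monte-Carlo quartet reconstruction accuracy
#'
#' Simulates `reps` alignments of `k` sites along the quartet tree, estimates
#' the six pairwise distances with the SR function (saturated entries
#' replaced by the cap policy: twice the largest finite distance in the same
#' replicate, 5.0 if none), resolves each replicate with the four-point
#' method, and returns the fraction recovering the true split (12|34).  Ties
#' are broken uniformly at random and their frequency reported.
#'
#' @param q A [quartet_model()].
#' @param delta An [sr_function()] or name.
#' @param k Sequence length.
#' @param reps Number of replicates (`>= 1`).
#' @param seed Optional seed.
#' @param chunk Number of replicates simulated per vectorised block
#'   (memory/speed trade-off; the default targets ~5e6 sites per block).
#' @return A list with `accuracy`, `tie_rate`, `n_saturated`, `reps`.
#' @export
quartet_accuracy_sim <- function(q, delta, k, reps, seed = NULL, chunk = NULL) {
  stopifnot(inherits(q, "quartet_model"))
  if (reps < 1) stop_invalid("'reps' must be at least 1")
  out <- quartet_accuracy_batch(q, list(delta), k, reps, seed = seed, chunk = chunk)
  list(accuracy = unname(out$accuracy[1L]), tie_rate = unname(out$tie_rate[1L]),
       n_saturated = unname(out$n_saturated[1L]), reps = reps)
}
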