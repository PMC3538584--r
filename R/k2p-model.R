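# Kimura two-parameter (K2P) model: parameterisation, exact transition
# probabilities, and estimation of transition statistics from aligned pairs.
#
# State coding used internally everywhere: A=1, G=2, C=3, T=4, so that states
# 1,2 are purines and 3,4 pyrimidines.  A substitution is transition-type (ti)
# if it stays within a class (A<->G, C<->T) and transversion-type (tv) if it
# crosses classes.

DNA_LEVELS <- c("A", "G", "C", "T")

#' K2P model parameters
#'
#' A point (R, t) of a homogeneous K2P sub-model.  `R = alpha / (2 beta)` is
#' the transition-transversion (ti-tv) ratio and `t` the evolutionary time in
#' expected substitutions per site under the unit rate matrix.  The derived
#' unit rates satisfy `alpha + 2 beta = 1`, i.e. one expected substitution per
#' unit time.
#'
#' @param R Ti-tv ratio, `R >= 1/2`.  `R = 1/2` is the Jukes-Cantor model
#'   (`alpha = beta`).
#' @param t Evolutionary time, `t >= 0`.
#' @return An object of class `k2p_params` with fields `R`, `t`, `alpha`,
#'   `beta`.
#' @examples
#' p <- k2p_params(10, 1.4)
#' p$alpha + 2 * p$beta  # always 1
#' @export
k2p_params <- function(R, t) {
  check_ratio(R)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop_invalid("'t' must be a single non-negative number")
  structure(
    list(R = R, t = t, alpha = R / (R + 1), beta = 1 / (2 * (R + 1))),
    class = "k2p_params"
  )
}

#' @export
print.k2p_params <- function(x, ...) {
  cat(sprintf("K2P parameters: R = %g, t = %g (alpha = %g, beta = %g)\n",
              x$R, x$t, x$alpha, x$beta))
  invisible(x)
}

check_ratio <- function(R) {
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R < 0.5)
    stop_invalid("ti-tv ratio 'R' must be a single number >= 1/2")
  invisible(R)
}

#' Unit rate matrix of a homogeneous K2P sub-model
#'
#' Returns the 4x4 rate matrix with transition rate `alpha = R/(R+1)` on the
#' ti pairs (A<->G, C<->T), transversion rate `beta = 1/(2(R+1))` elsewhere
#' off-diagonal, and rows summing to zero.  The normalisation `alpha + 2 beta
#' = 1` makes `t` the expected number of substitutions per site.
#'
#' @inheritParams k2p_params
#' @return A 4x4 numeric matrix with dimnames `A, G, C, T`.
#' @examples
#' unit_rate_matrix(0.5)  # Jukes-Cantor: all off-diagonals 1/3
#' @export
unit_rate_matrix <- function(R) {
  check_ratio(R)
  alpha <- R / (R + 1)
  beta <- 1 / (2 * (R + 1))
  M <- matrix(beta, 4, 4, dimnames = list(DNA_LEVELS, DNA_LEVELS))
  M["A", "G"] <- M["G", "A"] <- M["C", "T"] <- M["T", "C"] <- alpha
  diag(M) <- -(alpha + 2 * beta)
  M
}

#' Exact K2P transition probabilities
#'
#' Per-site probabilities of observing a transition-type difference
#' (`p_alpha`) and of each transversion-type difference (`p_beta`) after time
#' `t` under the homogeneous K2P sub-model with ti-tv ratio `R`:
#' \deqn{p_\alpha = (1 + e^{-4\beta t} - 2 e^{-2(\alpha+\beta)t})/4, \quad
#'       p_\beta = (1 - e^{-4\beta t})/4.}
#' Note that `p_beta` is the probability of each of the two transversion
#' targets, so the total transversion probability is `2 p_beta`.
#'
#' @param R Ti-tv ratio (`>= 1/2`), or a [k2p_params()] object (then `t` is
#'   ignored).
#' @param t Evolutionary time (`>= 0`).
#' @return A list of class `transition_probs` with fields `p_alpha`, `p_beta`.
#' @examples
#' transition_probs(2, 1)
#' @export
transition_probs <- function(R, t) {
  if (inherits(R, "k2p_params")) {
    t <- R$t
    R <- R$R
  }
  check_ratio(R)
  if (any(t < 0)) stop_invalid("'t' must be non-negative")
  alpha <- R / (R + 1)
  beta <- 1 / (2 * (R + 1))
  structure(
    list(
      p_alpha = (1 + exp(-4 * beta * t) - 2 * exp(-2 * (alpha + beta) * t)) / 4,
      p_beta = (1 - exp(-4 * beta * t)) / 4
    ),
    class = "transition_probs"
  )
}

#' K2P transition matrix after time t
#'
#' The matrix exponential `exp(t * unit_rate_matrix(R))` in closed form.
#'
#' @inheritParams transition_probs
#' @return A 4x4 stochastic matrix (dimnames `A, G, C, T`).
#' @export
k2p_transition_matrix <- function(R, t) {
  pr <- transition_probs(R, t)
  P <- matrix(pr$p_beta, 4, 4, dimnames = list(DNA_LEVELS, DNA_LEVELS))
  P["A", "G"] <- P["G", "A"] <- P["C", "T"] <- P["T", "C"] <- pr$p_alpha
  diag(P) <- 1 - pr$p_alpha - 2 * pr$p_beta
  P
}

#' Invert exact transition probabilities to (alpha t, beta t)
#'
#' Solves the K2P transformations for the rate-time products:
#' \deqn{\alpha t = -\tfrac12 \ln(1 - 2p_\beta - 2p_\alpha)
#'        + \tfrac14 \ln(1 - 4p_\beta), \quad
#'       \beta t = -\tfrac14 \ln(1 - 4p_\beta).}
#' Round-trips with [transition_probs()] so that `alpha_t + 2 beta_t = t`.
#'
#' @param p_alpha Transition-type probability, or a `transition_probs` object
#'   (then `p_beta` is ignored).
#' @param p_beta Per-target transversion-type probability.
#' @return Named numeric vector `c(alpha_t, beta_t)`.
#' @section Errors: signals a saturation error (see [is_saturation_error()])
#'   when either log argument is non-positive, recording which bound failed.
#' @export
invert_transition_probs <- function(p_alpha, p_beta) {
  if (inherits(p_alpha, "transition_probs")) {
    p_beta <- p_alpha$p_beta
    p_alpha <- p_alpha$p_alpha
  }
  w1 <- 1 - 2 * p_beta - 2 * p_alpha
  w2 <- 1 - 4 * p_beta
  if (w1 <= 0)
    stop_saturation("saturated: 1 - 2 p_beta - 2 p_alpha <= 0", which = "ti")
  if (w2 <= 0)
    stop_saturation("saturated: 1 - 4 p_beta <= 0", which = "tv")
  c(alpha_t = -0.5 * log(w1) + 0.25 * log(w2),
    beta_t = -0.25 * log(w2))
}

# ---- sequence coding helpers -------------------------------------------

# Accepts a single string ("ACGT..."), a character vector of single bases,
# or an already-encoded integer vector; returns integer codes 1..4.
dna_to_int <- function(x) {
  if (is.integer(x) || is.numeric(x)) {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 1L) || any(x > 4L))
      stop_invalid("integer-coded sequences must use codes 1..4")
    return(x)
  }
  if (is.character(x)) {
    if (length(x) == 1L && nchar(x) != 1L)
      x <- strsplit(x, "")[[1]]
    codes <- match(toupper(x), DNA_LEVELS)
    if (any(is.na(codes)))
      stop_invalid("sequences must contain only A, C, G, T")
    return(codes)
  }
  stop_invalid("cannot interpret sequence input")
}

int_to_dna <- function(x) paste(DNA_LEVELS[x], collapse = "")

#' Transition/transversion statistics of an aligned sequence pair
#'
#' Counts transition-type (A<->G, C<->T) and transversion-type mismatches
#' between two aligned sequences and returns the empirical K2P statistics
#' `p_alpha_hat = n_ti / k` and `p_beta_hat = n_tv / (2k)`.  The divisor `2k`
#' for transversions matches the per-target parameterisation of
#' [transition_probs()]; many texts instead use the total transversion
#' proportion `Q = 2 p_beta`.
#'
#' @param seq_i,seq_j Aligned sequences of equal length: strings over
#'   `A,C,G,T`, character vectors of bases, or integer codes 1..4.
#' @return A list of class `pair_stats` with fields `p_alpha_hat`,
#'   `p_beta_hat`, `k`, `n_ti`, `n_tv`.
#' @examples
#' estimate_pair_stats("AG", "GC")  # one ti, one tv
#' @export
estimate_pair_stats <- function(seq_i, seq_j) {
  a <- dna_to_int(seq_i)
  b <- dna_to_int(seq_j)
  if (length(a) != length(b)) stop_invalid("sequences must have equal length")
  k <- length(a)
  if (k < 1L) stop_invalid("sequences must contain at least one site")
  differ <- a != b
  same_class <- (a <= 2L) == (b <= 2L)
  n_ti <- sum(differ & same_class)
  n_tv <- sum(differ & !same_class)
  structure(
    list(p_alpha_hat = n_ti / k, p_beta_hat = n_tv / (2 * k),
         k = k, n_ti = n_ti, n_tv = n_tv),
    class = "pair_stats"
  )
}

#' @export
print.pair_stats <- function(x, ...) {
  cat(sprintf("pair stats: p_alpha_hat = %g, p_beta_hat = %g (k = %d, ti = %d, tv = %d)\n",
              x$p_alpha_hat, x$p_beta_hat, x$k, x$n_ti, x$n_tv))
  invisible(x)
}
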