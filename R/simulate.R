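# Site-i.i.d. simulation of the homogeneous K2P substitution process along a
# tree, plus FASTA I/O for the resulting alignments.

# Run `expr` under `set.seed(seed)` while preserving the caller's RNG state.
# seed = NULL means: use (and advance) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Evolve integer-coded states along one edge of time `t` at ti-tv ratio `R`.
# Fully vectorised: one uniform per site, compared against the cumulative
# rows of the K2P transition matrix.
evolve_states <- function(states, t, R) {
  if (t == 0) return(states)
  P <- k2p_transition_matrix(R, t)
  Pc <- P
  for (j in 2:4) Pc[, j] <- Pc[, j - 1] + P[, j]
  u <- stats::runif(length(states))
  1L + (u > Pc[states, 1L]) + (u > Pc[states, 2L]) + (u > Pc[states, 3L])
}

#' Simulate a K2P alignment along a tree
#'
#' Evolves `k` i.i.d. sites along `tree` under the homogeneous K2P sub-model
#' with ti-tv ratio `R`.  The sequence at an arbitrary internal node (the
#' representation root) is drawn uniformly over `A,C,G,T`; each edge then
#' applies the transition matrix `exp(t_e * unit_rate_matrix(R))`
#' independently per site.  Because the model is time-reversible with uniform
#' stationary distribution, the joint law at the leaves does not depend on
#' the root placement.
#'
#' @param tree A `phylo` tree with non-negative edge lengths in time units.
#' @param R Ti-tv ratio (`>= 1/2`).
#' @param k Number of sites (`>= 1`).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return An object of class `devadd_alignment`: a list with `labels`
#'   (leaf names), `states` (`k` x n integer matrix, codes A=1, G=2, C=3,
#'   T=4), `R` and `seed`.
#' @examples
#' tr <- caterpillar_tree(4, 0.1, 0.5)
#' aln <- simulate_alignment(tr, R = 2, k = 100, seed = 1)
#' as.character(aln)
#' @export
simulate_alignment <- function(tree, R, k, seed = NULL) {
  if (!inherits(tree, "phylo")) stop_invalid("'tree' must be a 'phylo' object")
  check_ratio(R)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1)
    stop_invalid("'k' must be a single integer >= 1")
  k <- as.integer(k)
  if (is.null(tree$edge.length)) stop_invalid("'tree' must have edge lengths")
  if (any(tree$edge.length < 0)) stop_invalid("edge lengths must be non-negative")
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  with_seed(seed, {
    states <- vector("list", ntip + tree$Nnode)
    root <- setdiff(edge[, 1L], edge[, 2L])[1L]
    states[[root]] <- sample.int(4L, k, replace = TRUE)
    # process edges parent-before-child
    remaining <- seq_len(nrow(edge))
    while (length(remaining)) {
      ready <- remaining[vapply(remaining, function(i) !is.null(states[[edge[i, 1L]]]), logical(1))]
      for (i in ready)
        states[[edge[i, 2L]]] <- evolve_states(states[[edge[i, 1L]]],
                                               tree$edge.length[i], R)
      remaining <- setdiff(remaining, ready)
    }
    m <- do.call(cbind, states[seq_len(ntip)])
    colnames(m) <- tree$tip.label
    structure(list(labels = tree$tip.label, states = m, R = R, seed = seed),
              class = "devadd_alignment")
  })
}

#' @export
print.devadd_alignment <- function(x, ...) {
  cat(sprintf("K2P alignment: %d sequences, %d sites (R = %g)\n",
              ncol(x$states), nrow(x$states), x$R))
  invisible(x)
}

#' @export
as.character.devadd_alignment <- function(x, ...) {
  out <- apply(x$states, 2L, int_to_dna)
  names(out) <- x$labels
  out
}

#' Write an alignment to FASTA
#'
#' @param aln A `devadd_alignment`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(aln, file) {
  if (!inherits(aln, "devadd_alignment")) stop_invalid("'aln' must be a devadd_alignment")
  m <- t(matrix(tolower(DNA_LEVELS)[aln$states], nrow = nrow(aln$states)))
  rownames(m) <- aln$labels
  ape::write.FASTA(ape::as.DNAbin(m), file)
  invisible(file)
}

#' Read a FASTA alignment
#'
#' Sequences must be equal-length and contain only `A,C,G,T` (any case).
#'
#' @param file Path to a FASTA file.
#' @return A `devadd_alignment` (with `R` and `seed` unset).
#' @export
read_fasta <- function(file) {
  dna <- ape::read.FASTA(file)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop_invalid("all sequences in the alignment must have equal length")
  chars <- as.character(dna)
  m <- vapply(chars, function(s) dna_to_int(toupper(s)), integer(lens[1L]))
  if (is.null(dim(m))) m <- matrix(m, nrow = lens[1L])
  labels <- names(dna)
  if (anyDuplicated(labels)) stop_invalid("sequence labels must be unique")
  colnames(m) <- labels
  structure(list(labels = labels, states = m, R = NA_real_, seed = NULL),
            class = "devadd_alignment")
}
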