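# Tree structures and I/O (Newick via ape), caterpillar fixtures, diameter
# scaling, and alignment-to-distance-matrix estimation.

#' Read / write Newick trees
#'
#' Thin wrappers around the ape Newick parser.  Trees are interpreted as
#' unrooted: a degree-2 root is suppressed on reading.
#'
#' @param x Newick text (containing `(`) or a file path.
#' @return `read_newick`: a `phylo` tree; `write_newick`: the Newick string
#'   (also written to `file` when given).
#' @export
read_newick <- function(x) {
  tree <- tryCatch(
    if (grepl("(", x, fixed = TRUE)) ape::read.tree(text = x)
    else ape::read.tree(file = x),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree)) stop_invalid("malformed Newick input")
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    tree <- ape::unroot(tree)
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` tree.
#' @param file Optional output path.
#' @export
write_newick <- function(tree, file = NULL) {
  if (!inherits(tree, "phylo")) stop_invalid("'tree' must be a 'phylo' object")
  txt <- ape::write.tree(tree)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Caterpillar tree fixture
#'
#' Builds the caterpillar topology (every internal node incident to an
#' external edge) on `n_leaves` leaves, with `n_leaves - 3` internal edges
#' of uniform time `t_int` and `n_leaves` external edges of uniform time
#' `t_ext`.  The leaf-to-leaf diameter is `2 t_ext + (n - 3) t_int`.
#'
#' @param n_leaves Number of leaves (`>= 4`).
#' @param t_int Internal edge time (> 0).
#' @param t_ext External edge time (> 0).
#' @return An unrooted `phylo` tree with tips `t1 ... tn`.
#' @examples
#' caterpillar_tree(7, 0.1, 0.5)  # 4 internal edges
#' @export
caterpillar_tree <- function(n_leaves, t_int, t_ext) {
  if (n_leaves < 4) stop_invalid("a caterpillar needs at least 4 leaves")
  if (t_int <= 0 || t_ext <= 0) stop_invalid("edge times must be positive")
  n <- as.integer(n_leaves)
  s <- sprintf("(t1:%.12g,t2:%.12g)", t_ext, t_ext)
  if (n > 4)
    for (j in 3:(n - 2))
      s <- sprintf("(%s:%.12g,t%d:%.12g)", s, t_int, j, t_ext)
  s <- sprintf("(%s:%.12g,t%d:%.12g,t%d:%.12g);", s, t_int, n - 1, t_ext, n, t_ext)
  read_newick(s)
}

#' Tree diameter
#'
#' The largest leaf-to-leaf path length in edge-time units.
#'
#' @param tree A `phylo` tree with edge lengths.
#' @return The diameter.
#' @export
tree_diameter <- function(tree) {
  if (!inherits(tree, "phylo")) stop_invalid("'tree' must be a 'phylo' object")
  max(ape::cophenetic.phylo(tree))
}

#' Rescale a tree to a target diameter
#'
#' Multiplies all edge lengths by `s / diameter(tree)`, preserving topology.
#'
#' @param tree A `phylo` tree with positive diameter.
#' @param s Target diameter (> 0).
#' @return The rescaled tree.
#' @export
scale_tree_to_diameter <- function(tree, s) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop_invalid("'s' must be a single positive number")
  diam <- tree_diameter(tree)
  if (diam <= 0) stop_invalid("tree has zero diameter")
  tree$edge.length <- tree$edge.length * (s / diam)
  tree
}

#' Pairwise distance matrix of an alignment under an SR function
#'
#' Estimates transition statistics for every pair of sequences with
#' [estimate_pair_stats()] and applies the SR function.  Saturated pairs are
#' flagged; under the default `"cap"` policy they are replaced by twice the
#' largest finite distance in the matrix (5.0 if none is finite), under
#' `"error"` a saturation error is raised.
#'
#' @param aln A `devadd_alignment` (or named character vector of equal-length
#'   sequences).
#' @param delta An [sr_function()] or name; `"logdet"` is also accepted and
#'   uses the pairwise joint count matrices via [delta_logdet()].
#' @param cap_policy `"cap"` (default) or `"error"`.
#' @return A symmetric numeric matrix with a logical attribute `"saturated"`
#'   marking capped entries and `"n_saturated"` with their count.
#' @export
distance_matrix <- function(aln, delta, cap_policy = c("cap", "error")) {
  cap_policy <- match.arg(cap_policy)
  if (is.character(aln)) {
    labels <- names(aln)
    if (is.null(labels)) labels <- paste0("s", seq_along(aln))
    states <- vapply(aln, dna_to_int, integer(nchar(aln[[1L]])))
    aln <- structure(list(labels = labels, states = states, R = NA_real_, seed = NULL),
                     class = "devadd_alignment")
  }
  if (!inherits(aln, "devadd_alignment")) stop_invalid("'aln' must be an alignment")
  n <- ncol(aln$states)
  if (n < 2L) stop_invalid("need at least two sequences")
  logdet <- is.character(delta) && length(delta) == 1L && identical(delta, "logdet")
  sr <- if (!logdet) sr_function(delta)
  D <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      val <- if (logdet) {
        cnt <- table(factor(aln$states[, i], levels = 1:4),
                     factor(aln$states[, j], levels = 1:4))
        tryCatch(delta_logdet(unclass(cnt)), devadd_saturation_error = function(e) NaN)
      } else {
        st <- estimate_pair_stats(aln$states[, i], aln$states[, j])
        sr_dist_vec(sr, st$p_alpha_hat, st$p_beta_hat)
      }
      D[i, j] <- D[j, i] <- val
    }
  }
  saturated <- !is.finite(D) & upper.tri(D) | !is.finite(D) & lower.tri(D)
  if (any(saturated)) {
    if (cap_policy == "error")
      stop_saturation(sprintf("%d saturated pairwise distances", sum(saturated) / 2))
    finite_max <- suppressWarnings(max(D[is.finite(D) & D > 0], 0))
    cap <- if (finite_max > 0) 2 * finite_max else 5
    D[!is.finite(D)] <- cap
  }
  attr(D, "saturated") <- saturated
  attr(D, "n_saturated") <- sum(saturated) / 2
  D
}
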