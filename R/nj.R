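# Neighbor joining and Robinson-Foulds evaluation.
#
# NJ is implemented in-repo so its contracts (affine invariance of the
# reconstructed topology, smallest-index tie-breaking) are testable, and so
# the experiment drivers can share one join engine between the phylo builder
# and a fast splits-only path.

# Core NJ agglomeration.  `d` is a symmetric numeric matrix (diag 0).
# Returns the edge list with internal nodes numbered n+1 .. 2n-2 in creation
# order (the last one is the trifurcating root of the unrooted tree) and the
# tip set under each created internal node.
nj_engine <- function(d) {
  n <- nrow(d)
  act <- seq_len(n)
  tips <- as.list(seq_len(n))
  E <- matrix(0, 2 * n - 3L, 3L)
  ei <- 0L
  nxt <- n
  tipsets <- vector("list", n - 2L)
  while (length(act) > 3L) {
    m <- length(act)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- arrayInd(which.min(Q), dim(Q))  # first minimum column-major:
    i <- min(ij)                          # smallest-index tie-break
    j <- max(ij)
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    nxt <- nxt + 1L
    E[ei + 1L, ] <- c(nxt, act[i], vi)
    E[ei + 2L, ] <- c(nxt, act[j], vj)
    ei <- ei + 2L
    newset <- c(tips[[i]], tips[[j]])
    tipsets[[nxt - n]] <- newset
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    act <- c(act[keep], nxt)
    tips <- c(tips[keep], list(newset))
  }
  nxt <- nxt + 1L
  v <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
         (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
         (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  for (q in 1:3) {
    E[ei + q, ] <- c(nxt, act[q], v[q])
  }
  tipsets[[nxt - n]] <- seq_len(n)
  list(edges = E, n = n, root = nxt, tipsets = tipsets)
}

#' Neighbor joining
#'
#' Classic NJ agglomeration: at each step the pair minimising the Q
#' criterion `(m-2) d_ij - r_i - r_j` is joined, with the standard
#' branch-length and distance updates.  Ties are broken deterministically by
#' the smallest linear index.  Negative branch lengths are retained in the
#' output (evaluation downstream is topology-only).  The reconstructed
#' topology is invariant to affine transformations `a D + b` (`a > 0`, `b`
#' added to off-diagonal entries) of the input.
#'
#' @param D Symmetric numeric matrix of pairwise distances with at least 4
#'   rows; dimnames, if present, become tip labels.  All entries must be
#'   finite.
#' @return An unrooted binary `phylo` tree.
#' @examples
#' tr <- caterpillar_tree(5, 0.2, 0.6)
#' D <- ape::cophenetic.phylo(tr)
#' rf_distance(neighbor_joining(D), tr)  # 0: NJ is consistent on additive input
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop_invalid("'D' must be a square matrix")
  n <- nrow(D)
  if (n < 4L) stop_invalid("need at least 4 leaves")
  if (any(!is.finite(D))) stop_invalid("all distances must be finite")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  eng <- nj_engine(D)
  # renumber internal nodes so the root becomes n+1 (ape convention);
  # creation order reversed keeps parents numbered below their children
  renum <- function(v) ifelse(v > n, 3L * n - 1L - v, v)
  edge <- cbind(renum(eng$edges[, 1L]), renum(eng$edges[, 2L]))
  tree <- list(edge = edge, edge.length = eng$edges[, 3L],
               tip.label = labels, Nnode = n - 2L)
  class(tree) <- "phylo"
  tree
}

# Canonical key of one side of a split: the side containing the reference
# (lexicographically smallest) label, sorted and collapsed.
canon_split <- function(side_labels, all_labels) {
  ref <- min(all_labels)
  side <- if (ref %in% side_labels) side_labels
          else setdiff(all_labels, side_labels)
  paste(sort(side), collapse = "\r")
}

# All nontrivial bipartitions of a phylo tree as canonical keys.
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  ch <- split(edge[, 2L], edge[, 1L])
  desc <- vector("list", n + tree$Nnode)
  get_desc <- function(v) {
    if (v <= n) return(v)
    if (!is.null(desc[[v]])) return(desc[[v]])
    out <- sort(unlist(lapply(ch[[as.character(v)]], get_desc), use.names = FALSE))
    desc[[v]] <<- out
    out
  }
  keys <- character(0)
  internal_children <- edge[edge[, 2L] > n, 2L]
  for (v in internal_children) {
    dset <- get_desc(v)
    sz <- length(dset)
    if (sz >= 2L && sz <= n - 2L)
      keys <- c(keys, canon_split(tree$tip.label[dset], tree$tip.label))
  }
  unique(keys)
}

# Fast path used by the tree-series driver: splits of the NJ tree straight
# from the join engine, skipping phylo construction.
nj_splits <- function(D, labels) {
  n <- nrow(D)
  eng <- nj_engine(D)
  keys <- character(0)
  for (s in eng$tipsets) {
    sz <- length(s)
    if (sz >= 2L && sz <= n - 2L)
      keys <- c(keys, canon_split(labels[s], labels))
  }
  unique(keys)
}

#' Robinson-Foulds distance between unrooted trees
#'
#' The size of the symmetric difference of the two trees' nontrivial
#' bipartition sets.  `normalized_rf` divides by the maximum `2 (n - 3)`
#' (twice the number of internal edges of a binary tree), giving a value in
#' `[0, 1]`.  Branch lengths are ignored.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return `rf_distance`: a non-negative integer count;
#'   `normalized_rf`: a fraction in `[0, 1]`.
#' @export
rf_distance <- function(t1, t2) {
  if (!inherits(t1, "phylo") || !inherits(t2, "phylo"))
    stop_invalid("both arguments must be 'phylo' trees")
  if (!setequal(t1$tip.label, t2$tip.label))
    stop_invalid("trees must share the same leaf set")
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' @rdname rf_distance
#' @export
normalized_rf <- function(t1, t2) {
  n <- length(t1$tip.label)
  if (n < 4L) stop_invalid("need at least 4 leaves")
  rf_distance(t1, t2) / (2 * (n - 3))
}
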