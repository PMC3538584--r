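test_that("Newick round trip preserves topology and branch lengths", {
  tr <- read_newick("((a:1,b:1):0.5,c:1,d:1);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("a", "b", "c", "d"))
  expect_equal(sort(tr$edge.length), sort(c(1, 1, 0.5, 1, 1)))
  back <- read_newick(write_newick(tr))
  expect_equal(rf_distance(tr, back), 0)
  expect_equal(tree_diameter(back), tree_diameter(tr), tolerance = 1e-12)
  cat7 <- caterpillar_tree(7, 0.1, 0.5)
  expect_equal(rf_distance(read_newick(write_newick(cat7)), cat7), 0)
  expect_error(read_newick("((a:1,b:1"), class = "devadd_invalid_input")
})

test_that("caterpillar trees have the stated edge counts and diameter", {
  tr <- caterpillar_tree(7, 0.1, 0.5)
  expect_equal(length(tr$tip.label), 7)
  expect_equal(sum(abs(tr$edge.length - 0.1) < 1e-12), 4)  # n - 3 internal edges
  expect_equal(sum(abs(tr$edge.length - 0.5) < 1e-12), 7)  # n external edges
  expect_equal(tree_diameter(tr), 2 * 0.5 + 4 * 0.1, tolerance = 1e-12)
  q <- caterpillar_tree(4, 0.2, 0.3)
  expect_equal(length(q$tip.label), 4)
  expect_equal(sum(abs(q$edge.length - 0.2) < 1e-12), 1)
  expect_error(caterpillar_tree(3, 0.1, 0.5), class = "devadd_invalid_input")
})

test_that("diameter rescaling is exact, linear, and topology-preserving", {
  tr <- caterpillar_tree(6, 0.15, 0.4)
  s1 <- scale_tree_to_diameter(tr, 1.7)
  expect_equal(tree_diameter(s1), 1.7, tolerance = 1e-12)
  expect_equal(tree_diameter(scale_tree_to_diameter(s1, tree_diameter(tr))),
               tree_diameter(tr), tolerance = 1e-12)
  expect_equal(rf_distance(s1, tr), 0)
  s2 <- scale_tree_to_diameter(scale_tree_to_diameter(tr, 2), 0.5)
  expect_equal(s2$edge.length, scale_tree_to_diameter(tr, 0.5)$edge.length,
               tolerance = 1e-12)
})

test_that("distance matrices are symmetric, zero for identical sequences, and consistent", {
  aln <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  D <- distance_matrix(aln, "k2p")
  expect_true(all(D == 0))
  tr <- caterpillar_tree(5, 0.2, 0.5)
  sim <- simulate_alignment(tr, R = 2, k = 1e5, seed = 13)
  Dk <- distance_matrix(sim, "k2p")
  expect_equal(Dk, t(Dk))
  true_times <- ape::cophenetic.phylo(tr)[rownames(Dk), colnames(Dk)]
  off <- upper.tri(Dk)
  expect_equal(Dk[off], true_times[off], tolerance = 0.05)
  expect_identical(attr(Dk, "n_saturated"), 0)
  # logdet route runs and is near the K2P distance under K2P data
  Dl <- distance_matrix(sim, "logdet")
  expect_equal(Dl[off], true_times[off], tolerance = 0.1)
})

test_that("saturated pairs follow the cap policy or raise a typed error", {
  # force transversion saturation: complementary purine/pyrimidine strings
  aln <- c(a = "AAAACCCC", b = "CCCCAAAA", c = "AAAACCCA")
  expect_error(distance_matrix(aln, "tv", cap_policy = "error"),
               class = "devadd_saturation_error")
  D <- distance_matrix(aln, "tv", cap_policy = "cap")
  expect_gt(attr(D, "n_saturated"), 0)
  expect_true(all(is.finite(D)))
  finite_orig <- D[!attr(D, "saturated") & upper.tri(D)]
  expect_equal(max(D), 2 * max(finite_orig))
})

test_that("neighbor joining recovers additive inputs and matches ape's NJ", {
  set.seed(17)
  for (i in 1:8) {
    tr <- random_tree(sample(5:9, 1))
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    expect_equal(rf_distance(nj, tr), 0)
    # branch lengths of the additive input are recovered too
    expect_equal(max(abs(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)] - D)),
                 0, tolerance = 1e-8)
    # independent implementation cross-check on noisy input
    Dn <- D + matrix(runif(length(D), 0, 0.01), nrow(D))
    Dn <- (Dn + t(Dn)) / 2
    diag(Dn) <- 0
    expect_equal(rf_distance(neighbor_joining(Dn), ape::nj(Dn)), 0)
  }
})

test_that("NJ topology is invariant to affine transformations of the distances", {
  set.seed(23)
  for (i in 1:10) {
    tr <- random_tree(7)
    D <- ape::cophenetic.phylo(tr)
    D <- D + matrix(runif(length(D), 0, 0.05), nrow(D))
    D <- (D + t(D)) / 2
    diag(D) <- 0
    a <- runif(1, 0.1, 5)
    b <- runif(1, -0.1, 2)
    D2 <- a * D + b
    diag(D2) <- 0
    expect_equal(rf_distance(neighbor_joining(D), neighbor_joining(D2)), 0)
  }
})

test_that("NJ recovers the topology under perturbations below the half-minimal-edge radius", {
  set.seed(29)
  tr <- caterpillar_tree(7, 0.2, 0.5)
  D <- ape::cophenetic.phylo(tr)
  for (i in 1:10) {
    E <- matrix(runif(length(D), -1, 1), nrow(D))
    E <- (E + t(E)) / 2
    diag(E) <- 0
    Dp <- D + E * (0.2 / 2) * 0.95 / max(abs(E))
    expect_equal(rf_distance(neighbor_joining(Dp), tr), 0)
  }
})

test_that("RF distance agrees with phangorn and behaves like a metric", {
  skip_if_not_installed("phangorn")
  set.seed(37)
  trees <- replicate(6, random_tree(8), simplify = FALSE)
  for (i in 1:5) {
    rf_mine <- rf_distance(trees[[i]], trees[[i + 1]])
    rf_ref <- phangorn::RF.dist(trees[[i]], trees[[i + 1]])
    expect_equal(rf_mine, rf_ref)
    expect_equal(rf_distance(trees[[i]], trees[[i]]), 0)
    expect_equal(rf_mine, rf_distance(trees[[i + 1]], trees[[i]]))
  }
  # triangle inequality spot checks
  for (i in 1:4)
    expect_lte(rf_distance(trees[[i]], trees[[i + 2]]),
               rf_distance(trees[[i]], trees[[i + 1]]) +
                 rf_distance(trees[[i + 1]], trees[[i + 2]]))
  t1 <- caterpillar_tree(5, 0.1, 0.3)
  t2 <- caterpillar_tree(6, 0.1, 0.3)
  expect_error(rf_distance(t1, t2), class = "devadd_invalid_input")
})

test_that("normalized RF lies in [0, 1] and the splits fast path matches the phylo path", {
  set.seed(41)
  for (i in 1:6) {
    tr1 <- random_tree(7)
    tr2 <- random_tree(7)
    nrf <- normalized_rf(tr1, tr2)
    expect_gte(nrf, 0)
    expect_lte(nrf, 1)
    D <- ape::cophenetic.phylo(tr1)
    keys_fast <- devadd:::nj_splits(D, rownames(D))
    keys_slow <- devadd:::tree_splits(neighbor_joining(D))
    expect_setequal(keys_fast, keys_slow)
  }
})
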