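test_that("unit rate matrix has K2P structure and matches the JC special case", {
  M <- unit_rate_matrix(10)
  expect_equal(M["A", "G"], 10 / 11)
  expect_equal(M["C", "T"], 10 / 11)
  expect_equal(M["A", "C"], 1 / 22)
  expect_equal(unname(rowSums(M)), rep(0, 4))
  # alpha + 2 beta = 1 puts one expected substitution per unit time
  expect_equal(M["A", "G"] + 2 * M["A", "C"], 1)
  expect_true(all(unit_rate_matrix(0.5)[upper.tri(diag(4))] == 1 / 3))
  expect_error(unit_rate_matrix(0.3), class = "devadd_invalid_input")
})

test_that("transition probabilities agree with the matrix-exponential oracle", {
  for (R in c(0.5, 1, 2, 5, 10, 20)) {
    for (t in c(0.1, 0.7, 1.5, 3)) {
      P <- expm_oracle(t * unit_rate_matrix(R))
      pr <- transition_probs(R, t)
      expect_equal(P["A", "G"], pr$p_alpha, tolerance = 1e-10)
      expect_equal(P["A", "C"], pr$p_beta, tolerance = 1e-10)
      expect_equal(P["A", "T"], pr$p_beta, tolerance = 1e-10)
      expect_equal(max(abs(P - k2p_transition_matrix(R, t))), 0, tolerance = 1e-10)
      expect_true(all(abs(rowSums(P) - 1) < 1e-12))
    }
  }
  expect_equal(transition_probs(3, 0)$p_alpha, 0)
  expect_equal(transition_probs(3, 0)$p_beta, 0)
  pr <- transition_probs(0.5, 1.3)
  expect_equal(pr$p_alpha, pr$p_beta)  # JC symmetry
})

test_that("transition probabilities increase toward the (1/4, 1/4) limit", {
  ts <- seq(0.01, 5, length.out = 200)
  for (R in c(0.5, 2, 10)) {
    pr <- transition_probs(R, ts)
    # p_beta and the total mismatch probability grow strictly with t;
    # p_alpha itself overshoots 1/4 and relaxes back for large R, so only
    # its saturation bound is monotone
    expect_true(all(diff(pr$p_beta) > 0))
    expect_true(all(diff(pr$p_alpha + 2 * pr$p_beta) > 0))
    expect_true(all(pr$p_alpha + 2 * pr$p_beta < 0.75))
    expect_true(all(pr$p_beta < 0.25))
  }
  pr <- transition_probs(4, 500)
  expect_equal(pr$p_alpha, 0.25, tolerance = 1e-6)
  expect_equal(pr$p_beta, 0.25, tolerance = 1e-6)
})

test_that("invert_transition_probs round-trips and recovers t = alpha t + 2 beta t", {
  for (R in c(0.5, 1, 2, 5, 10, 20)) {
    for (t in c(0.05, 0.5, 1.2, 2.5, 5)) {
      ab <- invert_transition_probs(transition_probs(R, t))
      expect_equal(unname(ab["alpha_t"] + 2 * ab["beta_t"]), t, tolerance = 1e-10)
      expect_equal(unname(ab["alpha_t"]), R / (R + 1) * t, tolerance = 1e-10)
    }
  }
  expect_equal(unname(invert_transition_probs(0, 0)), c(0, 0))
  err <- tryCatch(invert_transition_probs(0.1, 0.25), error = identity)
  expect_true(is_saturation_error(err))
  expect_equal(err$which, "tv")
})

test_that("pair statistics count ti and tv mismatches with the 2k transversion divisor", {
  st <- estimate_pair_stats("AAAA", "AAAA")
  expect_equal(c(st$p_alpha_hat, st$p_beta_hat, st$k), c(0, 0, 4))
  st <- estimate_pair_stats("AG", "GC")
  expect_equal(st$p_alpha_hat, 1 / 2)   # A<->G is a transition
  expect_equal(st$p_beta_hat, 1 / 4)    # G<->C transversion, divisor 2k
  st <- estimate_pair_stats("ACGT", "GCAT")
  expect_equal(st$p_alpha_hat, 2 / 4)
  expect_equal(st$p_beta_hat, 0)
  expect_error(estimate_pair_stats("ACG", "AC"), class = "devadd_invalid_input")
  expect_error(estimate_pair_stats("ACN", "ACG"), class = "devadd_invalid_input")
})

test_that("simulated alignments are deterministic under a seed and degenerate at t = 0", {
  tr <- caterpillar_tree(5, 0.2, 0.6)
  a1 <- simulate_alignment(tr, R = 2, k = 200, seed = 42)
  a2 <- simulate_alignment(tr, R = 2, k = 200, seed = 42)
  expect_identical(a1$states, a2$states)
  tr0 <- tr
  tr0$edge.length[] <- 0
  a0 <- simulate_alignment(tr0, R = 2, k = 50, seed = 7)
  expect_true(all(a0$states == a0$states[, 1]))
  expect_error(simulate_alignment(tr, R = 2, k = 0), class = "devadd_invalid_input")
})

test_that("simulated mismatch frequencies match the exact model probabilities", {
  # two leaves at total separation t: binomial check at the 4-sigma level
  t_tot <- 0.8
  R <- 2
  k <- 1e5
  tr <- read_newick(sprintf("(a:%g,b:%g);", t_tot / 2, t_tot / 2))
  aln <- simulate_alignment(tr, R = R, k = k, seed = 11)
  st <- estimate_pair_stats(aln$states[, 1], aln$states[, 2])
  pr <- transition_probs(R, t_tot)
  se_a <- sqrt(pr$p_alpha * (1 - pr$p_alpha) / k)
  se_b <- sqrt(2 * pr$p_beta * (1 - 2 * pr$p_beta) / k) / 2
  expect_lt(abs(st$p_alpha_hat - pr$p_alpha), 4 * se_a)
  expect_lt(abs(st$p_beta_hat - pr$p_beta), 4 * se_b)
})

test_that("leaf joint law is invariant to the simulation root placement", {
  # time-reversibility with uniform stationary distribution: re-rooting the
  # same unrooted tree must leave pairwise mismatch statistics unchanged
  nwk <- "((a:0.3,b:0.5):0.2,c:0.4,d:0.6);"
  tr1 <- read_newick(nwk)
  tr2 <- ape::unroot(ape::root(ape::read.tree(text = nwk), outgroup = "d", resolve.root = TRUE))
  k <- 5e4
  a1 <- simulate_alignment(tr1, R = 3, k = k, seed = 5)
  a2 <- simulate_alignment(tr2, R = 3, k = k, seed = 6)
  for (pair in list(c("a", "b"), c("a", "d"), c("c", "d"))) {
    s1 <- estimate_pair_stats(a1$states[, pair[1]], a1$states[, pair[2]])
    s2 <- estimate_pair_stats(a2$states[, pair[1]], a2$states[, pair[2]])
    p <- s1$p_alpha_hat + 2 * s1$p_beta_hat
    se <- sqrt(p * (1 - p) / k)
    expect_lt(abs((s2$p_alpha_hat + 2 * s2$p_beta_hat) - p), 6 * se + 1e-12)
  }
})

test_that("FASTA round trip preserves the alignment", {
  tr <- caterpillar_tree(4, 0.1, 0.4)
  aln <- simulate_alignment(tr, R = 2, k = 120, seed = 3)
  f <- tempfile(fileext = ".fasta")
  write_fasta(aln, f)
  back <- read_fasta(f)
  expect_identical(unname(as.character(back)), unname(as.character(aln)))
  expect_identical(back$labels, aln$labels)
  unlink(f)
})
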