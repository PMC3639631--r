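test_that("generators are reproducible under a fixed seed", {
  expect_identical(gen_iid_sequence(500, seed = 1), gen_iid_sequence(500, seed = 1))
  P <- matrix(0.25, 4, 4)
  expect_identical(gen_markov_sequence(500, P, seed = 2), gen_markov_sequence(500, P, seed = 2))
  expect_identical(gen_fbm_series(500, 0.7, seed = 3), gen_fbm_series(500, 0.7, seed = 3))
  expect_identical(
    gen_expression_table(c(g = 1), n_regions = 10, seed = 4),
    gen_expression_table(c(g = 1), n_regions = 10, seed = 4)
  )
  # and the caller's RNG stream is not consumed
  withr::with_seed(99, {
    a <- runif(1)
  })
  withr::with_seed(99, {
    invisible(gen_iid_sequence(100, seed = 5))
    b <- runif(1)
  })
  expect_identical(a, b)
})

test_that("i.i.d. generator honors base probabilities", {
  expect_equal(gen_iid_sequence(6, probs = c(A = 1, C = 0, G = 0, T = 0), seed = 1), "AAAAAA")
  expect_error(gen_iid_sequence(10, probs = c(0.5, 0.5, 0.5, -0.5)), "probs")
  expect_error(gen_iid_sequence(10, probs = c(0.3, 0.3, 0.3, 0.3)), "probs")
  s <- gen_iid_sequence(100000, seed = 6)
  expect_equal(mono_entropy(s), 2, tolerance = 0.01)
})

test_that("Markov chains reproduce their stationary pair distribution", {
  # uniform rows reduce to i.i.d.: dinucleotide entropy near the maximum
  s <- gen_markov_sequence(100000, matrix(0.25, 4, 4), seed = 7)
  expect_equal(di_entropy(s), 4, tolerance = 0.02)
  # deterministic cycle A->C->G->T->A: 4 equiprobable pairs = 2 bits exactly
  P <- matrix(0, 4, 4)
  P[cbind(1:4, c(2, 3, 4, 1))] <- 1
  s <- gen_markov_sequence(4001, P, seed = 8)
  expect_equal(di_entropy(s), 2)
  # empirical pair frequencies track pi_i * P_ij for a random chain
  withr::with_seed(9, {
    Q <- matrix(rgamma(16, 2), 4, 4)
    Q <- Q / rowSums(Q)
  })
  s <- gen_markov_sequence(200000, Q, seed = 10)
  counts <- entropy_counts(s)$di
  pi0 <- fractalseq:::stationary_distribution(Q)
  expected <- as.vector(outer(seq_len(4), seq_len(4), function(i, j) pi0[i] * Q[cbind(i, j)]))
  names(expected) <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  expect_equal(counts / sum(counts), expected[sort(names(expected))][names(counts)],
    tolerance = 0.02, ignore_attr = TRUE
  )
  # persistent chains suppress dinucleotide entropy
  sticky <- fractalseq:::sticky_transition_matrix(0.9)
  expect_lt(di_entropy(gen_markov_sequence(20000, sticky, seed = 11)), 3)
  expect_error(gen_markov_sequence(10, matrix(1, 4, 4)), "row-stochastic")
})

test_that("fractional Brownian motion has the exact increment structure", {
  x <- gen_fbm_series(20000, 0.5, seed = 12)
  inc <- diff(x)
  expect_lt(abs(cor(inc[-1], inc[-length(inc)])), 0.03) # H = 1/2: uncorrelated
  # variance of lag-k increments scales as k^{2H}
  x <- gen_fbm_series(20000, 0.7, seed = 13)
  for (k in c(1, 4, 16)) {
    expect_equal(var(diff(x, lag = k)), k^1.4, tolerance = 0.1)
  }
  expect_error(gen_fbm_series(100, 0), "inside")
  expect_error(gen_fbm_series(100, 1.2), "inside")
})

test_that("the Higuchi estimator recovers 2 - H on synthetic fBm", {
  fds <- vapply(1:5, function(s) higuchi_fd(gen_fbm_series(5000, 0.8, seed = s))$fd, numeric(1))
  expect_equal(mean(fds), 1.2, tolerance = 0.1)
})

test_that("pair panels achieve their planted fractal dimensions", {
  panel <- tiny_panel(seed = 14)
  expect_equal(nrow(panel), 4)
  expect_true(all(abs(panel$fd_mrna_achieved - panel$fd_mrna_target) <= 0.003))
  expect_true(all(abs(panel$fd_cds_achieved - panel$fd_cds_target) <= 0.003))
  # CDS sits at its declared coordinates and the remainder is consistent
  expect_equal(substr(panel$mrna, panel$cds_start, panel$cds_end), panel$cds)
  expect_equal(nchar(panel$mrna), nchar(panel$cds) + nchar(panel$noncoding))
  # delta signs follow the planted groups
  delta <- panel$fd_cds_achieved - panel$fd_mrna_achieved
  expect_true(all(delta[panel$planted_group == "collinear"] > 0))
  expect_true(all(delta[panel$planted_group == "offline"] < 0))
})

test_that("a single-pair panel is valid but refuses downstream regression", {
  panel <- gen_pair_panel(
    n_pairs = 1, n_negative = 0, mrna_length = 1000,
    fd_mrna_range = c(2.04, 2.05), seed = 15
  )
  expect_equal(nrow(panel), 1)
  rows <- compare_fd(panel)
  expect_error(fd_vs_ratio(rows), "at least 3")
})

test_that("unattainable planted fractal dimensions error, naming the offender", {
  expect_error(
    gen_pair_panel(
      n_pairs = 1, n_negative = 0, mrna_length = 600,
      fd_mrna_range = c(3, 3), seed = 16
    ),
    "unattainable.*gene01"
  )
})

test_that("expression tables hit their planted skewness", {
  tbl <- gen_expression_table(c(flat = 0), n_regions = 168, n_subjects = 4, seed = 17)
  expect_equal(nrow(tbl), 672)
  expect_lt(abs(skewness(tbl$value)$skewness), 0.2)
  # lognormal vs normal gene: ranking is correct in the typical draw
  tbl2 <- gen_expression_table(c(heavy = 2.2, flat = 0), n_regions = 168, seed = 18)
  sk <- expression_skewness(tbl2)
  expect_equal(sk$gene[sk$rank == 1], "heavy")
  # per-gene z-scoring
  means <- tapply(tbl2$value, tbl2$gene, mean)
  expect_equal(as.numeric(means), c(0, 0), tolerance = 1e-12)
  expect_error(gen_expression_table(c(g = 1), n_regions = 2), "at least 3")
  expect_error(gen_expression_table(c(g = NaN)), "finite")
  expect_error(gen_expression_table(c(1, 2)), "named")
})
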