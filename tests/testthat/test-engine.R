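test_that("boundary queries follow the occurrence-count conventions", {
  p <- example_pattern()
  mod <- uniform_dna()
  expect_identical(pattern_pvalue(p, mod, 20, 0)$p_value, 1)
  expect_identical(pattern_pvalue(p, mod, 5, 1)$p_value, 0)
  expect_identical(pattern_pvalue(p, mod, 6, 3)$p_value, 0)
  # at N = m only a single occurrence is possible: Prob(H)
  expect_equal(pattern_pvalue(p, mod, 7, 1)$p_value, 4 * 4^-7)
  expect_identical(pattern_pvalue(p, mod, 7, 2)$p_value, 0)
  expect_error(pattern_pvalue(p, mod, 0, 1), "N must be")
  expect_error(pattern_pvalue(p, mod, 10, -1), "S must be")
})

test_that("tiny instances match hand enumeration", {
  p <- pattern_words("aa", ab2)
  mod <- bernoulli_hmm(c(0.5, 0.5), ab2)
  expect_equal(pattern_pvalue(p, mod, 3, 1)$p_value, 3 / 8)
  expect_equal(pattern_pvalue(p, mod, 3, 2)$p_value, 1 / 8)
  # per-s decomposition is consistent and non-increasing
  res <- pattern_pvalue(p, mod, 3, 2)
  expect_equal(res$per_s, c(3 / 8, 1 / 8))
  expect_equal(sum(res$per_state), res$p_value)
})

test_that("single-letter patterns run through the degenerate graph", {
  p <- pattern_words("a", ab2)
  mod <- bernoulli_hmm(c(0.25, 0.75), ab2)
  for (N in 1:8) {
    for (S in 1:3) {
      expect_equal(pattern_pvalue(p, mod, N, S)$p_value,
                   1 - pbinom(S - 1, N, 0.25),
                   tolerance = 1e-13)
    }
  }
})

test_that("engine equals exhaustive enumeration on random small instances", {
  set.seed(501)
  models <- list(
    bernoulli_hmm(c(0.5, 0.5), ab2),
    bernoulli_hmm(c(0.15, 0.85), ab2),
    random_hmm(2, 2, ab2),
    random_hmm(3, 2, ab2)
  )
  for (rep in 1:6) {
    p <- random_pattern(sample(1:3, 1), sample(2:4, 1), ab2)
    g <- overlap_graph(p)
    for (mod in models) {
      tt <- transition_tables(g, mod)
      for (S in 1:2) {
        N <- sample(p$m:9, 1)
        expect_equal(
          pattern_pvalue(p, mod, N, S, graph = g, tables = tt)$p_value,
          pvalue_enumerate(p, mod, N, S),
          tolerance = 1e-12)
      }
    }
  }
})

test_that("P-values are monotone in S and N", {
  set.seed(90)
  p <- random_pattern(3, 3)
  mod <- random_hmm(2, 2)
  ps <- vapply(0:4, function(S) pattern_pvalue(p, mod, 12, S)$p_value, 1)
  expect_true(all(diff(ps) <= 1e-14))
  pn <- vapply(3:30, function(N) pattern_pvalue(p, mod, N, 2)$p_value, 1)
  expect_true(all(diff(pn) >= -1e-14))
})

test_that("uniform Bernoulli and its order-1 Markov embedding coincide", {
  V <- c("A", "C", "G", "T")
  b <- uniform_dna()
  mk <- markov_hmm(1, matrix(0.25, 4, 4, dimnames = list(V, V)))
  p <- example_pattern()
  g <- overlap_graph(p)
  for (N in c(7, 15, 40)) {
    for (S in 1:2) {
      expect_equal(pattern_pvalue(p, b, N, S, graph = g)$p_value,
                   pattern_pvalue(p, mk, N, S, graph = g)$p_value,
                   tolerance = 1e-12)
    }
  }
})

test_that("non-uniform Markov chains agree with the automaton embedding", {
  set.seed(12)
  tm <- matrix(runif(16), 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  tm <- tm / rowSums(tm)
  mk <- markov_hmm(1, tm)
  p <- example_pattern()
  e <- pattern_pvalue(p, mk, 60, 2)$p_value
  a <- pvalue_automaton(p, mk, 60, 2)
  expect_equal(e, a, tolerance = 1e-12)
})

test_that("underflowing probabilities are reported as zero with a warning", {
  p <- pattern_words("aaaa", ab2)
  mod <- bernoulli_hmm(c(1e-62, 1 - 1e-62), ab2)
  expect_warning(res <- pattern_pvalue(p, mod, 8, 2), "underflow")
  expect_identical(res$p_value, 0)
})
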