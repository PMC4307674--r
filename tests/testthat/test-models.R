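test_that("model construction validates the outgoing-mass condition", {
  m <- bernoulli_hmm(rep(0.25, 4))
  expect_length(m$states, 1L)
  expect_true(m$deterministic)

  expect_error(bernoulli_hmm(c(0.6, 0.6), ab2), "sum to 1")
  expect_error(bernoulli_hmm(c(0.5, 0.5, 0.1), ab2), "one probability per")

  # a state whose mass sums to 0.9 is rejected
  pi_bad <- array(0, c(2, 2, 2))
  pi_bad[1, , ] <- 0.25
  pi_bad[2, , ] <- c(0.2, 0.25, 0.2, 0.25)
  expect_error(hmm(pi_bad, ab2), "mass must be 1")

  # both-target transitions make the model non-deterministic
  pi2 <- array(0.25, c(2, 2, 2))
  m2 <- hmm(pi2, ab2)
  expect_false(m2$deterministic)
  expect_null(m2$phi)

  # deterministic models expose phi/rho consistent with pi
  pi3 <- array(0, c(2, 2, 2))
  pi3[1, 1, 2] <- 0.7; pi3[1, 2, 1] <- 0.3
  pi3[2, 1, 1] <- 0.5; pi3[2, 2, 2] <- 0.5
  m3 <- hmm(pi3, ab2)
  expect_true(m3$deterministic)
  expect_identical(m3$phi[1, 1], 2L)
  expect_equal(m3$rho[1, 1], 0.7)
  expect_equal(rowSums(m3$trans), c(q1 = 1, q2 = 1))
})

test_that("Markov embeddings are deterministic context chains", {
  V <- c("A", "C", "G", "T")
  mk <- markov_hmm(1, matrix(0.25, 4, 4, dimnames = list(V, V)))
  expect_length(mk$states, 5L)    # empty context + 4 letter contexts
  expect_true(mk$deterministic)

  tm <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  degen <- markov_hmm(1, tm, ab2, start = "uniform")
  expect_true(degen$deterministic)
  # once in context "a" the chain emits "a" forever
  expect_equal(sum(word_prob(degen, "aaaa")), 0.5)
  expect_equal(sum(word_prob(degen, "abab")), 0)

  mk2 <- markov_hmm(2, matrix(0.5, 4, 2,
                              dimnames = list(c("aa", "ab", "ba", "bb"), NULL)),
                    ab2)
  expect_length(mk2$states, 7L)   # contexts of lengths 0, 1, 2
  expect_true(mk2$deterministic)

  # order 0 collapses to the Bernoulli model
  m0 <- markov_hmm(0, c(0.1, 0.2, 0.3, 0.4))
  expect_length(m0$states, 1L)
  expect_equal(sum(word_prob(m0, "AC")), 0.1 * 0.2)

  expect_error(markov_hmm(1, matrix(c(0.5, 0.4, 0.5, 0.5), 2, 2,
                                    dimnames = list(c("a", "b"), NULL)), ab2),
               "sum to 1")
})

test_that("stationary start-up reproduces the chain's marginal letter law", {
  set.seed(9)
  tm <- matrix(runif(4), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tm <- tm / rowSums(tm)
  mk <- markov_hmm(1, tm, ab2, start = "stationary")
  # the first-letter law solves mu P = mu
  mu <- word_prob(mk, "a")
  first_a <- sum(mu)
  expect_equal(first_a * tm["a", "a"] + (1 - first_a) * tm["b", "a"], first_a,
               tolerance = 1e-12)
})

test_that("word probabilities agree with explicit path enumeration", {
  set.seed(31)
  for (rep in 1:5) {
    mod <- random_hmm(2 + rep %% 2, 2, ab2)
    for (t in c("a", "ab", "bba", "abab")) {
      expect_equal(unname(word_prob(mod, t)), brute_word_prob(mod, t),
                   tolerance = 1e-13)
    }
  }
  # empty word: indicator of the start state
  mod <- random_hmm(3, 2, ab2)
  expect_equal(unname(word_prob(mod, "", from = 2L)), c(0, 1, 0))
  # Bernoulli: product of letter probabilities
  expect_equal(sum(word_prob(uniform_dna(), "ACA")), 4^-3)
})

test_that("word probabilities over all fixed-length words sum to one", {
  set.seed(77)
  mods <- list(bernoulli_hmm(c(0.3, 0.7), ab2), random_hmm(3, 2, ab2),
               random_hmm(2, 1, ab2))
  words6 <- do.call(paste0, expand.grid(rep(list(c("a", "b")), 6)))
  for (mod in mods) {
    for (q0 in seq_along(mod$states)) {
      tot <- sum(vapply(words6, function(w) {
        sum(word_prob(mod, w, from = q0))
      }, numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
    if (mod$deterministic) {
      expect_lte(sum(word_prob(mod, "abba") > 0), 1L)
    }
  }
})

test_that("reachable-state sets prune the graph-model product", {
  g <- overlap_graph(example_pattern())
  ss <- state_sets(g, uniform_dna())
  expect_true(all(vapply(ss$all_state, identical, logical(1), 1L)))

  # order-1 Markov: nodes of length >= 1 pin the context to a single state
  V <- c("A", "C", "G", "T")
  mk <- markov_hmm(1, matrix(0.25, 4, 4, dimnames = list(V, V)))
  ssm <- state_sets(g, mk)
  for (i in seq_len(g$n_nodes)[-1L]) {
    expect_length(ssm$all_state[[i]], 1L)
  }

  # dense 3-state model: everything reachable everywhere
  set.seed(4)
  h3 <- random_hmm(3, 3)
  ss3 <- state_sets(g, h3)
  expect_true(all(vapply(ss3$all_state, length, integer(1)) == 3L))
  # prior states are subsets of the left parent's reachable set
  for (i in seq_len(g$n_nodes)[-1L]) {
    for (q in 1:3) {
      expect_true(all(ss3$prior_state[[i]][[q]] %in%
                        ss3$all_state[[g$lpred[i]]]))
    }
  }
})

test_that("transition tables hold the documented worked-example values", {
  g <- overlap_graph(example_pattern())
  tt <- transition_tables(g, uniform_dna())
  i_aca <- match("ACA", g$nodes)
  expect_equal(as.numeric(tt$left_trans[[i_aca]]), 4^-2)   # Back(ACA) = CA
  i_ta <- match("TA", g$nodes)
  expect_equal(as.numeric(tt$word_prob[[i_ta]]), 2 * 4^-7)
  k <- which(vapply(g$classes, function(cl) {
    g$nodes[cl$lpred] == "ACA" && g$nodes[cl$rpred] == "TA"
  }, logical(1)))
  expect_equal(as.numeric(tt$deep_trans[[k]]), 2 * 4^-4)   # {GCTA, TATA}
  expect_equal(as.numeric(tt$trans), 1)
  expect_equal(tt$h_end_prob[[1L]], 4 * 4^-7)
})
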