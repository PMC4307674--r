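test_that("the trie is the prefix closure with suffix links", {
  p <- pattern_words(c("aa", "ab"), ab2)
  tr <- build_trie(p)
  expect_identical(tr$n_nodes, 4L)
  expect_setequal(tr$word, c("", "a", "aa", "ab"))

  p <- example_pattern()
  tr <- build_trie(p)
  prefixes <- unique(unlist(lapply(p$words, function(w) {
    substring(w, 1L, 1:nchar(w))
  })))
  expect_identical(tr$n_nodes, length(prefixes) + 1L)

  tr1 <- build_trie(pattern_words("ACGTT"))
  expect_identical(tr1$n_nodes, 6L)

  # suffix link of every node is its longest proper suffix in the trie
  for (v in seq_len(tr$n_nodes)[-1L]) {
    w <- tr$word[v]
    sufs <- substring(w, 2:(nchar(w) + 1L), nchar(w))
    present <- sufs[sufs %in% tr$word]
    longest <- present[which.max(nchar(present))]
    expect_identical(tr$word[tr$fail[v]], longest)
  }
})

test_that("the worked example yields the documented overlap graph", {
  g <- overlap_graph(example_pattern())
  expect_identical(g$nodes, c("", "A", "ACA", "C", "TA"))
  st <- graph_stats(g)
  expect_identical(st$n_classes, 3L)
  expect_identical(st$n_left_edges, 4L)
  expect_identical(st$n_deep_edges, 3L)

  i_aca <- match("ACA", g$nodes)
  expect_identical(g$nodes[g$lpred[i_aca]], "A")
  expect_identical(g$nodes[g$rpred[i_aca]], "A")
  expect_identical(g$back[i_aca], "CA")

  cl <- class_of("ACAGCTA", g)
  expect_identical(g$nodes[cl$lpred], "ACA")
  expect_identical(g$nodes[cl$rpred], "TA")
  expect_setequal(cl$members, c("ACAGCTA", "ACATATA"))
  expect_setequal(cl$backs, c("GCTA", "TATA"))

  cl2 <- class_of("CTTTCGC", g)
  expect_identical(g$nodes[cl2$lpred], "C")
  expect_identical(g$nodes[cl2$rpred], "C")
  cl3 <- class_of("TACCACA", g)
  expect_identical(g$nodes[cl3$lpred], "TA")
  expect_identical(g$nodes[cl3$rpred], "ACA")
  expect_error(class_of("AAAAAAA", g), "not a pattern word")

  # words ending with TA / whose rpred is TA
  i_ta <- match("TA", g$nodes)
  expect_setequal(g$h_deep[[i_ta]], c("ACAGCTA", "ACATATA"))
  expect_setequal(g$h_end[[i_ta]], c("ACAGCTA", "ACATATA"))
  expect_setequal(g$h_end[[1L]], example_pattern()$words)
})

test_that("overlap prefixes list the overlap chain in ascending length", {
  g <- overlap_graph(example_pattern())
  op <- overlap_prefixes("ACA", g)
  expect_identical(op$prefix, c("A", "ACA"))
  expect_identical(op$back, c("CA", ""))
  op2 <- overlap_prefixes("ACAGCTA", g)
  expect_identical(op2$prefix, c("A", "ACA"))
  expect_identical(op2$back, c("CAGCTA", "GCTA"))
  expect_identical(overlap_prefixes("C", g)$prefix, "C")
  expect_error(overlap_prefixes("", g), "non-empty")
  expect_error(overlap_prefixes("GG", g), "neither")
})

test_that("overlap sets match the definitional brute force on random patterns", {
  set.seed(202)
  for (rep in 1:25) {
    alph <- if (rep %% 2 == 0) ab2 else dna_alphabet()
    m <- sample(2:6, 1)
    nw <- sample(seq_len(min(5, length(alph$symbols)^m - 1L)), 1)
    p <- random_pattern(nw, m, alph)
    g <- overlap_graph(p)
    expect_identical(g$nodes, brute_overlap_set(p$words))

    # lpred/rpred are the longest overlap proper prefix/suffix of each node
    for (i in seq_len(g$n_nodes)[-1L]) {
      w <- g$nodes[i]
      pre <- substring(w, 1L, 0:(nchar(w) - 1L))
      ovpre <- pre[pre %in% g$nodes]
      expect_identical(g$nodes[g$lpred[i]], ovpre[which.max(nchar(ovpre))])
      suf <- substring(w, 2:(nchar(w) + 1L), nchar(w))
      ovsuf <- suf[suf %in% g$nodes]
      expect_identical(g$nodes[g$rpred[i]], ovsuf[which.max(nchar(ovsuf))])
      expect_identical(paste0(g$nodes[g$lpred[i]], g$back[i]), w)
    }

    # classes partition the pattern; per-node word sets are consistent
    members <- unlist(lapply(g$classes, `[[`, "members"))
    expect_setequal(members, p$words)
    expect_length(members, length(p$words))
    expect_identical(sum(lengths(g$h_deep)), length(p$words))

    # both edge families are trees spanning all non-root nodes
    expect_identical(sum(!is.na(g$lpred)), g$n_nodes - 1L)
    expect_identical(sum(!is.na(g$rpred)), g$n_nodes - 1L)
  }
})

test_that("single-letter patterns degenerate to a root-only graph", {
  p <- pattern_words(c("a"), ab2)
  g <- overlap_graph(p)
  expect_identical(g$nodes, "")
  expect_length(g$classes, 1L)
  expect_identical(g$classes[[1L]]$lpred, 1L)
  expect_identical(g$classes[[1L]]$rpred, 1L)
  expect_true(g$is_right_deep[1L])
})

test_that("DOT export names every node and edge family", {
  g <- overlap_graph(example_pattern())
  txt <- write_dot(g)
  expect_match(txt, "digraph")
  expect_match(txt, "style=solid")
  expect_match(txt, "style=dashed")
  expect_match(txt, "style=bold")
  expect_match(txt, "ACAGCTA,ACATATA", fixed = TRUE)
  f <- withr::local_tempfile(fileext = ".dot")
  write_dot(g, f)
  expect_true(file.exists(f))
})
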