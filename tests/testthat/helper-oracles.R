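# Independent reference computations used across test files.

ab2 <- alphabet(c("a", "b"))

# definitional overlap set: strings that are simultaneously a proper suffix
# of some pattern word and a proper prefix of some pattern word (plus the
# empty word), by direct enumeration
brute_overlap_set <- function(words) {
  m <- nchar(words[[1L]])
  suf <- unique(unlist(lapply(words, function(w) {
    substring(w, (2:(m + 1L)), m)     # proper suffixes, "" included
  })))
  pre <- unique(unlist(lapply(words, function(w) {
    substring(w, 1L, 0:(m - 1L))      # proper prefixes, "" included
  })))
  sort(intersect(suf, pre))
}

# path-enumeration probability of emitting word t from state `from`,
# summed over explicit state sequences (independent of matrix products)
brute_word_prob <- function(model, t, from = model$initial) {
  nq <- length(model$states)
  if (!nzchar(t)) {
    out <- numeric(nq)
    out[from] <- 1
    return(out)
  }
  letters_t <- strsplit(t, "")[[1L]]
  L <- length(letters_t)
  out <- numeric(nq)
  paths <- expand.grid(rep(list(seq_len(nq)), L))
  for (i in seq_len(nrow(paths))) {
    states <- as.integer(paths[i, ])
    pr <- 1
    prev <- from
    for (j in seq_len(L)) {
      pr <- pr * model$pi[prev, letters_t[j], states[j]]
      prev <- states[j]
    }
    out[states[L]] <- out[states[L]] + pr
  }
  out
}

# worked 4-word example pattern used throughout
example_pattern <- function() {
  pattern_words(c("ACAGCTA", "ACATATA", "CTTTCGC", "TACCACA"))
}

uniform_dna <- function() bernoulli_hmm(rep(0.25, 4))
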