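#' Count pattern occurrences in a text
#'
#' An occurrence is a position of the text at which some pattern word ends.
#' Because all pattern words share one length, at most one word can end at
#' a given position, so the count is unambiguous.
#'
#' @param text A string over the pattern's alphabet.
#' @param p An `mp_pattern`.
#' @return Integer occurrence count.
#' @examples
#' p <- pattern_words(c("ACAGCTA", "ACATATA", "CTTTCGC", "TACCACA"))
#' count_occurrences("CTTTCGCCGAATCACAGCTA", p)   # 2
#' @export
count_occurrences <- function(text, p) {
  stopifnot(inherits(p, "mp_pattern"))
  n <- nchar(text)
  m <- p$m
  if (n < m) return(0L)
  ends <- m:n
  sum(substring(text, ends - m + 1L, ends) %in% p$words)
}

#' Reference P-value by exhaustive text enumeration
#'
#' Enumerates every text of length `N` over the alphabet, counts its
#' pattern occurrences, scores its probability under the model with the
#' forward recursion, and sums the probabilities of texts with at least
#' `S` occurrences.  This is the definitional oracle: slow (`|V|^N`
#' texts) but independent of the overlap-graph engine.
#'
#' @param p An `mp_pattern`.
#' @param model An `mp_hmm`.
#' @param N Text length; `|V|^N` must not exceed `cap`.
#' @param S Minimum occurrence count.
#' @param cap Refusal threshold on the number of texts (default `2^20`).
#' @return The P-value as a plain number.
#' @export
pvalue_enumerate <- function(p, model, N, S, cap = 2^20) {
  stopifnot(inherits(p, "mp_pattern"), inherits(model, "mp_hmm"))
  if (S == 0L) return(1)
  V <- model$alphabet$symbols
  if (length(V)^N > cap) {
    stop("refusing to enumerate ", length(V), "^", N, " > ", cap, " texts",
         call. = FALSE)
  }
  if (N < p$m) return(0)
  grid <- expand.grid(rev(rep(list(V), N)), stringsAsFactors = FALSE)
  texts <- do.call(paste0, grid[rev(seq_len(N))])
  total <- 0
  for (t in texts) {
    if (count_occurrences(t, p) >= S) {
      total <- total + sum(word_prob(model, t))
    }
  }
  total
}

#' Reference P-value by automaton-product dynamic programming
#'
#' The classical Markov chain embedding: a first-order chain on the product
#' of the Aho-Corasick automaton of the pattern, the model's state space,
#' and the occurrence count capped at `S`.  At each of the `N` steps the
#' chain follows the automaton's goto function for each letter, multiplies
#' by the model's emission-transition probability, and increments the
#' capped count when the automaton lands on a terminal node.  The answer is
#' the total mass with count `S` after `N` steps.  Exact, like the
#' overlap-graph engine, but with a state space proportional to the full
#' trie rather than to the overlap set — it exists for cross-validation,
#' not speed.
#'
#' @param p An `mp_pattern`.
#' @param model An `mp_hmm`.
#' @param N Text length.
#' @param S Minimum occurrence count.
#' @return The P-value as a plain number.
#' @export
pvalue_automaton <- function(p, model, N, S) {
  stopifnot(inherits(p, "mp_pattern"), inherits(model, "mp_hmm"))
  S <- as.integer(S)
  if (S == 0L) return(1)
  if (N < p$m) return(0)
  tr <- build_trie(p)
  K <- tr$n_nodes
  nq <- length(model$states)
  nv <- length(model$alphabet$symbols)
  sw <- S + 1L                         # counts 0..S (S means ">= S")
  ns <- K * sw
  sidx <- function(node, cnt) (node - 1L) * sw + cnt + 1L

  # per-letter 0/1 transfer matrix on (automaton node, capped count)
  src_node <- rep(seq_len(K), each = sw)
  src_cnt <- rep(0:S, times = K)
  transfer <- lapply(seq_len(nv), function(a) {
    tgt_node <- tr$delta[src_node, a]
    tgt_cnt <- pmin(src_cnt + as.integer(tr$terminal[tgt_node]), S)
    Matrix::sparseMatrix(i = sidx(tgt_node, tgt_cnt),
                         j = sidx(src_node, src_cnt),
                         x = 1, dims = c(ns, ns))
  })

  P <- matrix(0, ns, nq)
  P[sidx(1L, 0L), model$initial] <- 1
  for (step in seq_len(N)) {
    Pn <- matrix(0, ns, nq)
    for (a in seq_len(nv)) {
      Pn <- Pn + as.matrix(transfer[[a]] %*% (P %*% model$pi_letter[[a]]))
    }
    P <- Pn
  }
  sum(P[sidx(seq_len(K), S), ])
}
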