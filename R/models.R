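#' Hidden Markov models as text generators
#'
#' A model is a triple `<Q, q0, pi>`: a finite state set, an initial state
#' and an emission-transition function where `pi[q~, a, q]` is the
#' probability, being in state `q~`, of emitting letter `a` and moving to
#' state `q`.  For every state the total outgoing mass over letters and
#' target states must be 1.  A model is deterministic when each `(q~, a)`
#' pair has at most one positive-probability target; Bernoulli (one state)
#' and order-K Markov backgrounds are special cases.
#'
#' @param pi Numeric 3-d array of dimension `|Q| x |V| x |Q|`
#'   (from-state, letter, to-state).  `dimnames` may name states/letters;
#'   otherwise states are named `q1, q2, ...`.
#' @param alphabet An [alphabet()]; its symbols must match `dim(pi)[2]`.
#' @param initial Initial state (name or index); defaults to the first.
#' @param tol Absolute tolerance for the per-state normalization check.
#' @return An object of class `mp_hmm` with elements `states`, `initial`,
#'   `pi` (the array), `pi_letter` (list of `|Q| x |Q|` matrices, one per
#'   letter), `trans` (the letter-marginalized transition matrix),
#'   `deterministic` and, for deterministic models, `phi`/`rho` (transition
#'   and probability functions as `|Q| x |V|` matrices).
#' @examples
#' bernoulli_hmm(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
#' @export
hmm <- function(pi, alphabet, initial = 1L, tol = 1e-9) {
  stopifnot(is.array(pi), length(dim(pi)) == 3L)
  nq <- dim(pi)[1L]
  nv <- length(alphabet$symbols)
  if (dim(pi)[2L] != nv || dim(pi)[3L] != nq) {
    stop("pi must be |Q| x |V| x |Q|", call. = FALSE)
  }
  if (any(pi < 0) || any(pi > 1)) {
    stop("pi entries must be probabilities in [0, 1]", call. = FALSE)
  }
  states <- dimnames(pi)[[1L]]
  if (is.null(states)) states <- paste0("q", seq_len(nq))
  dimnames(pi) <- list(states, alphabet$symbols, states)
  rs <- apply(pi, 1L, sum)
  if (any(abs(rs - 1) > tol)) {
    stop("outgoing probability mass must be 1 for every state (found ",
         paste(signif(rs[abs(rs - 1) > tol], 6), collapse = ", "), ")",
         call. = FALSE)
  }
  if (is.character(initial)) initial <- match(initial, states)
  initial <- as.integer(initial)
  if (is.na(initial) || initial < 1L || initial > nq) {
    stop("invalid initial state", call. = FALSE)
  }
  pi_letter <- lapply(seq_len(nv), function(a) {
    matrix(pi[, a, ], nq, nq, dimnames = list(states, states))
  })
  names(pi_letter) <- alphabet$symbols
  trans <- Reduce(`+`, pi_letter)
  n_targets <- apply(pi > 0, c(1L, 2L), sum)
  deterministic <- all(n_targets <= 1L)
  phi <- rho <- NULL
  if (deterministic) {
    phi <- matrix(NA_integer_, nq, nv, dimnames = list(states, alphabet$symbols))
    rho <- matrix(0, nq, nv, dimnames = list(states, alphabet$symbols))
    for (a in seq_len(nv)) {
      hit <- pi_letter[[a]] > 0
      for (q in seq_len(nq)) {
        tgt <- which(hit[q, ])
        if (length(tgt) == 1L) {
          phi[q, a] <- tgt
          rho[q, a] <- pi_letter[[a]][q, tgt]
        }
      }
    }
  }
  structure(list(states = states, initial = initial, pi = pi,
                 pi_letter = pi_letter, trans = trans,
                 deterministic = deterministic, phi = phi, rho = rho,
                 alphabet = alphabet),
            class = "mp_hmm")
}

#' @export
print.mp_hmm <- function(x, ...) {
  cat("HMM: ", length(x$states), " state(s) over {",
      paste(x$alphabet$symbols, collapse = ","), "}, initial ",
      x$states[x$initial],
      if (x$deterministic) ", deterministic" else "", "\n", sep = "")
  invisible(x)
}

#' Bernoulli (memoryless) background model
#'
#' A single-state model where each letter is emitted independently with a
#' fixed probability.
#'
#' @param probs Numeric letter probabilities summing to 1, in alphabet
#'   order (or named by symbol).
#' @param alphabet An [alphabet()].
#' @param tol Tolerance for the sum-to-one check.
#' @return A one-state `mp_hmm`.
#' @export
bernoulli_hmm <- function(probs, alphabet = dna_alphabet(), tol = 1e-9) {
  nv <- length(alphabet$symbols)
  if (!is.null(names(probs))) {
    probs <- probs[alphabet$symbols]
    if (anyNA(probs)) stop("probs names must cover the alphabet", call. = FALSE)
  }
  if (length(probs) != nv) {
    stop("need one probability per alphabet symbol", call. = FALSE)
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > tol) {
    stop("letter probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  pi <- array(probs, dim = c(1L, nv, 1L),
              dimnames = list("q1", alphabet$symbols, "q1"))
  hmm(pi, alphabet)
}

#' Order-K Markov background model, embedded as a deterministic HMM
#'
#' States encode the last `K` letters of the emitted text, plus start-up
#' states for the contexts of length `0 .. K-1` so that texts shorter than
#' `K` are handled.  From a full context `c`, letter `a` is emitted with
#' the conditional probability `transitions[c, a]` and the state moves to
#' the length-`K` suffix of `c a`.  Start-up emissions follow `start`:
#' `"stationary"` (default) derives short-context letter laws from the
#' stationary distribution of the chain, `"uniform"` uses equal letter
#' probabilities, and a named list maps each short context to an explicit
#' letter distribution.  `K = 0` coincides with [bernoulli_hmm()].
#'
#' @param order Markov order `K >= 0`.
#' @param transitions For `K >= 1`, a `|V|^K x |V|` matrix of conditional
#'   letter probabilities; rows are named by context.  For `K = 0`, a
#'   letter probability vector.
#' @param alphabet An [alphabet()].
#' @param start Start-up convention (see above).
#' @param tol Tolerance for row-sum checks.
#' @return A deterministic `mp_hmm` with `(|V|^K - 1) / (|V| - 1) + |V|^K`
#'   states (all contexts of length `0..K`).
#' @export
markov_hmm <- function(order, transitions, alphabet = dna_alphabet(),
                       start = "stationary", tol = 1e-9) {
  K <- as.integer(order)
  if (K < 0L) stop("order must be >= 0", call. = FALSE)
  V <- alphabet$symbols
  nv <- length(V)
  if (K == 0L) return(bernoulli_hmm(transitions, alphabet, tol))

  all_ctx <- function(k) {
    if (k == 0L) return("")
    grid <- expand.grid(rev(rep(list(V), k)), stringsAsFactors = FALSE)
    sort(do.call(paste0, grid[rev(seq_len(k))]))
  }
  full <- all_ctx(K)
  transitions <- as.matrix(transitions)
  if (nrow(transitions) != length(full) || ncol(transitions) != nv) {
    stop("transitions must be |V|^K x |V|", call. = FALSE)
  }
  if (is.null(rownames(transitions))) rownames(transitions) <- full
  if (!setequal(rownames(transitions), full)) {
    stop("transition row names must be the length-K contexts", call. = FALSE)
  }
  transitions <- transitions[full, , drop = FALSE]
  if (!is.null(colnames(transitions))) {
    transitions <- transitions[, V, drop = FALSE]
  } else {
    colnames(transitions) <- V
  }
  bad <- abs(rowSums(transitions) - 1) > tol
  if (any(transitions < 0) || any(bad)) {
    stop("each conditional distribution must be non-negative and sum to 1",
         call. = FALSE)
  }

  shorts <- unlist(lapply(seq_len(K) - 1L, all_ctx))
  ctxs <- c(shorts, full)
  # state names carry a prefix so the empty (start) context has a usable name
  states <- paste0("s", ctxs)
  nq <- length(ctxs)

  # start-up letter laws for contexts shorter than K
  startup <- matrix(1 / nv, length(shorts), nv,
                    dimnames = list(shorts, V))
  if (is.list(start)) {
    for (ci in seq_along(shorts)) {
      pr <- start[[shorts[ci]]]
      if (is.null(pr) && shorts[ci] == "" && !is.null(start$root)) {
        pr <- start$root   # JSON objects cannot hold an empty-string key
      }
      if (is.null(pr)) {
        stop("start list must give a distribution for context '", shorts[ci],
             "'", call. = FALSE)
      }
      if (!is.null(names(pr))) pr <- pr[V]
      startup[ci, ] <- pr
    }
  } else if (identical(start, "stationary")) {
    # stationary law of the chain on length-K contexts
    Tm <- matrix(0, length(full), length(full), dimnames = list(full, full))
    for (c1 in full) {
      for (a in V) {
        c2 <- substr(paste0(c1, a), 2L, K + 1L)
        Tm[c1, c2] <- Tm[c1, c2] + transitions[c1, a]
      }
    }
    ev <- eigen(t(Tm))
    i1 <- which.min(abs(ev$values - 1))
    mu <- Re(ev$vectors[, i1])
    mu <- mu / sum(mu)          # fixes the eigenvector's arbitrary sign
    mu <- pmax(mu, 0)
    mu <- mu / sum(mu)
    names(mu) <- full
    # marginal law of a j-gram = total stationary mass of contexts ending in it
    gram_p <- function(g) {
      j <- nchar(g)
      sum(mu[substr(full, K - j + 1L, K) == g])
    }
    for (ci in seq_along(shorts)) {
      pc <- gram_p(shorts[ci])   # gram_p("") = 1
      pr <- vapply(V, function(a) gram_p(paste0(shorts[ci], a)), numeric(1L))
      startup[ci, ] <- if (pc > 0) pr / pc else 1 / nv
    }
  } else if (!identical(start, "uniform")) {
    stop("start must be \"stationary\", \"uniform\" or a named list",
         call. = FALSE)
  }
  bad <- abs(rowSums(startup) - 1) > tol
  if (any(startup < 0) || any(bad)) {
    stop("start-up distributions must be non-negative and sum to 1",
         call. = FALSE)
  }

  pi <- array(0, dim = c(nq, nv, nq), dimnames = list(states, V, states))
  for (si in seq_len(nq)) {
    ctx <- ctxs[si]
    for (ai in seq_len(nv)) {
      nxt <- paste0(ctx, V[ai])
      if (nchar(nxt) > K) nxt <- substr(nxt, nchar(nxt) - K + 1L, nchar(nxt))
      pr <- if (nchar(ctx) < K) {
        startup[match(ctx, shorts), ai]
      } else {
        transitions[ctx, ai]
      }
      pi[si, ai, match(nxt, ctxs)] <- pr
    }
  }
  hmm(pi, alphabet, initial = match("", ctxs))
}

# product of per-letter transition matrices for a word: entry [q~, q] is the
# probability to emit t and move from q~ to q
word_matrix <- function(model, t) {
  nq <- length(model$states)
  M <- diag(nq)
  if (nzchar(t)) {
    for (ch in chars(t)) {
      Pa <- model$pi_letter[[ch]]
      if (is.null(Pa)) stop("letter '", ch, "' not in model alphabet",
                            call. = FALSE)
      M <- M %*% Pa
    }
  }
  dimnames(M) <- list(model$states, model$states)
  M
}

# sum of word matrices over a set of words
set_matrix <- function(model, words) {
  Reduce(`+`, lapply(words, function(w) word_matrix(model, w)))
}

#' Probability of emitting a word
#'
#' `word_prob(model, t, from)` returns, for each state `q`, the total
#' probability of all state paths that start in `from`, emit exactly the
#' word `t`, and end in `q` (the forward recursion restricted to one word).
#' Summing the result gives the probability that the model emits `t` from
#' `from`; for the empty word the result is the indicator of `from`.
#'
#' @param model An `mp_hmm`.
#' @param t A word over the model alphabet (may be `""`).
#' @param from Start state (name or index); defaults to the initial state.
#' @return Named numeric vector over states.
#' @examples
#' m <- bernoulli_hmm(rep(0.25, 4))
#' sum(word_prob(m, "ACA"))   # 1/64
#' @export
word_prob <- function(model, t, from = model$initial) {
  stopifnot(inherits(model, "mp_hmm"))
  if (is.character(from)) from <- match(from, model$states)
  nq <- length(model$states)
  v <- numeric(nq)
  v[from] <- 1
  if (nzchar(t)) {
    for (ch in chars(t)) {
      Pa <- model$pi_letter[[ch]]
      if (is.null(Pa)) stop("letter '", ch, "' not in model alphabet",
                            call. = FALSE)
      v <- as.numeric(v %*% Pa)
    }
  }
  stats::setNames(v, model$states)
}

#' Reachable-state sets over an overlap graph
#'
#' For each overlap node `w`, `all_state[[w]]` is the set of states the
#' model can be in just after emitting any text ending with `w` (states
#' reachable from the initial state by at least one text with suffix `w`).
#' It is computed as the image of `w`'s word matrix over the closure
#' `R-inf` of states reachable from the initial state by texts of any
#' length.  `prior_state[[w]][[q]]` is the subset of `all_state[[lpred(w)]]`
#' from which `q` is reachable while emitting `Back(w)`.  For classes,
#' `all_state_class` unions the member words' sets.  These sets bound which
#' entries of the transition tables can be non-zero; the engine stores
#' dense matrices whose entries outside these sets are structurally zero.
#'
#' @param g An `mp_ovgraph`.
#' @param model An `mp_hmm` over the same alphabet.
#' @return A list with `r_inf`, `all_state`, `all_state_class` and
#'   `prior_state` (state indices).
#' @export
state_sets <- function(g, model) {
  nq <- length(model$states)
  # states reachable from the initial state by any text (including none)
  reach <- logical(nq)
  reach[model$initial] <- TRUE
  repeat {
    nxt <- reach | (as.numeric(reach %*% (model$trans > 0)) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  r_inf <- which(reach)
  Mnode <- lapply(g$nodes, function(w) word_matrix(model, w))
  all_state <- lapply(Mnode, function(M) {
    unname(which(colSums(M[r_inf, , drop = FALSE] > 0) > 0))
  })
  all_state_class <- lapply(g$classes, function(cl) {
    sort(unique(unlist(lapply(cl$members, function(H) {
      M <- word_matrix(model, H)
      unname(which(colSums(M[r_inf, , drop = FALSE] > 0) > 0))
    }))))
  })
  prior_state <- lapply(seq_len(g$n_nodes), function(i) {
    if (i == 1L) return(NULL)
    Mb <- word_matrix(model, g$back[i])
    par <- all_state[[g$lpred[i]]]
    lapply(seq_len(nq), function(q) {
      par[Mb[par, q] > 0]
    })
  })
  list(r_inf = r_inf, all_state = all_state,
       all_state_class = all_state_class, prior_state = prior_state)
}

#' Constant transition tables attached to an overlap graph
#'
#' Precomputes, once per (pattern, model) pair, every probability the
#' stage recursion reuses: the letter-marginalized transition matrix; per
#' non-root node the left transition matrix `Prob(q~, Back(w), q)`; per
#' class the deep transition matrix `Prob(q~, Back(H*(w,r)), q)` (summed
#' over the class's back words); per right deep node `r` the word matrix
#' `Prob(q~, H~(r), q)` summed over the words whose `rpred` is `r`; and per
#' node the initial-state probability vector of the words ending with it
#' (used for the length-`m` base case).
#'
#' @param g An `mp_ovgraph`.
#' @param model An `mp_hmm` over the same alphabet.
#' @return A list with `trans`, `left_trans`, `deep_trans`, `word_prob`
#'   and `h_end_prob`.
#' @export
transition_tables <- function(g, model) {
  check_over_alphabet(g$pattern$words[1L], model$alphabet)
  nq <- length(model$states)
  left_trans <- vector("list", g$n_nodes)
  for (i in seq_len(g$n_nodes)[-1L]) {
    left_trans[[i]] <- word_matrix(model, g$back[i])
  }
  deep_trans <- lapply(g$classes, function(cl) set_matrix(model, cl$backs))
  wp <- vector("list", g$n_nodes)
  for (i in which(g$is_right_deep)) {
    wp[[i]] <- set_matrix(model, g$h_deep[[i]])
  }
  h_end_prob <- lapply(seq_len(g$n_nodes), function(i) {
    ws <- g$h_end[[i]]
    if (length(ws) == 0L) return(numeric(nq))
    rowSums(matrix(vapply(ws, function(H) word_prob(model, H), numeric(nq)),
                   nrow = nq))
  })
  list(trans = model$trans, left_trans = left_trans,
       deep_trans = deep_trans, word_prob = wp, h_end_prob = h_end_prob)
}
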