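#' Exact P-value of a pattern occurrence count
#'
#' Computes `Prob(B(N, S))`: the probability that a random text of length
#' `N`, generated by the model, contains at least `S` occurrences of the
#' pattern (an occurrence is a position where some pattern word ends; since
#' all words share one length, at most one word ends per position).
#'
#' The computation is exact, by induction on the text length
#' `n = m+1 .. N` and, within each stage, on the occurrence count
#' `s = 1 .. S`.  Each stage runs over the overlap graph: texts with at
#' least `s` occurrences are decomposed by how their final pattern
#' occurrence overlaps the `s`-th one, which yields disjoint unions whose
#' probabilities are pure sums.  Per stage the work is (i) advance the
#' lagged `B`-set probabilities, (ii) a pass over the left and deep edges
#' that produces, for every right deep node, the probability of ending with
#' one of its words with exactly `s` occurrences (`RE`-sets), carrying the
#' `D`-set probabilities down the left tree, and (iii) a bottom-up pass
#' along the right edges aggregating the `R`-set probabilities into
#' circular buffers of depth `m - len(w)`.  All probabilities are kept per
#' model state; the final P-value sums the state-resolved `B(N, S)` values.
#'
#' Arithmetic is plain double precision in probability space; values below
#' `1e-300` are reported as 0 with a warning.
#'
#' @param p An `mp_pattern`.
#' @param model An `mp_hmm` over the same alphabet.
#' @param N Text length (`>= 1`).
#' @param S Minimum occurrence count (`>= 0`).  `S = 0` gives 1 by
#'   convention; `N < m` with `S >= 1` gives 0.
#' @param graph Optional precomputed [overlap_graph()] of `p` (re-used
#'   across calls with different models or query sizes).
#' @param tables Optional precomputed [transition_tables()].
#' @return An object of class `mp_pvalue`: a list with `p_value`,
#'   `per_state` (named vector, `Prob(B(N,S), q)`), `per_s`
#'   (`Prob(B(N,s))` for `s = 1..S`), and the query (`N`, `S`).
#' @examples
#' ab <- alphabet(c("a", "b"))
#' p <- pattern_words("aa", ab)
#' mod <- bernoulli_hmm(c(0.5, 0.5), ab)
#' pattern_pvalue(p, mod, N = 3, S = 1)$p_value   # 0.375
#' @export
pattern_pvalue <- function(p, model, N, S, graph = NULL, tables = NULL) {
  stopifnot(inherits(p, "mp_pattern"), inherits(model, "mp_hmm"))
  N <- as.integer(N)
  S <- as.integer(S)
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  if (S < 0L) stop("S must be >= 0", call. = FALSE)
  m <- p$m
  nq <- length(model$states)
  q0 <- model$initial

  finish <- function(B_final) {
    per_state <- pmin(pmax(B_final[S, ], 0), 1)
    pv <- sum(per_state)
    if (pv > 0 && pv < 1e-300) {
      warning("P-value underflowed below 1e-300; reporting 0")
      pv <- 0
    }
    structure(list(p_value = min(pv, 1),
                   per_state = stats::setNames(per_state, model$states),
                   per_s = pmin(pmax(rowSums(B_final), 0), 1),
                   N = N, S = S),
              class = "mp_pvalue")
  }

  if (S == 0L) {
    ps <- numeric(nq)
    ps[q0] <- 1   # placeholder state mass; Prob(B(N,0)) = 1 by convention
    return(structure(list(p_value = 1,
                          per_state = stats::setNames(ps, model$states),
                          per_s = numeric(0), N = N, S = 0L),
                     class = "mp_pvalue"))
  }
  if (N < m) {
    return(structure(list(p_value = 0,
                          per_state = stats::setNames(numeric(nq), model$states),
                          per_s = numeric(S), N = N, S = S),
                     class = "mp_pvalue"))
  }

  if (is.null(graph)) graph <- overlap_graph(p)
  g <- graph
  if (is.null(tables)) tables <- transition_tables(g, model)
  Trans <- tables$trans
  probH <- tables$h_end_prob[[1L]]    # Prob(H, q) from the initial state

  base_B <- function(s1_row) {
    B <- matrix(0, S, nq)
    B[1L, ] <- s1_row
    B
  }
  if (N == m) return(finish(base_B(probH)))

  widths <- m - nchar(g$nodes)
  # circular buffers: buf[[w]][[(l mod width) + 1]] holds Prob(R(l, s, w), q)
  # as an S x |Q| matrix, for l in the sliding window [n-m+len(w), n-1]
  buf <- lapply(seq_len(g$n_nodes), function(i) {
    rows <- rep(list(matrix(0, S, nq)), widths[i])
    rows[[m %% widths[i] + 1L]] <- base_B(tables$h_end_prob[[i]])
    rows
  })

  rd <- which(g$is_right_deep)
  cls_w <- vapply(g$classes, `[[`, integer(1L), "lpred")
  cls_r <- vapply(g$classes, `[[`, integer(1L), "rpred")
  left_pre <- g$left_pre
  right_post <- g$right_post

  v_free <- numeric(nq)
  v_free[q0] <- 1                      # Prob(V^0, q)
  B_prev <- matrix(0, S, nq)           # B(n - m - 1, s) for s >= 1
  B_cur <- NULL
  TempD <- vector("list", g$n_nodes)
  TempD[[1L]] <- matrix(0, S, nq)      # D(., ., eps) is empty
  zero_rd <- rep(list(NULL), g$n_nodes)

  for (n in (m + 1L):N) {
    j <- n - m
    v_free <- v_free %*% Trans         # Prob(V^j, q), 1 x |Q|

    # part 1: advance B(j, s)
    B_cur <- if (j < m) {
      matrix(0, S, nq)
    } else if (j == m) {
      base_B(probH)
    } else {
      B_prev %*% Trans + buf[[1L]][[j %% m + 1L]]
    }

    # part 2: accumulate E(n, s, r) for every right deep node r, as an
    # (S+1) x |Q| array; row 1 is E(n, 1, r), rows 2..S+1 collect the
    # F + sum-of-C' contributions for occurrence counts 2..S+1
    Acc <- zero_rd
    for (r in rd) {
      Acc[[r]] <- rbind(v_free, B_cur) %*% tables$word_prob[[r]]
    }
    # D-set probabilities down the left tree
    for (w in left_pre[-1L]) {
      i_old <- (j + m - widths[w]) %% widths[w] + 1L   # row l = k(n, w)
      TempD[[w]] <- TempD[[g$lpred[w]]] %*% tables$left_trans[[w]] +
        buf[[w]][[i_old]]
    }
    # deep-edge contributions C'(n, s+1, w, r)
    for (k in seq_along(g$classes)) {
      w <- cls_w[k]
      if (w == 1L) next                # D at the root is empty
      r <- cls_r[k]
      Acc[[r]][-1L, ] <- Acc[[r]][-1L, , drop = FALSE] +
        TempD[[w]] %*% tables$deep_trans[[k]]
    }

    # part 3: RE(n, s, r) = E(n, s, r) - E(n, s+1, r), then aggregate the
    # R-sets bottom-up along the right edges and write row l = n
    Rnew <- vector("list", g$n_nodes)
    for (w in right_post) {
      acc <- if (is.null(Acc[[w]])) {
        matrix(0, S, nq)
      } else {
        Acc[[w]][seq_len(S), , drop = FALSE] -
          Acc[[w]][seq_len(S) + 1L, , drop = FALSE]
      }
      for (x in g$right_children[[w]]) acc <- acc + Rnew[[x]]
      Rnew[[w]] <- acc
    }
    for (w in seq_len(g$n_nodes)) {
      buf[[w]][[n %% widths[w] + 1L]] <- Rnew[[w]]
    }
    B_prev <- B_cur
  }

  # post-processing: roll B forward from length N - m to N
  for (l in (N - m + 1L):N) {
    B_cur <- B_cur %*% Trans + buf[[1L]][[l %% m + 1L]]
  }
  finish(B_cur)
}

#' @export
print.mp_pvalue <- function(x, ...) {
  cat("Prob(at least ", x$S, " occurrence(s) in a text of length ", x$N,
      ") = ", format_pv(x$p_value), "\n", sep = "")
  invisible(x)
}

# scientific notation with 8 significant digits
format_pv <- function(x) {
  toupper(formatC(x, format = "e", digits = 7))
}
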