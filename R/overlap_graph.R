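#' Aho-Corasick trie for a pattern
#'
#' Builds the prefix tree of all pattern words, with failure (suffix) links
#' and the full goto function (the deterministic transition used by the
#' automaton reference implementation).  The trie is also the scaffold from
#' which the overlap graph is extracted: a string is an overlap of the
#' pattern iff its trie node is reachable by a chain of suffix links from
#' some terminal node.
#'
#' @param p An `mp_pattern`.
#' @return An object of class `mp_trie`: integer matrices/vectors `child`,
#'   `delta` (n_nodes x |V|), `fail`, `depth`, `parent`, logical `terminal`,
#'   character `word` (node labels), and `n_nodes`.
#' @examples
#' build_trie(pattern_words(c("aa", "ab"), alphabet(c("a", "b"))))$n_nodes
#' @export
build_trie <- function(p) {
  stopifnot(inherits(p, "mp_pattern"))
  V <- p$alphabet$symbols
  nv <- length(V)
  cap <- sum(nchar(p$words)) + 1L
  child <- matrix(0L, cap, nv)
  depth <- integer(cap)
  parent <- integer(cap)
  word <- character(cap)
  terminal <- logical(cap)
  n_nodes <- 1L                       # node 1 is the root (empty word)
  for (w in p$words) {
    letters_idx <- match(chars(w), V)
    cur <- 1L
    for (j in letters_idx) {
      nxt <- child[cur, j]
      if (nxt == 0L) {
        n_nodes <- n_nodes + 1L
        nxt <- n_nodes
        child[cur, j] <- nxt
        depth[nxt] <- depth[cur] + 1L
        parent[nxt] <- cur
        word[nxt] <- paste0(word[cur], V[j])
      }
      cur <- nxt
    }
    terminal[cur] <- TRUE
  }
  child <- child[seq_len(n_nodes), , drop = FALSE]
  depth <- depth[seq_len(n_nodes)]
  parent <- parent[seq_len(n_nodes)]
  word <- word[seq_len(n_nodes)]
  terminal <- terminal[seq_len(n_nodes)]

  # failure links and goto function, in breadth-first (depth) order
  ord <- order(depth, word)
  fail <- integer(n_nodes)
  fail[1L] <- 1L
  delta <- matrix(0L, n_nodes, nv)
  for (v in ord) {
    if (v == 1L) {
      for (j in seq_len(nv)) {
        delta[1L, j] <- if (child[1L, j] > 0L) child[1L, j] else 1L
      }
      next
    }
    u <- parent[v]
    j_via <- match(substr(word[v], depth[v], depth[v]), V)
    fail[v] <- if (u == 1L) 1L else delta[fail[u], j_via]
    for (j in seq_len(nv)) {
      delta[v, j] <- if (child[v, j] > 0L) child[v, j] else delta[fail[v], j]
    }
  }
  structure(list(child = child, delta = delta, fail = fail, depth = depth,
                 parent = parent, word = word, terminal = terminal,
                 n_nodes = n_nodes, alphabet = p$alphabet, m = p$m),
            class = "mp_trie")
}

#' @export
print.mp_trie <- function(x, ...) {
  cat("Aho-Corasick trie: ", x$n_nodes, " nodes, ",
      sum(x$terminal), " terminal(s), depth ", x$m, "\n", sep = "")
  invisible(x)
}

# first overlap node (by decreasing length) on the suffix-link chain of v,
# starting from fail(v); is_ov marks overlap nodes (root included)
first_ov_on_chain <- function(v, fail, is_ov) {
  f <- fail[v]
  while (!is_ov[f]) f <- fail[f]
  f
}

#' Overlap graph of a pattern
#'
#' An overlap of a pattern is a string that is simultaneously a proper
#' suffix of some pattern word and a proper prefix of some pattern word;
#' the empty word is always an overlap.  The overlap graph has the overlaps
#' as nodes and three edge families: a left edge links `lpred(w)` (the
#' longest overlap that is a proper prefix of `w`) to `w`; a right edge
#' links `rpred(w)` (the longest overlap that is a proper suffix of `w`) to
#' `w`; and a deep edge `(w, r)` stands for the non-empty equivalence class
#' of pattern words `H` with `lpred(H) = w` and `rpred(H) = r`.  The classes
#' partition the pattern, so pattern words never need to be stored as nodes.
#'
#' @param p An `mp_pattern`.
#' @return An object of class `mp_ovgraph`.  Nodes are indexed in prefix
#'   (lexicographic) order with the root (empty word) first.  Components
#'   include `nodes` (overlap words), `lpred`, `rpred`, `back` (the word
#'   `Back(w)` with `w = lpred(w) . Back(w)`), per-node child lists for the
#'   left and right trees, traversal orders, the class table (`classes`),
#'   `h_end` (pattern words ending with each overlap; the whole pattern for
#'   the root) and `h_deep` (pattern words whose `rpred` is each node).
#' @examples
#' g <- overlap_graph(pattern_words(c("ACAGCTA", "ACATATA",
#'                                    "CTTTCGC", "TACCACA")))
#' g$nodes   # "", "A", "ACA", "C", "TA"
#' @export
overlap_graph <- function(p) {
  stopifnot(inherits(p, "mp_pattern"))
  tr <- build_trie(p)
  n <- tr$n_nodes
  m <- p$m

  # overlap discovery: mark suffix-link ancestors of terminal nodes
  marked <- logical(n)
  for (t in which(tr$terminal)) {
    f <- tr$fail[t]
    while (f != 1L && !marked[f]) {
      marked[f] <- TRUE
      f <- tr$fail[f]
    }
  }
  is_ov <- marked
  is_ov[1L] <- TRUE                      # the empty word is always an overlap
  ov_trie <- which(is_ov)
  # prefix (lexicographic) order; "" sorts first
  ov_trie <- ov_trie[order(tr$word[ov_trie], method = "radix")]
  n_ov <- length(ov_trie)
  nodes <- tr$word[ov_trie]
  ov_index <- integer(n)                 # trie id -> overlap index (0 if none)
  ov_index[ov_trie] <- seq_len(n_ov)

  # deepest proper overlap ancestor of each trie node, in depth order
  ovanc <- integer(n)                    # 0 for the root
  for (v in order(tr$depth)[-1L]) {
    u <- tr$parent[v]
    ovanc[v] <- if (is_ov[u]) u else ovanc[u]
  }

  lpred <- rpred <- rep(NA_integer_, n_ov)
  back <- rep(NA_character_, n_ov)
  for (i in seq_len(n_ov)[-1L]) {
    v <- ov_trie[i]
    lpred[i] <- ov_index[ovanc[v]]
    rpred[i] <- ov_index[first_ov_on_chain(v, tr$fail, is_ov)]
    back[i] <- substr(nodes[i], nchar(nodes[lpred[i]]) + 1L, nchar(nodes[i]))
  }

  # pattern words: lpred/rpred and suffix membership
  term <- which(tr$terminal)
  words <- tr$word[term]
  w_lpred <- ov_index[ovanc[term]]
  w_rpred <- vapply(term, function(t) {
    ov_index[first_ov_on_chain(t, tr$fail, is_ov)]
  }, integer(1L))

  # h_end[[i]]: words of the pattern ending with overlap i (all words for root)
  h_end <- rep(list(character(0)), n_ov)
  h_end[[1L]] <- words
  for (k in seq_along(term)) {
    f <- tr$fail[term[k]]
    while (f != 1L) {
      if (is_ov[f]) h_end[[ov_index[f]]] <- c(h_end[[ov_index[f]]], words[k])
      f <- tr$fail[f]
    }
  }
  h_deep <- lapply(seq_len(n_ov), function(i) words[w_rpred == i])

  # equivalence classes = deep edges
  key <- paste(w_lpred, w_rpred)
  cls_split <- split(seq_along(words), key)
  classes <- lapply(cls_split, function(ix) {
    w_i <- w_lpred[ix[1L]]
    r_i <- w_rpred[ix[1L]]
    mem <- words[ix]
    list(lpred = w_i, rpred = r_i, members = mem,
         backs = substr(mem, nchar(nodes[w_i]) + 1L, m))
  })
  # deterministic class order: by (lpred index, rpred index)
  classes <- classes[order(vapply(classes, `[[`, integer(1L), "lpred"),
                           vapply(classes, `[[`, integer(1L), "rpred"))]
  names(classes) <- NULL

  left_children <- lapply(seq_len(n_ov), function(i) which(lpred == i))
  right_children <- lapply(seq_len(n_ov), function(i) which(rpred == i))

  # preorder along left edges (parents before children), postorder along
  # right edges (children before parents); iterative to avoid deep recursion
  traverse <- function(children, post) {
    out <- integer(0)
    stack <- 1L
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      out <- c(out, v)
      kids <- children[[v]]
      if (length(kids) > 0L) stack <- c(stack, rev(kids))
    }
    if (post) rev(out) else out
  }
  left_pre <- traverse(left_children, post = FALSE)
  right_post <- rev(traverse(right_children, post = FALSE))

  is_right_deep <- vapply(seq_len(n_ov),
                          function(i) length(h_deep[[i]]) > 0L, logical(1L))

  structure(list(
    nodes = nodes, n_nodes = n_ov, m = m, pattern = p,
    lpred = lpred, rpred = rpred, back = back,
    left_children = left_children, right_children = right_children,
    left_pre = left_pre, right_post = right_post,
    classes = classes, is_right_deep = is_right_deep,
    h_end = h_end, h_deep = h_deep,
    word_lpred = stats::setNames(w_lpred, words),
    word_rpred = stats::setNames(w_rpred, words),
    n_trie_nodes = tr$n_nodes
  ), class = "mp_ovgraph")
}

#' @export
print.mp_ovgraph <- function(x, ...) {
  st <- graph_stats(x)
  cat("Overlap graph: ", st$n_overlaps, " overlap(s), ",
      st$n_classes, " class(es); ",
      st$n_left_edges, " left / ", st$n_right_edges, " right / ",
      st$n_deep_edges, " deep edges\n", sep = "")
  invisible(x)
}

#' Summary counts for an overlap graph
#'
#' @param g An `mp_ovgraph`.
#' @return A list with the number of overlaps (root included), equivalence
#'   classes, left/right/deep edges, pattern words and Aho-Corasick trie
#'   nodes.
#' @export
graph_stats <- function(g) {
  list(n_overlaps = g$n_nodes,
       n_classes = length(g$classes),
       n_left_edges = sum(!is.na(g$lpred)),
       n_right_edges = sum(!is.na(g$rpred)),
       n_deep_edges = length(g$classes),
       n_words = length(g$pattern$words),
       n_trie_nodes = g$n_trie_nodes)
}

#' Overlap prefixes of a word
#'
#' The non-empty prefixes of `v` (including `v` itself when it is an
#' overlap) that are overlaps of the pattern, in ascending length.  For a
#' non-root overlap or a pattern word this is exactly the chain of `lpred`
#' links.  Each returned prefix `x` comes with `Back(x, v)`, the suffix
#' completing `x` to `v`.
#'
#' @param v A non-empty overlap word or pattern word.
#' @param g An `mp_ovgraph`.
#' @return A data frame with columns `node` (overlap index), `prefix` and
#'   `back`.
#' @export
overlap_prefixes <- function(v, g) {
  if (identical(v, "")) stop("v must be non-empty", call. = FALSE)
  i <- match(v, g$nodes)
  chain <- integer(0)
  if (!is.na(i)) {
    cur <- i
  } else {
    if (!(v %in% g$pattern$words)) {
      stop("'", v, "' is neither an overlap nor a pattern word", call. = FALSE)
    }
    cur <- g$word_lpred[[v]]
  }
  while (!is.na(cur) && cur != 1L) {
    chain <- c(cur, chain)
    cur <- g$lpred[cur]
  }
  pre <- g$nodes[chain]
  data.frame(node = chain, prefix = pre,
             back = substr(rep(v, length(chain)), nchar(pre) + 1L, nchar(v)),
             stringsAsFactors = FALSE)
}

#' Equivalence class of a pattern word
#'
#' Pattern words are equivalent when they share `lpred` and `rpred`; each
#' class corresponds to one deep edge of the overlap graph.
#'
#' @param word A pattern word.
#' @param g An `mp_ovgraph`.
#' @return The class entry: a list with `lpred`, `rpred` (overlap indices),
#'   `members` and `backs`.
#' @export
class_of <- function(word, g) {
  if (!(word %in% g$pattern$words)) {
    stop("'", word, "' is not a pattern word", call. = FALSE)
  }
  wl <- g$word_lpred[[word]]
  wr <- g$word_rpred[[word]]
  for (cl in g$classes) {
    if (cl$lpred == wl && cl$rpred == wr) return(cl)
  }
  stop("internal error: class not found")   # nocov
}

#' Export an overlap graph in DOT format
#'
#' Left edges are solid and labeled with `Back(w)`, right edges dashed,
#' deep edges bold and labeled with the class members.
#'
#' @param g An `mp_ovgraph`.
#' @param file Output path (or `""` to return the text invisibly).
#' @return Invisibly, the DOT text.
#' @export
write_dot <- function(g, file = "") {
  lab <- ifelse(g$nodes == "", "&epsilon;", g$nodes)
  lines <- c("digraph ovgraph {",
             sprintf('  n%d [label="%s"];', seq_len(g$n_nodes), lab))
  for (i in seq_len(g$n_nodes)[-1L]) {
    lines <- c(lines,
               sprintf('  n%d -> n%d [style=solid, label="%s"];',
                       g$lpred[i], i, g$back[i]),
               sprintf("  n%d -> n%d [style=dashed];", g$rpred[i], i))
  }
  for (cl in g$classes) {
    lines <- c(lines,
               sprintf('  n%d -> n%d [style=bold, label="%s"];',
                       cl$lpred, cl$rpred,
                       paste(cl$members, collapse = ",")))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (nzchar(file)) writeLines(txt, file)
  invisible(txt)
}
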