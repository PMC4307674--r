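#' Patterns: finite sets of equal-length words
#'
#' A pattern is a non-empty set of distinct words, all of the same length
#' `m`, over a common alphabet.  Occurrence statistics are computed for the
#' whole set: an occurrence is a text position at which some pattern word
#' ends.
#'
#' @name pattern
NULL

new_pattern <- function(words, alphabet) {
  words <- unique(toupper_if(words, alphabet))
  if (length(words) == 0L) {
    stop("pattern is empty", call. = FALSE)
  }
  m <- unique(nchar(words))
  if (length(m) != 1L) {
    stop("all pattern words must have the same length (lengths seen: ",
         paste(sort(m), collapse = ", "), ")", call. = FALSE)
  }
  if (m < 1L) stop("pattern words must be non-empty", call. = FALSE)
  check_over_alphabet(words, alphabet)
  structure(list(words = sort(words), m = as.integer(m), alphabet = alphabet),
            class = "mp_pattern")
}

# words are upper-cased only when the alphabet itself is upper case,
# so lower-case alphabets (e.g. {a,b}) are left alone
toupper_if <- function(words, alphabet) {
  if (all(alphabet$symbols == toupper(alphabet$symbols))) toupper(words) else words
}

#' @export
print.mp_pattern <- function(x, ...) {
  cat("Pattern of ", length(x$words), " word(s), length m = ", x$m, "\n",
      sep = "")
  shown <- utils::head(x$words, 8L)
  cat("  ", paste(shown, collapse = " "),
      if (length(x$words) > 8L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Build a pattern from an explicit word list
#'
#' Duplicate words are collapsed (set semantics); words of unequal length or
#' containing characters outside the alphabet are an error.
#'
#' @param words Character vector of words.
#' @param alphabet An [alphabet()]; defaults to DNA.
#' @return An `mp_pattern` object.
#' @examples
#' pattern_words(c("ACAGCTA", "ACATATA", "CTTTCGC", "TACCACA"))
#' @export
pattern_words <- function(words, alphabet = dna_alphabet()) {
  if (length(words) == 0L) stop("no words given", call. = FALSE)
  new_pattern(words, alphabet)
}

#' Build a pattern from a scoring matrix and a cutoff
#'
#' The pattern consists of all words whose additive score under the
#' position-specific scoring matrix (PSSM) exceeds the cutoff.  The score of
#' a word is the sum over positions of the matrix entry for the letter at
#' that position.  Enumeration is by depth-first branch and bound: a partial
#' word is abandoned as soon as its score plus the best possible completion
#' cannot reach the cutoff.
#'
#' @param scores Numeric matrix, `m` rows (positions) by `|V|` columns
#'   (letters).  Column names, when present, must name alphabet symbols and
#'   override the alphabet's declared column order.
#' @param cutoff Numeric score threshold.
#' @param alphabet An [alphabet()].
#' @param strict If `TRUE` (default) keep words with score strictly greater
#'   than `cutoff`; if `FALSE` use greater-or-equal, as some PSSM tools do.
#' @return An `mp_pattern` with every matching word.
#' @examples
#' s <- matrix(c(1, 1, 0, 0), nrow = 2,
#'             dimnames = list(NULL, c("a", "b")))
#' pattern_from_pssm(s, cutoff = 0.5, alphabet = alphabet(c("a", "b")))
#' @export
pattern_from_pssm <- function(scores, cutoff, alphabet = dna_alphabet(),
                              strict = TRUE) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop("PSSM must be numeric", call. = FALSE)
  nv <- length(alphabet$symbols)
  if (ncol(scores) != nv) {
    stop("PSSM must have one column per alphabet symbol (expected ", nv,
         ", got ", ncol(scores), ")", call. = FALSE)
  }
  if (!is.null(colnames(scores))) {
    if (!setequal(colnames(scores), alphabet$symbols)) {
      stop("PSSM column names must be the alphabet symbols", call. = FALSE)
    }
    scores <- scores[, alphabet$symbols, drop = FALSE]
  }
  m <- nrow(scores)
  keep <- if (strict) {
    function(x) x > cutoff
  } else {
    function(x) x >= cutoff
  }
  # best achievable score from position i onwards (inclusive)
  best_tail <- rev(cumsum(rev(apply(scores, 1L, max))))
  best_tail <- c(best_tail, 0)
  acc <- new.env(parent = emptyenv())
  acc$words <- character(0)
  recurse <- function(prefix, score, i) {
    if (!keep(score + best_tail[i])) return(invisible(NULL))
    if (i > m) {
      acc$words[length(acc$words) + 1L] <- prefix
      return(invisible(NULL))
    }
    for (j in seq_len(nv)) {
      recurse(paste0(prefix, alphabet$symbols[j]), score + scores[i, j], i + 1L)
    }
  }
  recurse("", 0, 1L)
  if (length(acc$words) == 0L) {
    stop("no word scores ", if (strict) "above" else "at or above",
         " the cutoff ", cutoff, ": pattern is empty", call. = FALSE)
  }
  new_pattern(acc$words, alphabet)
}

# IUPAC nucleotide degeneracy codes
iupac_dna <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand a degenerate word into a pattern
#'
#' Each position of `word` is a degeneracy code standing for a set of
#' symbols; the pattern is the Cartesian product of the per-position sets.
#' For the DNA alphabet the standard IUPAC codes are understood; for other
#' alphabets a `codes` list (code -> character vector of symbols) must be
#' supplied, and plain symbols always stand for themselves.
#'
#' @param word Degenerate word.
#' @param alphabet An [alphabet()].
#' @param codes Optional named list of degeneracy codes.
#' @return An `mp_pattern`.
#' @examples
#' pattern_degenerate("ACR")   # {ACA, ACG}
#' @export
pattern_degenerate <- function(word, alphabet = dna_alphabet(), codes = NULL) {
  if (is.null(codes)) {
    codes <- if (identical(alphabet$symbols, c("A", "C", "G", "T"))) {
      iupac_dna
    } else {
      stats::setNames(as.list(alphabet$symbols), alphabet$symbols)
    }
  }
  cc <- chars(toupper_if(word, alphabet))
  sets <- lapply(cc, function(ch) {
    s <- codes[[ch]]
    if (is.null(s)) {
      stop("unknown degeneracy code '", ch, "'", call. = FALSE)
    }
    s
  })
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)[rev(seq_along(sets))]
  new_pattern(do.call(paste0, grid), alphabet)
}

#' Hamming ball around a word
#'
#' All words at Hamming distance at most `d` from `word`.  The ball
#' saturates at the full set of length-`m` words when `d >= m`.
#'
#' @param word Center word.
#' @param d Maximum number of mismatches (non-negative integer).
#' @param alphabet An [alphabet()].
#' @return An `mp_pattern` of size `sum(choose(m, 0:d) * (|V|-1)^(0:d))`
#'   (capped at `|V|^m`).
#' @examples
#' pattern_mismatch("AA", 1)   # 7 words
#' @export
pattern_mismatch <- function(word, d, alphabet = dna_alphabet()) {
  if (length(d) != 1L || is.na(d) || d < 0 || d != floor(d)) {
    stop("mismatch count d must be a non-negative integer", call. = FALSE)
  }
  word <- toupper_if(word, alphabet)
  check_over_alphabet(word, alphabet)
  cc <- chars(word)
  m <- length(cc)
  acc <- new.env(parent = emptyenv())
  acc$words <- character(0)
  recurse <- function(prefix, i, left) {
    if (i > m) {
      acc$words[length(acc$words) + 1L] <- prefix
      return(invisible(NULL))
    }
    for (s in alphabet$symbols) {
      cost <- if (s == cc[i]) 0L else 1L
      if (cost <= left) recurse(paste0(prefix, s), i + 1L, left - cost)
    }
  }
  recurse("", 1L, as.integer(min(d, m)))
  new_pattern(acc$words, alphabet)
}

#' Reverse complement of words and patterns
#'
#' `reverse_complement()` maps a word to its reverse complement;
#' `add_reverse_complement()` augments a pattern with the reverse
#' complements of all its words, so occurrences on both strands are
#' counted.  The operation is idempotent and at most doubles the pattern.
#'
#' @param word A word over an alphabet with a complement map.
#' @param p An `mp_pattern` whose alphabet has a complement map.
#' @param alphabet An [alphabet()].
#' @return A word, or the strand-symmetric `mp_pattern`.
#' @examples
#' reverse_complement("AAGT")
#' add_reverse_complement(pattern_words("ACGT"))
#' @export
reverse_complement <- function(word, alphabet = dna_alphabet()) {
  comp <- alphabet$complement
  if (is.null(comp)) {
    stop("alphabet has no complement map", call. = FALSE)
  }
  vapply(word, function(w) {
    paste(rev(unname(comp[chars(w)])), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' @rdname reverse_complement
#' @export
add_reverse_complement <- function(p) {
  stopifnot(inherits(p, "mp_pattern"))
  rc <- reverse_complement(p$words, p$alphabet)
  new_pattern(c(p$words, rc), p$alphabet)
}
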