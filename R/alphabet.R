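#' Define a finite alphabet
#'
#' An alphabet is an ordered set of distinct single characters, optionally
#' equipped with a complement map (an involution on the symbols) so that
#' reverse complements of words are defined.
#'
#' @param symbols Character vector of distinct single characters, in the
#'   order used by score matrices and model files.
#' @param complement Optional named character vector mapping each symbol to
#'   its complement; must be a self-inverse permutation of `symbols`.
#' @return An object of class `mp_alphabet` with elements `symbols` and
#'   `complement` (or `NULL`).
#' @examples
#' alphabet(c("a", "b"))
#' dna_alphabet()
#' @export
alphabet <- function(symbols, complement = NULL) {
  symbols <- as.character(symbols)
  if (length(symbols) < 2L) {
    stop("an alphabet needs at least 2 symbols", call. = FALSE)
  }
  if (anyDuplicated(symbols)) {
    stop("alphabet symbols must be distinct", call. = FALSE)
  }
  if (any(nchar(symbols) != 1L)) {
    stop("alphabet symbols must be single characters", call. = FALSE)
  }
  if (!is.null(complement)) {
    complement <- complement[symbols]
    if (anyNA(complement) || !setequal(complement, symbols)) {
      stop("complement must map every symbol onto the alphabet", call. = FALSE)
    }
    # involution: complement of the complement is the identity
    if (!identical(unname(complement[complement]), symbols)) {
      stop("complement map must be self-inverse", call. = FALSE)
    }
  }
  structure(list(symbols = symbols, complement = complement),
            class = "mp_alphabet")
}

#' @rdname alphabet
#' @export
dna_alphabet <- function() {
  alphabet(c("A", "C", "G", "T"),
           complement = c(A = "T", C = "G", G = "C", T = "A"))
}

#' @export
print.mp_alphabet <- function(x, ...) {
  cat("Alphabet: {", paste(x$symbols, collapse = ", "), "}",
      if (!is.null(x$complement)) " with complement" else "", "\n", sep = "")
  invisible(x)
}

# split a word into single characters
chars <- function(word) strsplit(word, "", fixed = TRUE)[[1L]]

check_over_alphabet <- function(words, alph) {
  letters_used <- unique(unlist(strsplit(words, "", fixed = TRUE)))
  bad <- setdiff(letters_used, alph$symbols)
  if (length(bad) > 0L) {
    stop("character(s) not in alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
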