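#' Read and write pattern word lists
#'
#' Word-list files are plain text with one word per line; `#` starts a
#' comment (whole-line or trailing) and blank lines are ignored.
#'
#' @param file Path.
#' @param alphabet An [alphabet()].
#' @param p An `mp_pattern`.
#' @return `read_pattern_words()` returns an `mp_pattern`;
#'   `write_pattern_words()` returns the path invisibly.
#' @export
read_pattern_words <- function(file, alphabet = dna_alphabet()) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  words <- lines[nzchar(lines)]
  if (length(words) == 0L) {
    stop("no words found in '", file, "'", call. = FALSE)
  }
  tryCatch(pattern_words(words, alphabet), error = function(e) {
    stop("while reading '", file, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' @rdname read_pattern_words
#' @export
write_pattern_words <- function(p, file) {
  stopifnot(inherits(p, "mp_pattern"))
  writeLines(p$words, file)
  invisible(file)
}

#' Read and write scoring matrices
#'
#' A PSSM file is a whitespace-delimited numeric matrix with `m` rows
#' (positions) and one column per alphabet symbol.  An optional single
#' header line may name the columns, overriding the alphabet's declared
#' order; `#` comment lines are ignored.
#'
#' @param file Path.
#' @param alphabet An [alphabet()].
#' @param scores Numeric matrix to write.
#' @return `read_pssm()` returns the numeric score matrix with the
#'   alphabet's symbols as column names.
#' @export
read_pssm <- function(file, alphabet = dna_alphabet()) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty PSSM file '", file, "'", call. = FALSE)
  fields <- strsplit(lines, "[ \t]+")
  header <- NULL
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  if (anyNA(first)) {
    header <- fields[[1L]]
    fields <- fields[-1L]
    if (!setequal(header, alphabet$symbols)) {
      stop("PSSM header must name the alphabet symbols", call. = FALSE)
    }
  }
  nv <- length(alphabet$symbols)
  rows <- lapply(seq_along(fields), function(i) {
    x <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(x) || length(x) != nv) {
      stop("PSSM line ", i + length(header %||% integer(0)) / nv,
           ": expected ", nv, " numbers, got '",
           paste(fields[[i]], collapse = " "), "'", call. = FALSE)
    }
    x
  })
  scores <- do.call(rbind, rows)
  colnames(scores) <- header %||% alphabet$symbols
  scores[, alphabet$symbols, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_pssm
#' @export
write_pssm <- function(scores, file) {
  scores <- as.matrix(scores)
  lines <- apply(format(scores, trim = TRUE), 1L, paste, collapse = "\t")
  if (!is.null(colnames(scores))) {
    lines <- c(paste(colnames(scores), collapse = "\t"), lines)
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read and write probability-model files
#'
#' Models are stored as JSON with a `type` field selecting the schema:
#' \describe{
#'   \item{`bernoulli`}{`alphabet` (symbols) and `probs` (one per symbol).}
#'   \item{`markov`}{`alphabet`, `order`, `transitions` (object mapping
#'     each length-K context to its letter distribution) and optional
#'     `start` (`"stationary"` or `"uniform"`).}
#'   \item{`hmm`}{`alphabet`, `states`, `initial` and `transitions`, a list
#'     of `{from, symbol, to, prob}` entries (absent triples have
#'     probability 0).}
#' }
#' An optional `complement` object (symbol to symbol) equips the alphabet
#' with a complement map.
#'
#' @param file Path to a JSON model file.
#' @param model An `mp_hmm` (written in the `hmm` schema).
#' @return `read_model()` returns a validated `mp_hmm`.
#' @export
read_model <- function(file) {
  spec <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  if (is.null(spec$type)) stop("model file lacks a 'type' field", call. = FALSE)
  if (!spec$type %in% c("bernoulli", "markov", "hmm")) {
    stop("unknown model type '", spec$type, "'", call. = FALSE)
  }
  comp <- NULL
  if (!is.null(spec$complement)) {
    comp <- unlist(spec$complement)
  }
  alph <- alphabet(unlist(spec$alphabet), complement = comp)
  switch(spec$type,
    bernoulli = {
      pr <- unlist(spec$probs)
      bernoulli_hmm(pr, alph)
    },
    markov = {
      K <- as.integer(spec$order)
      tm <- do.call(rbind, spec$transitions)
      rownames(tm) <- names(spec$transitions)
      colnames(tm) <- alph$symbols
      markov_hmm(K, tm, alph, start = spec$start %||% "stationary")
    },
    hmm = {
      states <- unlist(spec$states)
      nq <- length(states)
      nv <- length(alph$symbols)
      pi <- array(0, dim = c(nq, nv, nq),
                  dimnames = list(states, alph$symbols, states))
      tr <- spec$transitions
      if (is.data.frame(tr)) {
        for (i in seq_len(nrow(tr))) {
          pi[tr$from[i], tr$symbol[i], tr$to[i]] <- tr$prob[i]
        }
      } else {
        for (e in tr) pi[e$from, e$symbol, e$to] <- e$prob
      }
      hmm(pi, alph, initial = spec$initial %||% states[1L])
    },
    stop("unknown model type '", spec$type, "'", call. = FALSE)
  )
}

#' @rdname read_model
#' @export
write_model <- function(model, file) {
  stopifnot(inherits(model, "mp_hmm"))
  nz <- which(model$pi > 0, arr.ind = TRUE)
  entries <- data.frame(
    from = model$states[nz[, 1L]],
    symbol = model$alphabet$symbols[nz[, 2L]],
    to = model$states[nz[, 3L]],
    prob = model$pi[nz],
    stringsAsFactors = FALSE
  )
  spec <- list(type = "hmm",
               alphabet = model$alphabet$symbols,
               states = model$states,
               initial = model$states[model$initial],
               transitions = entries)
  if (!is.null(model$alphabet$complement)) {
    spec$complement <- as.list(model$alphabet$complement)
  }
  jsonlite::write_json(spec, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Random patterns and models for testing and benchmarking
#'
#' `random_pattern()` draws `n_words` distinct words of length `m`
#' uniformly.  `random_hmm()` follows the randomized construction used in
#' benchmark studies of this algorithm family: for each state, `n_trans`
#' target states are drawn; every letter towards a chosen target gets an
#' independent uniform positive weight; weights are normalized so each
#' state's outgoing mass is 1.  With `n_trans = 1` the model is
#' deterministic.  Both use the current RNG state — set a seed for
#' reproducibility.
#'
#' @param n_words Number of words to draw.
#' @param m Word length.
#' @param alphabet An [alphabet()].
#' @param n_states Number of model states.
#' @param n_trans Targets per state (`1 <= n_trans <= n_states`).
#' @return An `mp_pattern` / `mp_hmm`.
#' @export
random_pattern <- function(n_words, m, alphabet = dna_alphabet()) {
  V <- alphabet$symbols
  if (n_words > length(V)^m) {
    stop("cannot draw ", n_words, " distinct words of length ", m, call. = FALSE)
  }
  words <- character(0)
  while (length(words) < n_words) {
    more <- replicate(n_words - length(words),
                      paste(sample(V, m, replace = TRUE), collapse = ""))
    words <- unique(c(words, more))
  }
  pattern_words(words, alphabet)
}

#' @rdname random_pattern
#' @export
random_hmm <- function(n_states, n_trans, alphabet = dna_alphabet()) {
  stopifnot(n_trans >= 1L, n_trans <= n_states)
  nv <- length(alphabet$symbols)
  states <- paste0("q", seq_len(n_states))
  pi <- array(0, dim = c(n_states, nv, n_states),
              dimnames = list(states, alphabet$symbols, states))
  for (q in seq_len(n_states)) {
    targets <- sample.int(n_states, n_trans)
    w <- matrix(stats::runif(nv * n_trans), nv, n_trans)
    pi[q, , targets] <- w / sum(w)
  }
  hmm(pi, alphabet)
}

#' Write a reproducible set of test fixtures
#'
#' Generates word-list, PSSM and model files (Bernoulli, order-1 Markov,
#' and random HMMs of the benchmark construction) under `dir`.  The same
#' seed always produces identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @param alphabet An [alphabet()].
#' @return Invisibly, the vector of file paths written.
#' @export
generate_fixtures <- function(dir, seed, alphabet = dna_alphabet()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- character(0)
  put <- function(name) {
    paths[length(paths) + 1L] <<- file.path(dir, name)
    file.path(dir, name)
  }
  write_pattern_words(random_pattern(8L, 6L, alphabet), put("pattern8x6.txt"))
  sc <- matrix(round(stats::rnorm(6L * length(alphabet$symbols)), 3), nrow = 6L)
  colnames(sc) <- alphabet$symbols
  write_pssm(sc, put("pssm6.txt"))
  nv <- length(alphabet$symbols)
  bp <- stats::runif(nv)
  bp <- bp / sum(bp)
  jsonlite::write_json(list(type = "bernoulli", alphabet = alphabet$symbols,
                            probs = bp),
                       put("bernoulli.json"), auto_unbox = TRUE, digits = NA)
  tm <- matrix(stats::runif(nv * nv), nv, nv)
  tm <- tm / rowSums(tm)
  jsonlite::write_json(
    list(type = "markov", alphabet = alphabet$symbols, order = 1L,
         transitions = stats::setNames(lapply(seq_len(nv), function(i) tm[i, ]),
                                       alphabet$symbols),
         start = "stationary"),
    put("markov1.json"), auto_unbox = TRUE, digits = NA)
  write_model(random_hmm(2L, 1L, alphabet), put("hmm2_det.json"))
  write_model(random_hmm(3L, 3L, alphabet), put("hmm3_dense.json"))
  invisible(paths)
}
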