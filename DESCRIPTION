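Package: motifpv
Title: Exact P-Values for Pattern Occurrence Counts in Random Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact computation of the probability that a random text of
    length N, generated by a hidden Markov model, contains at least S
    occurrences of a pattern (a finite set of equal-length words).  The
    core engine runs dynamic-programming recursions over an overlap graph
    built from the Aho-Corasick trie of the pattern, so its cost scales
    with the number of word overlaps rather than with the full automaton.
    Bernoulli and order-K Markov backgrounds are handled as special hidden
    Markov models.  Patterns can be given as word lists, position-specific
    scoring matrices with a cutoff, IUPAC degenerate words, or Hamming
    balls around a word, optionally augmented with reverse complements.
    Two independent reference implementations (exhaustive text enumeration
    and an automaton-product Markov chain embedding) are included for
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
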