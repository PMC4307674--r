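# motifpv

Exact P-values for pattern occurrence counts in random texts.

## The problem

Motif-finding pipelines score a candidate region by asking: how surprising
is it that this sequence contains `S` or more hits of a motif?  The
standard answer is the P-value

    Prob(B(N, S)) = Prob( a random text of length N contains
                          at least S occurrences of the pattern H )

where the pattern `H` is a finite set of words of one common length `m`
(for example, all 12-mers scoring above a cutoff under a transcription
factor's position weight matrix, on both strands), an *occurrence* is a
text position at which some pattern word ends, and the random text is
generated by a background model.  `motifpv` computes this probability
**exactly**, in double precision, for the most general background in
common use — a hidden Markov model `⟨Q, q0, π⟩` with
`π(q̃, a, q) = Prob(emit letter a and move q̃ → q)` — with Bernoulli and
order-K Markov backgrounds handled as special cases of the HMM.

## The algorithm

Naive dynamic programming over the Aho-Corasick automaton costs time
proportional to the automaton size, which grows like `m·|H|`.  The engine
here instead recurses over the **overlap graph** of the pattern: nodes are
the overlaps (strings that are simultaneously a proper suffix of one
pattern word and a proper prefix of another, plus the empty word), with

* *left edges* `lpred(w) → w` (`lpred(w)` = longest overlap that is a
  proper prefix of `w`, with label `Back(w)` so that
  `w = lpred(w)·Back(w)`),
* *right edges* `rpred(w) → w` (longest overlap proper suffix), and
* *deep edges* `(w, r)`, one per equivalence class of pattern words
  sharing `lpred = w` and `rpred = r` — so the words themselves never
  appear as nodes.

The P-value follows by induction on the text length `n = m+1 … N` and the
occurrence count `s = 1 … S`, classifying texts by how their final pattern
occurrence overlaps the `s`-th one.  All unions in the recursion are
disjoint, so probabilities add; per stage the work is one pass down the
left/deep edges (carrying `D`-set probabilities) and one pass up the right
edges (aggregating `R`-set probabilities in circular buffers), each value
resolved per HMM state.  The number of overlaps is typically close to
`|H|` for random patterns and far below `0.1·|H|` for PSSM-derived ones,
which is where the method earns its keep.

Two independent reference implementations ship with the package and are
used by the test suite to cross-validate every computation path:
`pvalue_enumerate()` (exhaustive enumeration of all `|V|^N` texts) and
`pvalue_automaton()` (the classical Markov chain embedding on
automaton-state × HMM-state × capped count).

## Worked example

```r
library(motifpv)

p <- pattern_words(c("ACAGCTA", "ACATATA", "CTTTCGC", "TACCACA"))
g <- overlap_graph(p)
g$nodes
#> [1] ""    "A"   "ACA" "C"   "TA"
graph_stats(g)[c("n_overlaps", "n_classes", "n_left_edges",
                 "n_right_edges", "n_deep_edges")]
#> $n_overlaps    [1] 5
#> $n_classes     [1] 3
#> $n_left_edges  [1] 4
#> $n_right_edges [1] 4
#> $n_deep_edges  [1] 3

count_occurrences("CTTTCGCCGAATCACAGCTA", p)
#> [1] 2

mod <- bernoulli_hmm(rep(0.25, 4))        # uniform DNA background
pattern_pvalue(p, mod, N = 20, S = 1)
#> Prob(at least 1 occurrence(s) in a text of length 20) = 3.4096342E-03

pvalue_automaton(p, mod, 20, 1)           # independent cross-check
#> [1] 0.003409634
```

The five overlaps, three word classes and the edge counts describe the
graph the engine walks; the P-value says a ~0.34% chance that a random
20-mer contains one of the four words.  Patterns can equally come from a
scoring matrix (`pattern_from_pssm()`), an IUPAC degenerate word
(`pattern_degenerate()`), a Hamming ball (`pattern_mismatch()`), or a file
(`read_pattern_words()`, `read_pssm()`), and can be made strand-symmetric
with `add_reverse_complement()`.  Backgrounds come from `bernoulli_hmm()`,
`markov_hmm()`, `hmm()` or a JSON model file via `read_model()`.

A command-line driver is installed under `exec/`:

```sh
motifpv --pattern words.txt --model background.json --length 1000 --count 10
```

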