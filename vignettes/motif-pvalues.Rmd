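---
title: "Exact occurrence-count P-values over overlap graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact occurrence-count P-values over overlap graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifpv)
```

## The statistic

Given a pattern `H` — a non-empty set of distinct words of one length `m`
over an alphabet `V` — and a random text of length `N` generated by a
hidden Markov model, `motifpv` computes

    Prob(B(N, S)) = Prob(the text contains at least S occurrences of H),

where an occurrence is a position at which some word of `H` ends.  Because
all words share one length, at most one word ends at any position, so the
occurrence count of a text is well defined.  `S = 0` gives 1 by
convention, and `N < m` gives 0.

The background is a hidden Markov model `⟨Q, q0, π⟩` in emission-transition
form: `π(q̃, a, q)` is the probability, in state `q̃`, of emitting letter
`a` while moving to state `q`, with total outgoing mass 1 from every
state.  This form subsumes the backgrounds used in sequence analysis:

* **Bernoulli**: one state, `π(q, a, q)` = the letter frequency;
* **order-K Markov**: a deterministic HMM whose states are the contexts of
  length `0 … K` (short contexts are explicit start-up states, so texts of
  any length are covered);
* general HMMs, e.g. compositional-segment models fitted elsewhere.

The initial condition is a point mass on a single start state.  A start
*distribution* can always be emulated by adding one silent-start-like
state whose outgoing probabilities mix the desired initial law into the
first emission; we did not add a separate interface for it.

## Why an overlap graph

The classical exact method embeds the problem in a Markov chain on
(Aho-Corasick automaton state) × (model state) × (occurrence count capped
at `S`).  Its cost is driven by the automaton size, which is of order
`m·|H|`.  The engine here instead walks the *overlap graph*: its nodes are
the strings that are simultaneously a proper suffix of one pattern word
and a proper prefix of another (plus the empty word ε).  For each
non-root overlap `w`, `lpred(w)` and `rpred(w)` are the longest overlap
proper prefix and suffix; `Back(w)` completes `lpred(w)` to `w`.  Pattern
words with equal `(lpred, rpred)` form equivalence classes, each drawn as
one *deep edge* — the words themselves are never graph nodes.  Overlap
counts are usually close to `|H|` for random word sets and an order of
magnitude below `|H|` for cutoff-defined PSSM patterns, which is the
source of the method's advantage.

Overlap discovery uses the Aho-Corasick trie: a trie node is an overlap
exactly when it lies on a suffix-link chain starting from a terminal node
(that chain enumerates precisely the trie-resident suffixes of the word).
We mark suffix-link ancestors of all terminals in one pass; `lpred` is the
deepest marked proper ancestor on the trie path, `rpred` the first marked
node on the suffix-link chain.  The trie is kept only as long as the graph
is being built (the automaton oracle rebuilds its own).

## The recursion

Probabilities are propagated per model state.  Writing `Prob(X, q)` for
the probability of emitting a text in set `X` and ending in state `q`, the
engine advances stages `n = m+1 … N`, and within each stage occurrence
counts `s = 1 … S`, over these text families:

* `B(n, s)`: texts with at least `s` occurrences — the answer;
* `E(n, s, r)`: as `B`, additionally ending with a word whose `rpred` is
  `r`;
* `RE(n, s, r) = E(n, s, r) \ E(n, s+1, r)`: exactly `s` occurrences;
* `R(n, s, w)`: exactly `s` occurrences, ending with a word that has
  suffix `w` — obtained from the `RE` values bottom-up along right edges;
* `D(k, s, w)`: length-`k` texts with at least `s` occurrences, ending
  with `w`, whose `s`-th occurrence intersects that suffix — carried down
  the left tree via `D(parent) · Back(w) ∪ R(k(n,w), s, w)` with
  `k(n, w) = n − m + len(w)`.

`E(n, s+1, r)` splits disjointly into texts whose `s`-th occurrence does
not intersect the final one (`B(n−m, s)` concatenated with the words of
`r`'s class set) and, per deep edge `(w, r)`, texts where it does
(`D(k(n,w), s, w)` concatenated with the class's `Back` words).  All the
unions involved are disjoint, so every probability is a pure sum; set
concatenation becomes a `|Q| × |Q|` matrix product of precomputed word-set
matrices.  One stage therefore costs one pass down the left/deep edges and
one pass up the right edges, `O(S·|Q|²·(|OV| + |H|))` arithmetic in total
per stage.

Concretely, for each right deep node we accumulate the `(S+1) × |Q|` array
of `E(n, s, r)` values (`s = 1` directly from `Prob(V^{n−m})`; `s ≥ 2`
from the lagged `B` values plus the deep-edge contributions) and take
first differences in `s` to obtain `RE`.  This is the same telescoping
arithmetic as accumulating the `F`/`C′` differences term by term, but
organized per node so that each step is one vectorized matrix operation —
the natural formulation in R.  For the same reason the per-node `D`
arrays for a whole stage are kept live (at most `|OV|` small matrices)
rather than allocated and released along a depth-first recursion; the
asymptotic memory bound is unchanged.

`R`-set probabilities are stored in per-node circular buffers of depth
`m − len(w)` (the window of lengths `k(n, w) … n−1` the recursion can
reference).  Because the window depth for the root equals `m`, writing the
stage-`n` row would overwrite the row for `n − m`; the engine therefore
reads all old rows (parts 1 and 2 of a stage) strictly before writing
(part 3).  After the last stage, `B` is rolled forward the final `m` steps
from `B(N−m)` using the buffered root `R` values, and the P-value is the
sum of `Prob(B(N, S), q)` over states.

### Reachable-state sets

For pruning and introspection, `state_sets()` computes `AllState(w)` (the
states reachable from the start by some text with suffix `w`) and
`PriorState(w, q)` (the states of `AllState(lpred(w))` from which `q` is
reachable while emitting `Back(w)`).  `AllState` quantifies over
infinitely many texts; it is evaluated in closed form as the image of
`w`'s word matrix over the closure `R∞` of states reachable from the
start by texts of any length — equivalent, because every prefix leaves
the chain somewhere in `R∞` and every state of `R∞` is realized by some
prefix.  The engine itself stores dense `|Q| × |Q|` matrices whose
entries outside these sets are structurally zero: in R, dense
linear-algebra primitives beat bookkeeping over index subsets at the
state-space sizes the package targets (tens of states).  For an order-K
Markov background, `AllState(w)` with `len(w) ≥ K` is a single context
state, and the zeros make the dense products equivalent to the pruned
ones.

## Numerical choices

* Plain double precision in probability space, no log-space: the engine
  only ever adds and multiplies probabilities of disjoint events, so
  cancellation is confined to the `RE = E(s) − E(s+1)` difference, where
  both terms are exact sums of the same scale.  Doubles reach ~1e-308;
  P-values that small are far beyond any practical significance
  threshold.  Results in `(0, 1e-300)` are reported as 0 with a warning.
* Final values are clamped to `[0, 1]` to absorb last-bit roundoff.
* Model validation: outgoing mass per state must equal 1 within `1e-9`
  absolute; the stationary start-up law of a Markov embedding is the
  unit-eigenvalue eigenvector of the context chain, sign-normalized and
  renormalized.
* PSSM cutoffs compare strictly (`score > cutoff`) by default, since a
  cutoff is conventionally quoted as the largest rejected score; tools
  that include the boundary are served by `strict = FALSE`.
* Degenerate cases are first-class: `m = 1` collapses the graph to the
  root only (all classes on the root, no `D` terms — occurrences of
  single letters cannot overlap); patterns with no self-overlap have only
  the root node and the recursion reduces to the lagged `B` update.

## Randomized test instances

`random_pattern()` draws distinct words uniformly; `random_hmm()` follows
the standard benchmark construction for this algorithm family: each state
chooses `n_trans` target states, every letter toward a chosen target
receives an independent uniform weight, and rows are normalized
(`n_trans = 1` yields deterministic models, the Markov-like extreme;
`n_trans = n_states` yields dense ones).  These generators emulate the
*combinatorial* structure of real inputs — overlap-rich word sets,
sparse-to-dense state graphs — but not the letter composition or fitted
parameters of genomic backgrounds; a pass over them certifies the
arithmetic, not the biological realism of any particular background.

The test suite validates the engine against exhaustive enumeration on
binary-alphabet instances (up to `N = 10`, `S = 3`, across Bernoulli and
random 2/3-state models) and against the automaton-product implementation
at realistic scale (a 60-word DNA pattern of length 12, `N = 1000`,
`S = 10`, under Bernoulli, order-1 Markov and 3-state HMM backgrounds).
These sizes keep the whole suite under a minute while exercising every
code path several hundred times; both cross-checks agree to near machine
precision, far inside the `1e-12` absolute / `1e-10` relative margins the
tests assert.

## Limitations

* No parameter estimation: backgrounds are taken as given (fit them with
  your favourite HMM/Markov tooling and export to the JSON schema).
* Markov backgrounds run through the generic HMM engine; a specialized
  order-K implementation could exploit context determinism further.
* Cost is linear in `N` and `S` jointly; for `N` in the millions a
  doubling/divide-and-conquer scheme would win, and is not implemented.
* The reverse-complement option requires an alphabet with a complement
  map; protein alphabets work everywhere else.
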