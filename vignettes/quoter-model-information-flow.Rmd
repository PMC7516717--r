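---
title: "Information flow in the quoter model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information flow in the quoter model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(quoterflow)
```

## The model

The quoter model idealizes how people in an online social network produce
text. Each node of an undirected graph grows a timestamped stream of word
ids. At each of `T = steps_per_node * N` time steps one node (the *ego*)
acts. With probability `q` it *quotes*: it picks a neighbour (the *alter*)
uniformly at random and appends a copy of a contiguous random segment of the
alter's past stream. Otherwise it generates fresh content by sampling words
i.i.d. from a Zipf vocabulary: word of rank r has probability
`r^(-alpha) / H(z, alpha)` over a vocabulary of `z` words. Both quote and
fresh-content lengths are Poisson(`lam`). Defaults are the study conditions
used throughout the package: `q = 0.5`, `lam = 3`, `z = 1000`,
`alpha = 1.5`, and `steps_per_node = 1000`, so a node ends up with roughly
`1000 * lam = 3000` words — enough for the entropy estimators below to
behave stably.

Quoting moves predictive information along edges without any notion of
discrete "infection", which is exactly what makes the model interesting to
compare against contagion: information flow is read off the generated text,
not off adoption events.

## Measuring flow: match-length estimators

The entropy rate of a stream of length `T` is estimated nonparametrically as
`h = T log2(T) / sum(Lambda_t)`, where the match length `Lambda_t` is the
length of the shortest substring starting at position `t` that does not
occur in the stream's past. The same construction gives a cross-entropy
between two streams A and B,

```
hx(A | B) = TA * log2(TB) / sum_t Lambda_t(A | B),
```

where position `t` of A is matched only against the words of B written
*strictly before* the time of A's t-th word. This temporal precedence makes
`hx` a directed measure: B's past predicting A's future. Lower `hx` means
more information flow from B (the alter) to A (the ego). The production
matcher is an online suffix automaton grown over B in time order (amortized
linear work); its contract is exact equality with a transparent quadratic
scan (`match_length()`), enforced on thousands of random instances in the
test suite.

Two conventions needed fixing where the verbal definition runs out:

* **End of sequence.** If the source is exhausted while still matching,
  `Lambda_t = remaining + 1`, the standard convention for this family of
  estimators.
* **Self matching.** For the entropy rate, the past of position `t` is the
  stream's first `t - 1` words, and a match must lie fully inside that past
  — the same "past only" semantics the cross-entropy uses. Target words with
  timestamps exactly equal to `time(A_t)` are excluded (strict inequality).

**Predictability.** Fano's inequality converts an entropy into the maximal
success probability of an ideal next-word predictor:
`predictability(h, z)` returns the largest `Pi` with
`h(Pi) + (1 - Pi) log2(z - 1) = h`. On `[1/z, 1]` the left-hand side falls
monotonically from `log2 z` to 0, so the root is found by bisection
(tolerance 1e-12, checked against an independent two-stage grid scan).
Finite-sample estimates occasionally exceed `log2 z`; these are clamped with
a warning rather than erroring.

**Estimator bias.** The match-length estimator converges slowly — the error
decays like `1/log T` — and at desk-scale stream lengths it sits *below*
the true entropy of i.i.d. Zipf text (the acceptance suite measures this gap
directly for `z = 1000`, `alpha = 1.5` at `T ~ 3000`). Comparisons in this
package are therefore always *relative*: the same estimator at the same
stream length across structures, where the common bias cancels. Absolute
agreement with analytic entropies should not be expected at these lengths.

## Contagion baselines

`simulate_sir()` is a continuous-time Gillespie simulation: every S–I edge
transmits at rate `beta` (default 20) and every infected node recovers at
rate `gamma` (default 1); `ceiling(init_frac * N)` nodes start infected
(default 5%). Rates rather than per-step probabilities are essential —
`beta = 20` is meaningless as a probability. `simulate_threshold_sir()`
adds the complex-contagion gate: a susceptible node receives transmission
only while the fraction of its neighbours currently infected is at least
`phi` (default 0.18), re-evaluated at every event. The threshold is taken
over the node's *total* degree, the standard reading of "proportion of
infected neighbours". With `phi = 0` the two models share a code path and
are bitwise identical under the same seed. The headline statistic is the
*peak* outbreak size (maximum simultaneous prevalence); final size is also
recorded.

## Network ensembles

All generators return simple undirected igraph graphs and take explicit
seeds.

* **Erdős–Rényi**: `p = k_avg / (N - 1)`; used as generated, possibly
  disconnected — the quoter simulation tolerates isolated nodes, which
  simply never quote.
* **Barabási–Albert**: growth with `m = k_avg / 2` links per arrival. The
  `m` seed nodes start with no edges, so the first arrival cannot attach
  preferentially; it links to all `m` seeds, after which standard
  preferential attachment applies. This yields connected graphs with
  exactly `m * (N - m)` edges.
* **Watts–Strogatz**: ring lattice with `k` nearest neighbours, each edge
  rewired with probability `p_rewire`; the edge count `N k / 2` is
  preserved.
* **Dichotomous**: the minimal degree-heterogeneous ensemble — half the
  nodes have degree `k1`, half `k2` (mean `(k1 + k2)/2`, variance exactly
  `(k1 - k2)^2 / 4`). Realized with the Viger–Latapy connected
  configuration-model sampler so the degree histogram is exact and the
  graph simple and connected.
* **Two-block SBM**: within-block probability `p0`, between-block `p1`,
  equal blocks of size `m = N/2`.
* **x-swap**: degree-preserving randomization. A swap is accepted only if
  it keeps the graph simple, and connectivity is checked after every
  accepted swap (`check_every` batches the check for speed, reverting the
  batch on failure). `n_swaps` counts *attempted* swaps, so graphs with no
  admissible swap (e.g. complete graphs) terminate trivially.

`graph_transitivity()` is `3 * triangles / triads` with the convention
`T = 0` when no triads exist (avoiding 0/0). `summary_metrics()` reports
both density conventions in circulation — edges over node pairs, and
`M / N^2` — explicitly labelled, because both are used when relating flow
to density.

**Expected SBM modularity.** For the planted two-block partition the
expected within-block edge total is `p0 m(m-1)` and the between total
`p1 m^2`, while by symmetry each block holds half the degree, so the null
term is 1/2 and

```
Q = p0 (m - 1) / (p0 (m - 1) + p1 m) - 1/2
  = (1/2) * (p0 (m-1) - p1 m) / (p0 (m-1) + p1 m).
```

Limits check out (`p1 = 0` gives 1/2; `p0 = p1` with large `m` gives ~0) and
the tests verify the form against the Monte-Carlo mean of
`newman_modularity()` on sampled SBMs across a `(p0, p1)` grid.

## Design choices that were genuinely open

* **Scheduling.** Whether nodes act in random order or round-robin is not
  fixed by the model statement ("approximately `1000 lam` words" suggests
  stochastic action counts). Random scheduling is the default;
  `schedule = "round_robin"` is available and the experiments are
  insensitive to the choice.
* **Poisson zero.** An action of drawn length 0 writes nothing; it is not
  resampled.
* **Empty-alter fallback.** Quoting from an empty stream is undefined; the
  ego generates fresh content instead, which keeps the first steps
  well-posed.
* **Quote clamping.** A requested quote longer than the alter's stream is
  clamped to the full stream.
* **Block vocabularies.** With per-block Zipf exponents, fresh content uses
  the ego's own block table; quoting copies verbatim across blocks. All
  blocks share `z`, so predictabilities remain comparable.
* **Within/between pairs.** Block-level flow compares *edges* by default
  (within-block versus between-block links); `include_nonedges = TRUE`
  samples non-adjacent pairs instead, since the estimator does not require
  adjacency.

## Reduced-scale study conditions

Full-scale versions of these experiments (N = 1000 graphs, hundreds to
thousands of trials per point, millions of swaps) are out of reach of a
single desk CPU, so the packaged experiments and the test suite run a
scaled-down design whose *directions* are the object of interest:

* structural sweeps on `N = 200` graphs (`N = 100` for the SBM, matching
  the original block experiments exactly), with 500 actions per node
  (~1500 words per stream);
* flow means estimated from a uniform subsample of 300–600 directed edges
  per graph — an unbiased estimate of the edge mean at a fraction of the
  cost;
* 30 independent (graph, corpus) replicates per grid point, 15 for the
  vocabulary-heterogeneity contrasts.

What the synthetic experiments do *not* emulate: real text (no syntax, no
topical correlations, a fixed global vocabulary), directed or weighted
ties, and the preprocessing quirks of empirical networks. Passing tests
show the estimators and dynamics interact as designed on model graphs; they
do not certify effect sizes on real social data. The `read_edgelist()`
loader accepts any user-supplied edge list for such comparisons.

## Known limitations

* The `1/log T` estimator bias noted above: absolute cross-entropies at
  desk scale sit well below asymptotic values; only comparisons at matched
  stream length are meaningful.
* Undirected, unweighted graphs only; per-edge quote probabilities are not
  implemented (the model collapses them to a single `q`).
* Transfer- and causation-entropy style multi-source measures are out of
  scope; `cross_entropy()` is strictly pairwise.
* `xswap_randomize()` checks connectivity after each accepted swap by
  default, which is the correct but slower contract; raise `check_every`
  for large graphs.
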