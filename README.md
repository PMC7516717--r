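# quoterflow

Simulation and estimation toolkit for studying **social information flow on
networks with the quoter model**, for researchers in network science,
computational social science and epidemiological modelling who want to
compare an information-theoretic view of spreading with classic contagion.

## The science in brief

Nodes of an undirected graph grow timestamped text streams. At each time
step one node acts: with probability *q* it **quotes** — copies a random
contiguous segment (Poisson(λ) words) of a uniformly chosen neighbour's
past text — and otherwise it writes fresh words drawn i.i.d. from a Zipf
vocabulary, W(w) ∝ r_w^(−α) over z words. Information flow along an edge is
then *measured from the text itself* with a nonparametric match-length
cross-entropy estimator,

    ĥ×(A|B) = T_A · log2(T_B) / Σ_t Λ_t(A|B),

where Λ_t(A|B) is the length of the shortest substring of ego text A
starting at position *t* not found among the alter text B's words written
strictly **before** the t-th word of A (temporal precedence). Fano's
inequality converts ĥ× into the predictability Π, the best possible
next-word hit rate. Lower ĥ× / higher Π = more information flow.

The package contains everything needed to rerun the structural experiments
at desk scale:

* network ensembles — Erdős–Rényi, Barabási–Albert, Watts–Strogatz,
  two-degree "dichotomous" configuration-model graphs, two-block stochastic
  block models, plus degree-preserving **x-swap** randomization with
  connectivity preservation and a closed form for the expected SBM
  modularity;
* the quoter-model simulator (random or round-robin scheduling, per-block
  vocabularies for dynamic heterogeneity);
* entropy-rate / cross-entropy / predictability estimators with an exact
  brute-force reference implementation;
* event-driven (Gillespie) SIR and threshold-SIR contagion baselines with
  peak-outbreak-size ensembles;
* scenario runners (`run_scenario()`) for the density, degree-heterogeneity,
  clustering, community and vocabulary-heterogeneity sweeps;
* plain-text I/O: whitespace edge lists, corpus TSV + JSON sidecar, and a
  thin CLI (`inst/exec/quoterflow`).

## Worked example

```r
library(quoterflow)

g <- generate_er(50, 6, seed = 1)          # ER graph, N = 50, <k> = 6
corp <- simulate_quoter(g, q = 0.5, seed = 2)
corp
#> Quoter-model corpus: 50 nodes, 50000 time steps (q = 0.5, lambda = 3, z = 1000)
#>   words per node: mean 2996.8, range [2803, 3209]

fl <- edge_cross_entropies(corp)           # hx over both orientations of every edge
fl
#> Edge information flow over 286 directed pairs (0 skipped)
#>   mean h_x 3.2639 bits | Var(h_x) 0.00327 | mean predictability 0.7533

summary_metrics(g, on_disconnected = "largest-component")
#> Network: N = 50, M = 143, <k> = 5.72
#>   density (pairs) 0.1167 | M/N^2 0.0572 | transitivity 0.13
#>   ASPL 2.4 | Louvain Q 0.339 | assortativity 0.00723

simulate_sir(g, seed = 3)                  # simple contagion baseline
#> SIR outbreak on N = 50: peak 49, final size 50 (beta = 20, gamma = 1)
simulate_threshold_sir(g, seed = 3)        # complex contagion (phi = 0.18)
#> Threshold (phi = 0.18) outbreak on N = 50: peak 48, final size 50 (beta = 20, gamma = 1)
```

Reading the numbers: each node wrote ≈ 1000·λ = 3000 words; with q = 0.5
the mean edge cross-entropy (3.26 bits/word) sits well below the
independent-stream baseline for this vocabulary, i.e. neighbours' texts
carry substantial predictive information about each other, and an ideal
predictor would get ≈ 75% of next words right. On this dense little graph
the SIR outbreak sweeps almost everyone, while the threshold model is
slightly suppressed.

Structural sweeps go through `run_scenario()`, e.g.

```r
res <- run_scenario("density_sweep",
                    params = list(model = "er", n = 200, k_grid = c(6, 12, 24)),
                    quoter = list(steps_per_node = 500),
                    replicates = 30, seed = 42, sample_edges = 300)
aggregate(mean_pi ~ k, res, mean)   # predictability falls as density rises
```

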