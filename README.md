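# tegrn — directed gene regulatory networks from time-series expression via transfer entropy

`tegrn` infers **directed** gene regulatory networks (GRNs) from long, evenly
sampled gene-expression time series. Correlation and mutual-information
networks tell you that two genes co-vary; they cannot tell you which gene
drives which. Transfer entropy can: it measures how much the recent past of a
source gene reduces uncertainty about a target gene's next state *beyond*
what the target's own past already explains, and it is asymmetric by
construction. The package is aimed at systems biologists with densely sampled
time-course data — the motivating design is a circadian experiment with one
sample every 3 minutes for 24 hours (480 time points) — who want a scored,
screened, Cytoscape-ready directed network plus the tooling to benchmark the
whole procedure on data with a known answer.

## The statistic

For series \(x\) (target) and \(y\) (source) with first-order (Markov)
histories, the transfer entropy from \(y\) to \(x\) is

```
T(y->x) = Σ p(x_{n+1}, x_n, y_n) · log2 [ p(x_{n+1}, x_n, y_n) p(x_n) / ( p(x_{n+1}, x_n) p(x_n, y_n) ) ]
```

estimated by a plug-in equal-width histogram (8 bins by default, log base 2,
so results are in bits). All marginals are derived from one joint count
table, which guarantees the estimate is a genuine conditional mutual
information and therefore non-negative. The **net information flow**
`T(y->x) − T(x->y)` assigns the edge direction: positive means `y` drives
`x`.

Around that core, the pipeline mirrors a complete inference protocol:

1. centered moving-average smoothing (window 5) and removal of
   zero-variance genes;
2. optional rhythm-gene target selection: fuzzy c-means and
   cosine-similarity clustering of z-scored profiles (12 clusters each),
   intersected around a reference gene such as AANAT;
3. transfer entropy + permutation p-value for every ordered gene pair
   (`n(n−1)` pairs);
4. a screening cascade — keep the dominant direction of each pair
   (`n(n−1)/2` edges), then `p < 0.001`, then `TE ≥ 0.5` bits;
5. strongest-outgoing and strongest-incoming edge networks, exported as
   SIF/TSV for Cytoscape;
6. AUROC / AUPRC / PPV / sensitivity evaluation against DREAM-style
   gold-standard edge lists.

A synthetic generator (`planted_network()` / `simulate_expression()`) plants
known lag-1 regulatory cascades — optionally on a 24-hour circadian
baseline — so every stage can be validated end to end.

## Worked example

```r
library(tegrn)

design <- sampling_design(interval_minutes = 3, duration_hours = 24) # 480 points
net    <- random_planted_network(10, 12, coupling_range = c(0.7, 1),
                                 seed = 42, mode = "linear-lag")
sim    <- simulate_expression(net, design, seed = 42)

run <- run_pipeline(sim$expression,
                    run_config(n_permutations = 200, alpha = 0.01, seed = 42))
run
#> Directed network inference run (seed 42)
#>   stage              n
#> 1 input_genes       10
#> 2 filtered_genes    10
#> 3 selected_genes    10
#> 4 te_pairs          90
#> 5 one_way           45
#> 6 pvalue            19
#> 7 te_threshold       5
#> 8 strongest_out      5
#> 9 strongest_in       4

benchmark_network(run$te_matrix, sim$gold)
#> Network benchmark: 12 positive / 78 negative pairs
#>   AUROC: 0.9113
#>   AUPRC: 0.6962
```

Reading the output: 10 genes give 90 ordered pairs; keeping the dominant
direction of each pair leaves 45; 19 of those have permutation `p < 0.01`;
5 carry at least 0.5 bits of transfer entropy; the strongest-edge reductions
yield the final 5-edge (outgoing) and 4-edge (incoming) networks. Scoring
the full TE matrix against the planted gold standard: AUROC 0.91 means a
true edge out-ranks a non-edge 91% of the time; AUPRC 0.70 against a 13%
positive prevalence shows strong early precision.

The top-scored edges are real plantings:

```r
dplyr::arrange(run$te_matrix, dplyr::desc(te)) |> head(5)
#>   source target    te p_value
#> 1 G02    G08    0.660 0.00498
#> 2 G05    G06    0.597 0.00498
#> ...
```

`tidy()`, `glance()`, and `autoplot()` methods are provided for run bundles
and benchmarks, and `inst/cli/tegrn-cli.R` exposes the pipeline as shell
subcommands (`simulate`, `smooth`, `select`, `te`, `screen`, `network`,
`eval`, `run`).

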