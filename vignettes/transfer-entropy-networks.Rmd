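---
title: "Inferring directed gene regulatory networks with transfer entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring directed gene regulatory networks with transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tegrn)
```

## The model

`tegrn` treats each gene's expression time course as a stochastic process
and asks, for every ordered pair of genes, whether the source's past carries
information about the target's next state that the target's own past does
not. That quantity is the transfer entropy

$$
T_{y \to x} = \sum p(x_{n+1}, x_n, y_n)\,
  \log_2 \frac{p(x_{n+1}, x_n, y_n)\, p(x_n)}
              {p(x_{n+1}, x_n)\, p(x_n, y_n)},
$$

written here for first-order (lag-1) histories. Unlike correlation or
mutual information, transfer entropy is asymmetric: $T_{y\to x}$ and
$T_{x \to y}$ generally differ, and the sign of the *net information flow*
$T_{y\to x} - T_{x\to y}$ assigns the direction of the inferred regulatory
edge. Transfer entropy is equivalent to Granger causality for Gaussian
linear systems but requires no linearity assumption.

Two assumptions matter in practice:

* **Markov order.** The default `k = l = 1` treats both series as
  first-order Markov, which keeps the estimated joint distribution
  three-dimensional. Higher orders are supported (`k`, `l` arguments) but
  the number of histogram cells grows as $B^{1+k+l}$ and quickly outstrips
  any realistic series length.
* **Stationarity within the window.** The histogram pools all time points,
  so slow trends inflate the marginal entropy. The smoothing step reduces
  measurement outliers, not trends; strongly non-stationary series should
  be detrended before inference.

## Estimation choices

The probabilities in the transfer-entropy sum are plug-in estimates from an
**equal-width histogram** over each series' observed range. Defaults and
rationale:

* `n_bins = 8`. For 480-point series this leaves on average roughly one
  observation per cell of the $8^3$ joint table — coarse enough that the
  estimator's bias is comparable across pairs (what matters for ranking),
  fine enough to resolve waveform structure. Fewer bins (2–4) suit shorter
  series.
* **Top bin closed.** Bins are half-open on the right except the last, so
  the maximum value is always assigned; a constant series maps to a single
  symbol and contributes zero entropy.
* **One joint table.** Every marginal is obtained by summing the single
  joint count table, never by a separate pass. This makes the plug-in
  estimate a true conditional mutual information, hence non-negative, and
  lets empty cells contribute exactly zero (the $0 \log 0 = 0$ limit).
* **Bits.** All entropies use $\log_2$; the screening threshold
  (`min_te = 0.5`) is therefore in bits. A natural-log base can be passed
  via `base = exp(1)`.

## Significance

Each directed score gets a permutation p-value: the source series is fully
shuffled (`n_permutations = 1000` by default), which destroys any
cross-series coupling while the target's autocorrelation is preserved
through its own history term in the statistic. The add-one rule
$p = (1 + \#\{T_{\text{perm}} \ge T_{\text{obs}}\})/(1 + n_{\text{perm}})$
keeps p-values in $(0, 1]$. Note the floor: with 1000 permutations the
smallest attainable p-value is $1/1001 \approx 0.000999$, which is exactly
what the default strict screen `p < 0.001` requires — fewer permutations
make that screen unsatisfiable.

Per-pair seeds are derived by hashing the master seed with the two gene
names, so a whole-matrix run is reproducible pair by pair and independent
of computation order (the contract that makes serial and concurrent
execution bit-identical).

## Target selection

When a reference gene is supplied (the motivating use case: AANAT, the
rate-limiting melatonin-synthesis enzyme, as the anchor for rhythmic genes
in the pineal gland), candidate genes are selected by **agreement of two
clusterings** of the z-scored profiles:

* fuzzy c-means (fuzzifier 2.0, tolerance $10^{-5}$ on the maximum
  membership change, at most 1000 iterations, seeded random membership
  initialization — the objective trace is stored and is non-increasing);
* average-linkage agglomerative clustering under cosine distance.

Both use 12 clusters by default, a granularity that separates phase and
waveform families in genome-wide rhythmic data; both operate on per-gene
z-scores because pattern, not amplitude, defines co-rhythmicity. The genes
kept are the intersection of the two clusters containing the reference
gene. Any further manual pruning is replaced by explicit include/exclude
lists (`curate_genes()`), so no gene is dropped untraceably.

## The screening cascade

From the $n(n-1)$ scored ordered pairs:

1. **One-way screen** — keep the direction with larger TE in each
   unordered pair; exact ties keep the lexicographically first
   `(source, target)`. Output is always $n(n-1)/2$ edges.
2. **p-value screen** — strict `p < 0.001`.
3. **TE screen** — inclusive `TE >= 0.5` bits.
4. **Strongest-edge reduction** — at most one outgoing edge per gene
   (its maximum-TE edge; ties lexicographic by target), and, as a separate
   network, one incoming edge per gene. Both networks are emitted.

All tie-breaks are lexicographic on gene names purely for reproducibility.

## The synthetic generator

`simulate_expression()` produces genes × time tables from lag-1 coupled
dynamics: each gene's deviation follows an AR(1) (coefficient 0.5) plus the
coupling-weighted lag-1 deviations of its regulators plus Gaussian noise
(sd 0.1, one tenth of the unit signal amplitude), optionally squashed
through `tanh` (`nonlinear-lag`) or superimposed on a 24-hour cosine
baseline with per-gene phase jitter (`circadian`, emulating a 3-minute /
24-hour / 480-point circadian sampling design). Random planted networks are
**acyclic by default**: regulatory cascades drawn consistent with a random
topological order. This is deliberate — cyclic networks with couplings near
1 are explosive under linear lag-1 dynamics, which destroys the
discretization; DAG cascades are stationary for any coupling in $[0, 1]$.
Cyclic networks remain available (`acyclic = FALSE`) for stress testing.

What the generator does **not** emulate: read-count noise models
(expression is Gaussian around the dynamics, not negative-binomial),
unequal sampling, missing time points, long-memory dynamics (except via
the lag-2 mismatch mode), and transcriptome-scale gene counts. Passing
tests on this generator therefore demonstrates correctness of the
estimator and pipeline mechanics and recoverability under the stated
dynamics — not performance on any particular real data set.

A further caveat the synthetic experiments expose: in `circadian` mode
with a strong shared baseline, the full-shuffle permutation null is
*conservative* — a shuffled source has higher marginal entropy than the
smooth rhythmic original, so permuted TE can exceed observed TE and
p-values concentrate near 1. This mirrors a genuine inferential
difficulty: when all genes ride one deterministic rhythm, cross-coupling
carries little information beyond the target's own history. Detection
power on the coupled dynamics themselves (lag modes) is excellent.

## Numerical and degenerate-input conventions

* Constant series discretize to a single symbol; TE involving a constant
  target is exactly 0, and a constant source yields p = 1.
* Tiny negative totals from floating-point cancellation are clamped to 0.
* Zero-variance genes are refused by the clustering (they have no pattern)
  and removed by `filter_flat_genes()` with a reasoned report; removing
  every gene warns rather than failing silently.
* Smoothing boundaries default to `shrink` (average the available
  neighbors); `reflect` mirrors the series. The window must be odd so the
  window is centered.
* The moving-average window (default 5 points) follows the standard
  centered form $F_t = (A_{t-n} + \dots + A_{t+n})/(2n+1)$.

## Problem sizes in the test and acceptance suites

The suites are sized to exercise every property at desk scale: estimator
oracle checks enumerate series of length ≤ 20 with 2–3 bins; null
calibration uses 500 independent 480-point pairs with 99 permutations;
planted-network recovery uses 10 genes × 480 points × 20 replicate
simulations; determinism uses a 6-gene circadian run with 99 permutations.
These sizes were chosen so each property is measured with comfortable
statistical margin while a full run stays interactive.

## Known limitations

* The histogram estimator's additive bias grows with `n_bins` and shrinks
  with series length; absolute TE values (and hence the 0.5-bit screen)
  are estimator-dependent, while rankings are much more stable. Comparing
  TE values across different bin counts or lengths is not meaningful.
* Lag-1 estimation misses couplings at longer delays (the generator's
  lag-2 mode exists precisely to demonstrate this mismatch).
* Transfer entropy is pairwise: common drivers and indirect chains can
  produce elevated scores between non-interacting genes; the screening
  cascade mitigates but does not eliminate this.
* The permutation null assumes exchangeability of the source series;
  strongly autocorrelated sources make it conservative (see above).
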