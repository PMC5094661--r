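---
title: "Margin-constrained null models for presence-absence data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-constrained null models for presence-absence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullmargins)
```

## The two constraint families

A presence-absence matrix `M` is a 0/1 matrix whose rows are taxa and whose
columns are sites (a convention only; every statistic takes an `axis`
argument). Its margin sums — row sums `R`, column sums `C` — describe species
frequencies and site richness, the "trivial" structure a null model should
preserve while randomizing everything else. `nullmargins` implements the two
maximum-entropy ways of doing that.

**Fixed-fixed (FF).** The null is the uniform distribution over `M_{R,C}`,
the set of matrices with exactly the observed margins. Uniformity over a
constraint set is the maximum-entropy distribution for strict constraints.
Sampling uses the sequential swap chain: one attempt draws a uniformly
random unordered row pair and column pair and toggles the 2×2 submatrix when
it is a checkerboard unit (diagonal cells equal, off-diagonal cells equal,
the two different). Two points are easy to get wrong:

* *Attempts, not successes, are counted.* The proposal is symmetric and the
  acceptance probability is 1 on checkerboard units and 0 elsewhere, so the
  chain is a Metropolis sampler with uniform stationary distribution only
  when failed attempts also advance the clock. The historical
  successes-counting variant is biased toward matrices with few units.
* *Nested data locks in.* Every checkerboard unit breaches a
  superset-subset (nestedness) relation between two rows, so a perfectly
  nested matrix has zero units and the chain cannot move at all:
  `ff_sample()` then returns the input forever and any randomization test
  degenerates to `p = 1`. This is a property of the constraints, not of the
  implementation.

**Rasch (stochastic constraints).** Relaxing the constraints to hold in
expectation and maximizing entropy yields independent cells with
`p_ij = plogis(μ_i + λ_j)`, the Rasch model of item-response theory. The
parameters are fitted so expected margins equal observed margins; matrices
are then sampled cell-by-cell, so convergence is a non-issue and the
probability of any pattern can be written down in closed form. One useful
closed-form fact: a checkerboard swap permutes cell values within one row
pair and one column pair, which leaves `Σ x_ij μ_i` and `Σ x_ij λ_j`
unchanged — so the Rasch log-probability is invariant under swaps, and the
whole FF class sits on a single Rasch likelihood level set. This is why swap
chains started from Rasch draws are expected to wander around their starting
statistic level rather than drift.

## Fitting the Rasch model

`fit_rasch()` solves the moment equations `Σ_j p_ij = R_i`, `Σ_i p_ij = C_j`
by alternating damped Newton updates of all row effects (columns held fixed)
and all column effects. Each one-dimensional equation is strictly monotone
and the joint log-likelihood is concave, so the block iteration converges
from any start; the `mu0`/`lam0` arguments exist to let the test-suite verify
initialization independence. Numerical choices:

* **Tolerance** `tol = 1e-8` absolute per margin entry (configurable), with
  `max_iter = 10000` sweeps and an explicit error reporting the worst
  residual on failure. Typical matrices converge in well under 20 sweeps.
* **Degenerate margins are pinned, not clamped.** A row with sum 0 (or full)
  has no finite parameter; its cells are pinned to probability exactly 0
  (or 1) via the `fixed_cells` mask, the pinning cascades (removing a full
  column can make another row degenerate), and the remainder is fitted.
  Pinning avoids tolerance-dependent behaviour that large finite parameters
  would introduce; an all-ones matrix is entirely pinned and fits in zero
  sweeps.
* **Gauge.** `p_ij` is invariant under `(λ + c, μ − c)`, so reported
  parameters are normalized to `mean(λ) = 0` over non-degenerate columns.
  Probabilities do not depend on the gauge.

## The statistics

Three statistics cover global and local structure; each carries a tail
direction used by the test engine (`"structure"`: larger = stronger;
`"error"`: smaller = stronger).

* **Checkerboard unit count** (global, `error`): computed per row pair as
  `n10 · n01` from the co-occurrence counts, summed over pairs — identical
  to the brute-force count over all 2×2 submatrices but `O(n²m)`. Used as an
  order-independent proxy for (anti-)nestedness.
* **Correlation counts** (local, `structure`): for every unordered pair of
  vectors on the chosen axis, the 2×2 co-occurrence table is tested with the
  Fisher exact test. "Positive" uses the one-sided upper hypergeometric tail
  `P(N11 ≥ n11)`, "negative" the lower tail, "two-tailed" the standard
  two-sided rule (sum of table probabilities no larger than the observed
  table's, the `stats::fisher.test` convention). The positive and negative
  counts need not sum to the two-tailed count; all tails are computed from
  `phyper`/`dhyper` directly, with the exact two-sided sum evaluated only
  for pairs whose smaller one-sided tail is below the cutoff (a valid
  shortcut because the two-sided p is never smaller than that tail).
  Default cutoff `alpha = 1e-6`, deliberately unadjusted for multiple
  testing so counts stay comparable across matrices of one shape.
* **K-means clustering error** (global, `error`): `stats::kmeans` on the
  axis vectors with `n_init = 10` restarts from sampled distinct points,
  keeping the best squared-error objective, then reporting the sum of
  *unsquared* Euclidean distances to assigned centroids (the literal
  "sum of distances" reading). When the number of distinct points is at
  most `k` the error is exactly 0. Restart randomness is controlled by a
  per-replicate derived seed, which makes the statistic deterministic for a
  given master seed and invariant to execution order.

## The randomization test

`randomization_test()` follows the classical protocol: evaluate the
statistic on the data, draw `n` null matrices, and report

```
p = (1 + #{null at least as extreme}) / (1 + n)
```

tie-inclusive, where "extreme" respects the statistic's direction. The
add-one form is the standard valid permutation p-value; with the customary
`n = 1000` its floor is `1/1001 ≈ 0.001`, and a completely locked-in null
(nested data under FF) gives exactly 1. FF nulls default to independent
chains of `1000 × (number of ones)` attempts each, a generous multiple of
the usual convergence recommendation; a thinned single-chain mode
(burn-in, then record every `n_attempts`) is available and was used for the
uniformity checks below because it exercises long-run behaviour cheaply.

**Calibration, and a caveat about refitting.** When data are generated from
a *known* Rasch model and tested against that same model (via the `params`
argument), the Monte-Carlo p-value is exactly calibrated: over 200 simulated
30×20 datasets with 199 nulls each, the p-values are indistinguishable from
U(0,1) (Kolmogorov-Smirnov, the acceptance suite's check). The field
protocol for real data, however, *refits* the model to the data before
sampling nulls. That refit absorbs the data's margin noise into the null —
the fitted column effects treat sampling fluctuations of the margins as real
heterogeneity — and for margin-coupled statistics (checkerboard count,
clustering error) the test becomes markedly conservative: in the same
simulation with refitting, p-values pile up near 1. This is a property of
all parametric-bootstrap tests with estimated nuisance parameters, worth
keeping in mind when reading near-1 p-values for global statistics.

## Chain diagnostics

`swap_chain_trace()` records a statistic every `record_every` attempts
(defaults 2000 attempts, every 10 → 200 recordings; `moving_average()` with
a window of 50 recordings smooths traces for plotting).
`chain_experiment()` runs the two-set comparison: swap chains from the data
versus swap chains from independent Rasch draws, with three two-sample
Kolmogorov-Smirnov tests between the endpoint/start statistic samples at
Bonferroni threshold `0.05 / 3 ≈ 0.017`. The KS null hypothesis is the
standard "same distribution"; rejection means the chain sets ended in
different regimes. Theory predicts the Rasch-start endpoints stay
distributionally indistinguishable from the Rasch starts (swap-invariance of
the Rasch likelihood); whether chains from the *data* end elsewhere is
exactly the lock-in question the experiment probes.

## Synthetic fixtures: what they emulate and what they do not

All test inputs are generated in code (`make_nested`, `make_random`,
`make_planted_correlations`, `make_with_margins`); every generator is
deterministic given its seed.

* `make_nested` builds left-justified perfectly nested matrices — the FF
  lock-in extreme.
* `make_random` takes a scalar fill, a per-row fill vector, or a full
  probability matrix. The vector/matrix forms exist because heterogeneous
  margins are the defining feature of real occurrence data (fossil-site
  matrices have fills near 0.08 with strongly skewed richness) and because
  several of the phenomena studied here only appear under heterogeneity.
* `make_planted_correlations` copies each planted row from its partner with
  per-cell retention probability `overlap`, preserving expected margins so
  planted rows are not trivially flagged by margin-based nulls.

The chain-comparison experiment uses a 20-site × 300-taxon fixture with
bimodal per-taxon fills (240 taxa at 0.05, 60 at 0.4) and 9 planted
identical site pairs, chains of 100000 attempts (about 100 × the number of
ones) recorded every 500 attempts. The heterogeneity matters: under a Rasch
model fitted to such data, pairwise co-occurrence counts are overdispersed
relative to the hypergeometric reference, so Rasch draws carry a nonzero
Fisher-significant pair count for the chains to preserve, while swap chains
from the data destroy the planted pairs and settle at the FF level. With
homogeneous fills all three chain samples would sit at zero significant
pairs and the comparison would be vacuous. Scale choices throughout the test
suite (3×3 enumeration classes with 20000 thinned samples; 200 calibration
datasets of 30×20 with 199 nulls; 10 chains per set) were picked as the
smallest sizes at which the respective distributional checks have useful
power.

What the fixtures do *not* emulate: taphonomic or sampling biases of fossil
data, spatial autocorrelation among sites, phylogenetic correlation among
taxa, or abundance information. Passing tests establish the samplers'
distributional correctness and the engine's calibration, not ecological
realism of any particular dataset.

## Other numerical choices and limitations

* Exhaustive enumeration (`enumerate_same_margin_matrices`) fills rows
  depth-first in lexicographic column order with Gale-Ryser feasibility
  pruning and a hard cap (default 100000) that errors rather than truncates.
  It is an oracle for tests and tiny examples; `M_{R,C}` grows far too fast
  for anything else.
* `make_with_margins` draws uniformly via enumeration for classes of at
  most 20 cells, otherwise builds a Ryser-style greedy fill and randomizes
  it with `1000 × ones` swap attempts — an approximately, not exactly,
  uniform draw.
* Per-replicate seeds derive from the master seed through a fixed integer
  recurrence, so results are identical regardless of evaluation order; all
  derived seeds stay below 2³¹.
* Matrices are stored dense; the statistics are vectorized (`tcrossprod`,
  vectorized `phyper`), which is comfortable up to a few thousand rows. The
  swap kernel is a blocked pure-R loop at roughly 3M attempts/second at
  small sizes; very large matrices with the full `1000 × ones` budget will
  be slow, and no sparse or compiled path is provided.
* The two-sided Fisher rule and the one-sided tail definitions are fixed
  choices documented above; other two-sided conventions (doubling the
  smaller tail) would change two-tailed counts slightly.
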