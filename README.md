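# nullmargins

Significance testing for patterns in binary presence-absence matrices under
margin-sum-constrained null models.

## The problem

A presence-absence matrix records which taxa (rows) occur at which sites
(columns) as 0/1 cells. Its row sums (species occurrence frequencies) and
column sums (site richness) — the *margin sums* — carry most of the trivial
structure of such data, so null models for testing co-occurrence patterns,
nestedness, or clustering are built to respect them. Two constraint families
do this in fundamentally different ways:

* **Fixed-fixed (FF)**: the null distribution is uniform over the set
  `M_{R,C}` of all 0/1 matrices with *exactly* the observed row sums `R` and
  column sums `C`. It is sampled with the **sequential swap** Markov chain:
  each attempt picks a random row pair and column pair and, when the 2×2
  submatrix is a *checkerboard unit* (pattern `10/01` or `01/10`), toggles
  it. Counting attempts rather than successful swaps makes the stationary
  distribution uniform.
* **Rasch (stochastic constraints)**: the maximum-entropy distribution whose
  *expected* margins equal the observed ones. Cells are independent with

  ```
  p_ij = exp(λ_j + μ_i) / (1 + exp(λ_j + μ_i))
  ```

  where row effects `μ_i` and column effects `λ_j` are fitted so that
  `Σ_j p_ij = R_i` and `Σ_i p_ij = C_j`.

The strict FF constraints can interlock ("lock-in"): a perfectly nested
matrix contains no checkerboard units and cannot be permuted at all, and
even well-randomizable matrices may give the two models sharply different
significance verdicts. The package provides both models, the structure
statistics used to compare them (checkerboard unit count, pairwise
Fisher-exact correlation counts, K-means clustering error), a
randomization-test engine with add-one empirical p-values, swap-chain
diagnostics (traces, chain-set Kolmogorov-Smirnov comparisons), exhaustive
enumeration of small margin classes, and synthetic fixture generators.

## Worked example

The 2×3 matrix `M` below has margins `R = <2, 1>`, `C = <1, 1, 1>`: a common
species, a rare species, three sites with one occurrence each.

```r
library(nullmargins)
M <- binary_matrix(rbind(c(1, 0, 1), c(0, 1, 0)))
margin_sums(M)
#> row sums:  2 1
#> col sums:  1 1 1

length(enumerate_same_margin_matrices(margin_sums(M)))
#> [1] 3
```

Only 3 matrices share these margins exactly, and the FF model can only ever
produce those. The Rasch fit instead spreads probability over all 64 grids:

```r
fit <- fit_rasch(M)
fit$prob
#>           [,1]      [,2]      [,3]
#> [1,] 0.6666667 0.6666667 0.6666667
#> [2,] 0.3333333 0.3333333 0.3333333

exp(rasch_log_probability(fit, rbind(c(1, 1, 1), c(0, 0, 0))))
#> [1] 0.0877915
```

The single most probable matrix under the fit (probability 64/729 ≈ 0.088)
is the perfectly nested matrix in which the common species occupies all
three sites — a matrix the FF model assigns probability zero because its
margins differ.

A randomization test at survey scale (a 56×28 synthetic matrix at fill
0.564) with the checkerboard count, under each null:

```r
V <- make_random(56, 28, fill = 0.564, seed = 7)
randomization_test(V, statistic_spec("checkerboard"), model = "rasch",
                   n = 999, seed = 1)
#> randomization_result: checkerboard under rasch null (n = 999)
#>   observed 68470, null median 61370, p = 1 (error direction)

randomization_test(V, statistic_spec("checkerboard"), model = "ff",
                   n = 99, n_attempts = 10000, seed = 1)
#> randomization_result: checkerboard under ff null (n = 99)
#>   observed 68470, null median 68457, p = 0.58 (error direction)
```

The checkerboard count is an *error* statistic (smaller = more nested =
stronger structure), so `p` is the add-one empirical probability that a null
matrix has a count at most the observed one. Note how closely the FF null
median hugs the observed value compared with the Rasch median — the two
models disagree about how much of the count is "explained" by the margins.

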