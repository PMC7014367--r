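---
title: "RMT-thresholded molecular ecological networks: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RMT-thresholded molecular ecological networks: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menanet)
```

This vignette documents the statistical model behind `menanet`, the
parameters that matter and why their defaults are what they are, what the
synthetic data generator does and does not emulate, and the numerical
choices made where the methodology left them open.

## 1. The pipeline model

A molecular ecological network treats each OTU's abundance profile across
replicate samples as a random variable and each strong pairwise
association as an ecological interaction. The chain is:

1. **Filtering.** Only consistently detected taxa carry correlation
   signal over, say, 10 replicates. `filter_otus()` keeps OTUs with a
   minimum summed count over samples (`min_total`) and a minimum
   prevalence (`min_prevalence`, default present in half the samples).
   A minimum summed count over the replicate set is the reading we adopt
   for "minimum OTU value" style cutoffs, which are stated ambiguously in
   much of the applied literature; both knobs are exposed so either
   reading can be enforced. No rarefaction is applied by default: the
   log transform and Pearson correlation are insensitive to moderate
   depth variation, and rarefying discards counts the correlation step
   can use.
2. **Transform.** `log10(c + 1)`. The pseudocount maps zeros to zeros
   and keeps the transform monotone. Microbial abundances are
   approximately log-normal, so correlations on the log scale are the
   natural association measure.
3. **Similarity.** `S = |r|` with the sign of `r` retained separately.
   Thresholding the magnitude while keeping the sign is the only
   convention under which a single cutoff can coexist with signed
   (cooperative/competitive) edges, and it is what the signed network
   figures of MENA-style studies imply.
4. **RMT threshold.** See section 2.
5. **Topology, modules, roles, nulls, environment.** Sections 3–5.

## 2. The RMT threshold

### Model

Random matrix theory provides a universality result: the
nearest-neighbour spacing distribution (NNSD) of the eigenvalues of a
large random real symmetric matrix follows GOE (Wigner–Dyson)
statistics, `P(d) ≈ (πd/2) exp(−πd²/4)`, while a matrix that decomposes
into independent blocks has Poisson spacings, `P(d) = exp(−d)`. A
thresholded correlation matrix moves from the first regime (noise
correlations everywhere) to the second (only intra-module correlations
survive) as the threshold rises. The chosen threshold is the smallest
grid value whose NNSD is Poisson — the point where the surviving
structure stops looking like noise.

### Procedure and numerical choices

For each threshold on a grid (default 0.30–0.99 by 0.01):

* entries below `t` are zeroed, rows/columns with no surviving
  off-diagonal entry removed, the diagonal set to 1 (correlation
  convention);
* eigenvalues are computed and **numerically duplicate values (within
  1e−8) collapsed** — degenerate eigenvalues produce zero spacings that
  would mimic Poisson's mode at `d → 0` for free;
* the spectrum is **unfolded** with a cubic smoothing spline fitted to
  the empirical CDF points `(λ_i, i/n)`; unfolded levels are
  `e_i = n·F̂(λ_i)` and the spacings `d_i = e_{i+1} − e_i` then have
  mean ≈ 1. The spline starts at 10 effective degrees of freedom and
  steps down until the fitted CDF is monotone at the eigenvalues; a
  spectrum that defeats every df is an error, not a silent pass.
* the spacings are binned into 30 equal bins on [0, 3] (the tail beyond
  3 folds into the last bin) and chi-square statistics are computed
  against both reference densities. `poisson_ok` requires the Poisson
  chi-square to beat the GOE one *and* its goodness-of-fit p-value to
  exceed `alpha = 0.05`. If more than 20% of bins have expected count
  < 1 the bin count is halved with a warning.

None of the grid, bin count, test level or minimum spectrum size
(`min_eigenvalues = 30`) is dictated by the methodology itself; the
defaults follow common RMT practice and all are arguments of
`scan_thresholds()`. The scan is fully deterministic.

On simulated planted-module communities (section 6) the scan chooses
thresholds between roughly 0.35 and 0.7 depending on the noise
realization — always below the planted block strength, so the blocks
survive thresholding essentially intact — while on pure noise
correlation matrices it moves to ~0.7 and on sparse incoherent
("near-diagonal") matrices it stays at the bottom of the grid. With only
10 samples the spurious-correlation tail is heavy (|r| noise SD ≈ 1/3),
which is exactly why published studies at this design scale end up with
thresholds near 0.86–0.88; a user reproducing such an analysis can fix
`threshold = 0.88` and still record the scan.

## 3. Topology panel

All indices are standard; the choices worth stating:

* **Isolated OTUs are dropped** at network construction and excluded
  from the node count: published node counts in this literature are far
  below the number of OTUs entering the correlation, which is only
  consistent with connected-node counting.
* **Average path distance** is the mean geodesic over *connected* pairs
  only; published panels report finite path lengths alongside
  connectivity < 1, so the infinite inter-component distances cannot be
  included.
* **Connectivity** is Krackhardt connectedness: the fraction of node
  pairs joined by some path.
* **Power-law R²** is the OLS fit of `log10 n_k` on `log10 k` over the
  raw degree-frequency histogram (not the CCDF), the convention of
  MENA-style reports. Fewer than three distinct degrees yields NaN with
  a warning rather than a fabricated fit.
* `avgK = 2L/N` and `density = 2L/(N(N−1))` are exact identities and are
  tested as such.

Report files round half-up at three decimals (so 2.7875 prints as
2.788), matching how such panels are conventionally printed; base R's
round-half-even would disagree in the last digit.

## 4. Modules, roles, eigengenes

* **Module detection** is Clauset–Newman–Moore fast-greedy modularity on
  the unweighted, unsigned graph — the default of the platform family
  this methodology comes from, and deterministic, which matters for
  reproducible reports. One guard: on graphs where greedy merging stops
  at a negative-Q tie (e.g. a single clique), the partition falls back
  to one-module-per-component, whose Q ≥ 0 is the floor the returned
  partition must beat.
* **Zi–Pi roles** use the standard quadrants with inclusive thresholds
  `Zi ≥ 2.5`, `Pi ≥ 0.62`. Zi is defined as 0 for modules smaller than
  3 or with zero within-degree variance (a z-score there is
  meaningless). The fourth quadrant ("network hub") is retained even
  when a given dataset happens not to populate it.
* **Module eigengenes** are computed from the z-scored log abundances
  (not the binary graph): the first right singular vector per module,
  sign-oriented to correlate positively with the module's mean profile,
  with variance explained `σ₁²/Σσ²`. Only modules with more than 5
  nodes (`min_module_size = 6`) are summarized — smaller modules give
  eigengenes dominated by single taxa. The eigengene hierarchy is
  average-linkage clustering at distance `1 − cor`.
* Module counts are reported both as the total number of modules and as
  the number at or above `min_module_size`; the two can differ by a
  factor of 2–3 on sparse networks, which explains apparent
  inconsistencies between "number of modules" entries and module-level
  analyses in published tables.

## 5. Null models and environment

* **Null ensembles** use Maslov–Sneppen double edge swaps
  (`igraph::keeping_degseq`, 10·L attempted swaps per replicate,
  100 replicates by default), the field-standard degree-preserving
  null. Correlation attributes are dropped after rewiring — signs are
  properties of the data, not the topology. Average degree is invariant
  by construction, so its z-score being exactly 0 is a built-in
  integrity check.
* **Mantel tests** correlate Bray–Curtis community distances (on
  relative abundances) with Euclidean distances of the z-scored factor;
  `p = (1 + #{r_perm ≥ r_obs})/(n_perm + 1)`, one-sided, 999
  permutations, seeded. Bray–Curtis is the amplicon default;
  `community_distance = "euclidean-log"` switches to Euclidean on log
  abundances for gradient-like data.
* **Module–environment heatmaps** correlate module *eigengenes* (not
  per-node means) with factors, with two-sided t-test p-values and a
  significance mask at `alpha = 0.05`.
* **Species–environment networks** stack the top-k (default 50) most
  abundant taxa (log scale) with the z-scored factors and run the same
  similarity–threshold machinery, tagging `node_kind` so species and
  factor nodes stay distinguishable.

## 6. The synthetic community generator

`simulate_community()` generates the statistical structure the pipeline
assumes, with known ground truth:

* per module m and sample s a latent factor `g_m(s) ~ N(0,1)`;
* OTU i in module m has log10 abundance
  `z_is = μ_i + a·g_m(s) + ε_is`, `ε ~ N(0, noise_sd²)`, with
  `a = noise_sd · sqrt(w/(1−w))` so the within-module correlation is
  exactly `w = within_corr`;
* baselines `μ_i ~ N(2.5, 0.4)` (log10 scale) give a realistic
  rare-to-dominant abundance spread;
* counts are multinomial per sample at fixed depth (default 20,000
  reads), which adds realistic compositional coupling and sampling
  noise.

Defaults — 80 OTUs, 10 samples (the replicated-pot design scale),
4 modules, `within_corr = 0.9`, `noise_sd = 0.3` — produce realized
within-module |r| medians of 0.84–0.93 and spurious between-module
correlations around |0.2|–0.3 (the finite-sample noise floor at n = 10).

`simulate_env()` couples each factor to one module
(`value = β·g_m + noise`) or makes it pure noise; the default layout has
pH, EC, OM, AK tracking modules and NN, AN, AP as noise, mimicking a
soil chemistry panel where some nutrients follow the community and
others do not.

`simulate_two_conditions()` encodes the dense-vs-sparse land-use style
contrast: dense = 120 OTUs in 6 modules at `within_corr = 0.9`;
sparse = 80 OTUs in 3 modules at `within_corr = 0.65`. The sparse
condition is deliberately *fewer taxa in fewer, weaker modules* — a
recently disturbed community engages less of its membership in
correlated dynamics — because that, and not merely weaker correlations
in equally large blocks, is what produces fewer nodes, fewer links and
lower average degree through the pipeline (bigger blocks at weaker
correlation can otherwise compensate on raw edge counts). Conditions
are compared at a common similarity threshold (0.8 in the tests), the
comparable-threshold design used when networks from two treatments are
contrasted.

### What the generator does *not* emulate

Phylogenetic correlation structure, realistic taxon-abundance tails
(Poisson-lognormal zero inflation), depth variation between samples,
and genuinely non-linear species interactions. Tests that pass on these
simulations establish that the pipeline recovers planted linear-Gaussian
block structure under multinomial sampling at n = 10 — not that any
particular real-soil inference is correct.

### Compositionality caveats

Two deliberate consequences of the multinomial sampling are worth
knowing. A latent factor shared by *all* taxa cancels in relative
abundances, so a community-wide gradient is invisible to Bray–Curtis —
the Mantel power analysis therefore couples the tested factor to the
*difference* of two module factors (the actual compositional gradient).
And a factor coupled to one of four modules caps Mantel power near
0.35 at this design size, not because the test is broken but because
the factor genuinely explains a quarter of the community variance.
These are properties of compositional data, reproduced faithfully.

## 7. Problem sizes used in validation

The shipped tests and the acceptance script use: 200 random graphs of
≤ 12 nodes for brute-force oracle equivalence (clustering, path
distance, modularity, Zi, Pi at 1e−10); 20 seeded communities for
threshold-scan behaviour; 10 for module recovery (adjusted Rand ≥ 0.8
against the planted partition) and for the two-condition contrast; 500
null simulations at 999 permutations for Mantel type-I calibration
(observed rate 0.04 at seed 1) and 30 for power. These sizes give
stable pass/fail behaviour at comfortable runtimes; all are arguments,
not constants, and scale up directly.

## 8. Known limitations

* Pearson-on-log is the only association measure (by design — it is
  the measure of the methodology implemented); SparCC/Spearman
  alternatives are out of scope.
* The NNSD chi-square compares binned histograms; with fewer than ~30
  distinct eigenvalues the test is skipped rather than trusted.
* Greedy modularity has a resolution limit; very small true modules
  fused into neighbours will depress Zi for their members.
* Mantel p-values are one-sided (greater); negative association is
  deliberately not "significant".
* With 10 samples, correlation noise is heavy-tailed; thresholds below
  ~0.6 admit appreciable false edges, and any biological reading of
  single edges (rather than modules) is discouraged.
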