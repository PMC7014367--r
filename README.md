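# menanet

Molecular ecological network analysis (MENA) for microbial communities,
with automatic similarity-threshold selection by random matrix theory
(RMT).

## What it does

Co-occurrence networks are a standard way to ask how the populations of a
soil (or any microbial) community interact: OTU abundance profiles are
correlated across replicate samples, strong correlations become network
edges, and the topology of the resulting graph — its modules, hubs and
their coupling to soil chemistry — is read as ecology. The weak point of
the recipe is the correlation cutoff. `menanet` implements the RMT
solution: as the threshold rises, the eigenvalue spectrum of the retained
correlation matrix transitions from Wigner–Dyson (GOE) statistics, the
signature of noise, to Poisson statistics, the signature of modular
structure. The smallest threshold whose nearest-neighbour spacing
distribution (NNSD) is Poisson is taken as the noise floor.

Concretely, for an OTU table with counts `c_ij` the pipeline computes
`x_ij = log10(c_ij + 1)`, the Pearson correlation `r` of every OTU pair
across samples, and the similarity `S = |r|` (sign kept as an edge
attribute). For a candidate threshold `t`, entries below `t` are zeroed,
empty rows dropped, and the spacings `d` of the unfolded eigenvalues are
tested against

* Poisson: `P(d) = exp(-d)` — accepted spectrum, modular signal;
* GOE (Wigner surmise): `P(d) = (pi d / 2) exp(-pi d^2 / 4)` — noise.

Downstream the package provides the full MENA panel:

* topological indices: nodes, links, avgK = 2L/N, average clustering,
  average path distance over connected pairs, density, Krackhardt
  connectedness, power-law R² of the degree distribution;
* fast-greedy modularity modules, Newman Q, and Zi–Pi node roles
  (module hubs Zi ≥ 2.5, connectors Pi ≥ 0.62, network hubs both);
* module eigengenes (first PC of the standardized module profiles),
  their average-linkage hierarchy, and module–environment correlation
  heatmap tables;
* Maslov–Sneppen degree-preserving null ensembles with z-scores;
* Mantel tests (Bray–Curtis community distance vs environmental factor
  distance, one-sided permutation p);
* alpha diversity (Shannon, Gini-Simpson, Chao1, ACE);
* Cytoscape-ready exports (GraphML and SIF-style edge lists);
* a synthetic community generator with planted modules and planted
  environmental coupling, so every stage can be validated against known
  ground truth.

## Worked example

```r
library(menanet)

sim <- simulate_community(n_otus = 80, n_samples = 10, n_modules = 4,
                          within_corr = 0.9, seed = 1)
env <- simulate_env(sim$truth, seed = 2)

res <- run_all(sim$otu, env, out_dir = "mena_out",
               config = pipeline_config(seed = 1))
res$scan
#> spectral_scan: chosen threshold 0.600 (automatic)
#>   grid of 70 thresholds, 66 usable, 29 Poisson-ok
res$report
#> topology_report
#>   nodes              80
#>   links              917
#>   avg_degree         22.925
#>   avg_clustering     0.837
#>   avg_path_distance  2.116
#>   density            0.29
#>   connectivity       1
#>   n_modules          3
#>   modularity         0.495
#>   powerlaw_r2        0.516
#>   threshold          0.6
```

The scan settles at 0.60: below that the spacing distribution of the
retained correlation matrix still looks GOE (noise correlations survive),
above it the planted blocks dominate. At this permissive threshold two of
the four planted blocks are bridged by residual noise edges, so three
modules are detected (rebuilding at `threshold = 0.8` separates all
four); the moderate power-law R² is expected because a planted-block
community is not scale-free. `mena_out/` contains the network
(GraphML + SIF), the
index report, node roles, eigengenes and their Newick hierarchy, the
null-model comparison, Mantel table and module–environment heatmap
tables.

With real data, replace the simulated tables:

```r
otu <- read_otu_table("otu.tsv")                  # taxa x samples TSV
env <- read_env_table("env.tsv")                  # samples x factors TSV
run_all(otu, env, out_dir = "out",
        config = pipeline_config(min_total = 150, threshold = 0.88))
```

A thin command-line wrapper with the same stages lives at
`inst/scripts/menanet.R`
(`Rscript inst/scripts/menanet.R run-all --otu otu.tsv --env env.tsv --out out`).

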