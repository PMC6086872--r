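# bayesconn

Functional networks — graphs whose links encode statistical dependence
between the dynamics of node pairs — are the workhorse representation of
systems neuroscience and of many other fields. The standard
reconstruction is frequentist: each link weight is the Pearson sample
correlation `r` of the two series, the matrix is thresholded to a fixed
link density, and topological metrics are read off the binary graph.
With finite series, `r` carries sampling uncertainty, and because a
topological metric `m = f(A)` is a non-linear function of the whole
weight matrix, `E[f(A)] ≠ f(E[A])`: ignoring that uncertainty acts like
a hidden random rewiring and consistently **overestimates** topological
structure (clustering, modularity, small-worldness), especially for
short time series.

`bayesconn` implements the uncertainty-aware pipeline and its
diagnostics for researchers reconstructing networks from multichannel
time series (EEG/fMRI-style recordings, or any channels × samples
matrix):

* **Posterior inference.** For a bivariate-normal pair with
  noninformative nuisance priors, the marginal posterior of the
  correlation is

      p(ρ | X, Y) ∝ p(ρ) (1−ρ²)^((n−1)/2) ∫₀^∞ ω⁻¹ (ω + ω⁻¹ − 2ρr)^−(n−1) dω
                  ≈ p(ρ) (1−ρ²)^((n−1)/2) / (1−ρr)^(n−3/2)

  (`correlation_posterior()`, exact and approximate kernels, gridded,
  with sampling and credible intervals).
* **Ensemble reconstruction.** `frequentist_network()` (point
  estimates), `bayesian_ensemble()` (networks sampled from per-link
  posteriors), `fisher_ensemble()` (the cheap correction: weights drawn
  from N[r, tanh(σ_Z)], σ_Z = 1/√(df−3), with effective degrees of
  freedom 1/df ≈ 1/n + (2/n) Σ_τ ϱ_xx(τ) ϱ_yy(τ) for autocorrelated
  series).
* **Topology metrics.** Efficiency, degree-distribution entropy,
  clustering, assortativity, Louvain modularity, small-worldness,
  information content (`network_metrics()`).
* **Bias analysis.** `metric_bias()` (fraction of ensemble values below
  the frequentist one; 0.5 = agreement, →1 = overestimation),
  `log2_ratio()`, `error_reduction()`, `bias_report()`,
  `bias_vs_sigma()`.
* **Synthetic generators.** Star/modular coupled noise maps
  (`coupled_dynamics()`) and a BOLD-like fMRI emulator (`fmri_emulate()`
  with a canonical double-gamma HRF), plus `length_sweep()` error
  surfaces over coupling and series length.
* **IO and CLI.** Delimited series matrices, UCI EEG trial files,
  edge-list/matrix networks, ensemble manifests; a command-line wrapper
  (`inst/cli/bayesconn.R`) with `simulate | reconstruct | metrics | bias
  | correct | sweep`.

## Worked example

Simulate a 10-node star system, reconstruct it both ways, and measure
the entropy bias and the Fisher correction:

```r
library(bayesconn)

st  <- star_adjacency(10)
ts  <- coupled_dynamics(st, gamma = 0.5, t_len = 256, seed = 42)
#> <ts_set> 10 channels x 256 samples @ 1 Hz

freq <- frequentist_network(ts, density = 0.2)
#> <binary_network> 10 nodes, 9 links (density 0.200)
relative_error(st, freq)
#> [1] 0

r <- sample_correlation(ts$values[1, ], ts$values[2, ])
correlation_posterior(r, 256)
#> <cor_posterior> approximate posterior of rho | r = 0.3234, n = 256
#>   mean 0.3194  sd 0.0560  95% CI [0.2066, 0.4259]  (2001 grid points)

ens <- bayesian_ensemble(ts, density = 0.2, count = 500, seed = 42)
h   <- ensemble_metric(ens, "degree_entropy")
#> <metric_distribution> degree_entropy: 500 samples (0 excluded), mean 0.7606
metric_bias(degree_entropy(freq), h)
#> [1] 0

fis <- fisher_ensemble(correlation_matrix(ts), effective_df_matrix(ts),
                       0.2, count = 100, seed = 42)
hc  <- ensemble_metric(fis, "degree_entropy")
error_reduction(degree_entropy(freq), mean(h$samples), mean(hc$samples))
#> [1] 0.8553690
```

Reading the numbers: the frequentist network recovers the star exactly
(`relative_error` 0) and its degree entropy is 0.469 bits — but the
Bayesian ensemble, which propagates the posterior spread of every link
weight (sd ≈ 0.056 per link at T = 256), averages 0.761 bits: at this
series length the point estimate *underestimates* the entropy the data
actually support, and every ensemble member sits above it (bias 0, i.e.
maximally one-sided). The Fisher rewiring ensemble — 100 networks drawn
from the back-transformed Fisher law, no posterior evaluation needed —
reproduces 86% of that frequentist-vs-Bayesian gap.

The same pipeline from a shell:

```sh
Rscript inst/cli/bayesconn.R simulate --model star --n 10 --gamma 0.5 \
    --length 256 --seed 42 --out series.csv
Rscript inst/cli/bayesconn.R correct --input series.csv --density 0.2 \
    --count 100 --seed 42 --out correction.json
```

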