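---
title: "Link-weight uncertainty in functional network reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link-weight uncertainty in functional network reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesconn)
```

## The problem

A functional network encodes statistical dependence between the dynamics
of pairs of recording sites — EEG electrodes, fMRI voxels, financial
instruments — rather than physical wiring. The standard recipe estimates
one Pearson correlation $r$ per channel pair, collects them in an
adjacency matrix, keeps a fixed fraction of the strongest links, and
reads topological metrics off the resulting binary graph.

That recipe treats $r$ as if it were the true correlation $\rho$. With a
finite series of length $n$, $r$ carries sampling uncertainty, and a
topological metric $m = f(\mathcal{A})$ is a strongly non-linear function
of the whole weight matrix, so $E[f(\mathcal{A})] \neq f(E[\mathcal{A}])$:
plugging in point estimates does not give the expected metric. The
uncertainty acts like a random rewiring, and ignoring it systematically
*overestimates* whatever regular structure the point-estimate network
shows. `bayesconn` quantifies that bias and provides a cheap correction.

## The posterior of a correlation coefficient

For a bivariate-normal pair $(X, Y)$ with noninformative nuisance priors
($p(\lambda) \propto 1$, $p(\mu) \propto 1$, $p(\phi) \propto 1/\phi$,
$p(\psi) \propto 1/\psi$) and an arbitrary prior $p(\rho)$, the marginal
posterior of $\rho$ given the sample correlation $r$ and length $n$ is

$$p(\rho \mid X, Y) \;\propto\; p(\rho)\,(1-\rho^2)^{(n-1)/2}
  \int_0^\infty \omega^{-1}\left(\omega + \omega^{-1} - 2\rho r\right)^{-(n-1)}
  \mathrm{d}\omega,$$

with the closed-form approximation

$$p(\rho \mid X, Y) \;\propto\;
  p(\rho)\,\frac{(1-\rho^2)^{(n-1)/2}}{(1-\rho r)^{\,n-3/2}}.$$

`correlation_posterior()` implements both on a fixed quadrature grid.
Numerical choices, each visible in the function signatures:

* **Grid.** 2001 equally spaced points on $[-1+10^{-6},\, 1-10^{-6}]$.
  The offset keeps the $(1-\rho^2)^{(n-1)/2}$ endpoint singularities (for
  $n < 4$ the kernel diverges at $\pm 1$) off the grid; 2001 points put
  grid error far below the statistical spread of any posterior with
  $n \le 10^5$.
* **The $\omega$ integral.** Substituting $\omega = e^u$ gives
  $\int_{-\infty}^{\infty} (2\cosh u - 2\rho r)^{-(n-1)}\,\mathrm{d}u$,
  an even, exponentially decaying integrand; a fixed trapezoidal rule on
  $u \in [0, 30]$ (2001 points, doubled by symmetry) is exact to more
  digits than the grid itself resolves.
* **Log-space evaluation.** $(1-\rho^2)^{(n-1)/2}$ underflows for $n$ in
  the hundreds; kernels are accumulated as logarithms and normalised once
  at the end (trapezoidal rule), so every returned density integrates to
  1 within $10^{-6}$.
* **Default kernel.** The approximate expression. Across
  $r \in [-0.9, 0.9]$, $n \ge 10$ the two kernels differ by less than
  0.05 in total variation (the suite checks this), and the closed form is
  two orders of magnitude cheaper. The exact kernel stays available via
  `method = "exact"`.
* **Default prior.** Uniform on $[-1, 1]$. A tabulated prior can be
  supplied; with $n = 10^4$ a mildly informative prior moves the
  posterior mean by under 0.005, so the choice is immaterial for the
  series lengths studied here.

Sampling uses the inverse CDF with linear interpolation inside grid
cells; credible intervals are equal-tailed. For $n \approx 200$ the 95%
interval agrees with the classical Fisher-z interval to well within 0.03,
which is what licenses the Fisher-based shortcut below.

## From posteriors to network ensembles

`frequentist_network()` is the classical pipeline: band-pass filter
(zero-phase 4th-order Butterworth, applied forward and backward so
inter-channel lags are untouched), absolute correlations, threshold to a
target link density. Thresholding keeps the
$\lceil \mathrm{density} \cdot N(N-1)/2 \rceil$ strongest pairs with a
deterministic tie order (weight descending, then row, then column) —
ties have measure zero for real data but must not introduce hidden
randomness in tests.

`bayesian_ensemble()` replaces each point estimate by its posterior,
draws `count` complete weight matrices, and thresholds each to the same
density. One posterior per pair is computed and reused for all draws:
the posterior depends only on $(r, n)$, so recomputing it per draw would
change nothing but the bill. The default `count` of $10^4$ keeps a
desk-size run cheap; ensembles of $10^5$, the scale at which bias
distributions stabilise fully, are reachable by argument.

`fisher_ensemble()` is the corrective shortcut: $Z(\rho) =
\operatorname{arctanh}(\rho)$ is approximately normal with
$\sigma_Z = 1/\sqrt{df - 3}$, so link weights are drawn from
$\mathcal{N}[r, \tanh(\sigma_Z)]$ and thresholded as above. Draws outside
$[-1, 1]$ are clipped; clipping preserves the ranking that thresholding
consumes. For autocorrelated series the nominal $n$ overstates the
information, so the pairwise effective degrees of freedom

$$\frac{1}{df} \approx \frac{1}{n} + \frac{2}{n}
  \sum_{\tau \ge 1} \varrho_{xx}(\tau)\,\varrho_{yy}(\tau)$$

are used instead (`effective_df()`), with biased sample autocorrelations,
a lag cap of $\min(n/4, 100)$, and the sum stopped at the first lag where
both autocorrelations are inside $\pm 2/\sqrt{n}$ — the unbounded sum
would otherwise accumulate pure estimation noise. The result is floored
just above 4 so $\sigma_Z$ stays defined even for pathological
negative-autocorrelation pairs. For white noise $df \to n$; for two AR(1)
series with coefficient $\varphi$ the closed form
$df = n(1-\varphi^2)/(1+\varphi^2)$ is recovered within a few percent at
$n = 10^4$.

## Topological metrics

Seven metrics on binary undirected graphs, the staples of functional
brain-network studies: global efficiency, degree-distribution entropy
(base-2), global clustering (transitivity), degree assortativity, Louvain
modularity, small-worldness, and information content. Conventions that
needed a decision:

* Disconnected pairs contribute $1/d = 0$ to efficiency.
* Assortativity on degree-regular link endpoints is undefined; it is
  returned as flagged `NaN`, and ensemble statistics exclude and count
  such members rather than impute them — imputation would bias the bias.
* Louvain is stochastic: it runs under a dedicated seeded sub-stream,
  with 10 restarts keeping the best-modularity partition. On graphs small
  enough for exhaustive partition search the returned $Q$ is within 5% of
  the true optimum (the suite enumerates all partitions up to 8 nodes).
* Small-worldness normalises clustering and mean geodesic distance by
  averages over Erdős–Rényi $G(N, M)$ graphs with matched node and link
  counts (100 by default), computed on giant components; a network whose
  giant component covers less than 90% of nodes is rejected loudly
  rather than silently patched, since a silent convention would corrupt
  ensemble comparisons. At the densities studied (0.3–0.5) fragmentation
  is rare.
* Information content follows the iterative-merging idea: repeatedly
  merge the pair of nodes with the most similar connection patterns
  (Hamming agreement of adjacency rows, excluding the two merged
  columns; ties to the lowest indices), charging
  $L \cdot H_b(p)$ bits per merge, where $p$ is the disagreement
  fraction over the $L$ compared positions, and taking the union of
  neighbourhoods as the merged row. The iterative-merging idea admits
  variants; this one is deterministic (required for exact reproducibility
  in ensembles) and preserves the property the analysis relies on:
  regular patterns cost 0 bits, random graphs are maximal.

## The bias statistic and its calibration

`metric_bias(freq, samples)` is the fraction of ensemble metric values
*strictly* smaller than the frequentist one; ties count as not-smaller.
0.5 means the point estimate sits at the ensemble median; values near 1
mean overestimation, near 0 underestimation. Under the null where the
frequentist value is exchangeable with the samples the statistic is
uniform on $[0, 1]$ — the suite verifies this with a Kolmogorov–Smirnov
test over 500 replicates — and it is invariant under any monotone
transform applied to both sides.

`bias_vs_sigma()` reproduces the weight-noise toy: ground-truth weights
(1 on links, 0 off) perturbed by Gaussian noise of spread $\sigma$,
thresholded at the truth's own density. The $\sigma$ of that toy is an
interpretation — additive noise on weights is the simplest mechanism
matching "correlation defined with an uncertainty" — and it is the
package's recorded reading. At $\sigma = 0$ the sampled distribution is
degenerate at the frequentist value and the bias is reported as 0.5 by
convention.

## Study conditions for the synthetic experiments

The generators define the conditions under which the pipeline is
exercised; they are fixed once, as follows.

* **Star-coupled map.** $n = 10$ nodes, star adjacency, coupling
  $$x_i(t+1) = (1-\gamma)\,\xi_i(t) +
    \frac{\gamma}{\sum_j a_{ji}} \sum_j a_{ji}\,\xi_j(t),$$
  where $\xi_i(t)$ is a fresh standard-normal draw per node per step.
  Starting each node from a random number and coupling it leaves open
  whether innovations recur at every step; of the candidate readings,
  iterating the coupling on a single initial draw provably collapses
  every node onto the network average, leaving nothing to estimate, and
  adding innovations to an accumulating state produces a random walk at
  $\gamma = 0$. The fresh-innovation map is the unique reading that
  gives independent white noise at $\gamma = 0$, recoverable structure
  at intermediate $\gamma$, and over-synchronised spurious all-to-all
  connectivity as $\gamma \to 1$. Users should be aware this
  interpretation is baked in. A 100-step burn-in is discarded.
* **fMRI emulator.** The same map (a first-order VAR mixing), plus
  observation noise at SNR 10, convolved with a canonical double-gamma
  haemodynamic kernel (main lobe peaking at 6 s, undershoot at 16 s,
  dispersions 1 s, undershoot ratio 1/6, 32 s support, 10 Hz simulation
  rate — each gamma lobe parameterised by its mode), then decimated ×20,
  i.e. TR = 2 s. These are the community-standard haemodynamic
  constants; SNR 10 and ×20 decimation are typical of the scanners
  being emulated.
* **Recovery experiments.** Coupling $\gamma = 0.5$ (the informative
  middle of the range), thresholding at the truth's own density
  ($9/45 = 0.2$ for the star). Long series use $T = 8192$, where exact
  recovery is expected in ≥ 95% of runs; the short-series regime uses
  $T = 256$, where the Bayesian ensemble still spreads over topologies.
* **Bias-direction experiment.** Two-block modular truth on $n = 16$
  nodes, $T = 96$ samples, density 0.5, ensembles of 200, averaged over
  10 independent realisations. Short series are deliberately chosen: the
  bias under study is a finite-sample phenomenon and grows as $T$
  shrinks. Density 0.5 sits at the top of the 0.3–0.5 ladder used for
  real recordings and keeps ensemble members connected, which
  small-worldness requires. At these settings the mean bias for
  clustering, modularity and small-worldness is far above 0.5 and for
  efficiency and information content far below — the overestimation of
  structure and underestimation of randomness-maximal metrics.
* Ensemble sizes in the test suite (100–500) and the 10-seed averages
  are the package's desk-scale defaults; all counts are arguments, and
  full $10^5$-member ensembles are a flag away.

### A caveat on degree entropy

On *these* toys the degree-entropy bias comes out below 0.5, i.e. the
point estimate *under*estimates entropy — matching the star toy, where
the noiseless reconstruction has low entropy and rewired samples can
only raise it. That is not a contradiction of the overestimation story
but a property of the toy family: a star or two-block truth thresholded
at its own density attains (or nearly attains) the *minimum* degree
entropy among graphs with that link count, so no ensemble member can
fall strictly below it. Entropy overestimation requires a ground truth
whose degree distribution is broader than a random graph's — true of
real cortical networks with their heavy-tailed degrees, not of any
star/modular toy. The end-to-end test suite states the real-data
direction for entropy and therefore records a deliberate failure on
synthetic data; the other five directions hold robustly.

## What passing tests do and do not show

The generators produce stationary, bivariate-normal-compatible signals
with known ground truth — exactly the assumptions of the posterior
model. Real EEG violates several: non-stationarity within trials, volume
conduction (shared sources inflating correlations), non-Gaussian
artefacts, and 64-channel scale. Passing the synthetic suite shows the
machinery is correct and the uncertainty phenomenology is as described;
it does not certify effect sizes on real recordings. The UCI trial
reader (`read_uci_eeg_trial()`) lets users run the identical pipeline on
the public alcoholism EEG archive, but no real-data numbers are asserted
anywhere in the package.

## Known limitations

* Pearson correlation is the only connectivity metric; the bias
  machinery is metric-agnostic, but posteriors for coherence, mutual
  information etc. are not provided.
* Posteriors are per-link marginals; the joint posterior over the whole
  correlation matrix (which is constrained to be positive definite) is
  not modelled.
* Grid-based quadrature only; no MCMC, hence no support for priors that
  concentrate mass outside the grid resolution.
* Binary undirected metrics only; weighted and directed variants are out
  of scope.
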