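#' Ground-truth network structures
#'
#' `star_adjacency(n)` builds the star on n nodes (node 1 is the hub linked
#' to every other node; no peripheral-peripheral links).
#' `modular_adjacency(n)` builds two equal fully-connected blocks with no
#' inter-block links. Both return 0/1 symmetric matrices with zero
#' diagonal, of class `binary_network`, with attribute `kind`.
#'
#' @param n number of nodes (star: >= 3; modular: even, >= 4).
#' @return A `binary_network` ground truth.
#' @export
star_adjacency <- function(n) {
  if (!is.numeric(n) || n < 3)
    stop_bayesconn("too_small", "a star needs at least 3 nodes")
  n <- as.integer(n)
  A <- matrix(0L, n, n)
  A[1, -1] <- 1L
  A[-1, 1] <- 1L
  structure(binary_network(A), kind = "star")
}

#' @rdname star_adjacency
#' @export
modular_adjacency <- function(n) {
  if (!is.numeric(n) || n < 4 || n %% 2 != 0)
    stop_bayesconn("too_small",
                   "the two-block modular structure needs an even n >= 4")
  n <- as.integer(n)
  half <- n / 2
  A <- matrix(0L, n, n)
  A[seq_len(half), seq_len(half)] <- 1L
  A[(half + 1):n, (half + 1):n] <- 1L
  diag(A) <- 0L
  structure(binary_network(A), kind = "modular")
}

# True link density of a ground-truth structure.
structure_density <- function(A) sum(A) / (nrow(A) * (nrow(A) - 1))

#' Star-coupled noise map dynamics
#'
#' Generates N coupled time series from a ground-truth adjacency. At every
#' step each node's output starts as a fresh standard-normal draw
#' \eqn{\xi_i(t)} which the coupling map then mixes with its neighbours':
#' \deqn{x_i(t+1) = (1-\gamma)\,\xi_i(t) +
#'   \frac{\gamma}{\sum_j a_{ji}} \sum_j a_{ji}\,\xi_j(t).}
#' At \eqn{\gamma = 0} the channels are independent white noise; at
#' intermediate coupling the linked pairs are the most correlated ones (so
#' the structure is recoverable); as \eqn{\gamma \to 1} the system
#' over-synchronises and spurious all-to-all connectivity appears. Note
#' this is a noise-driven map, not an accumulating recursion: iterating the
#' coupling on a single initial draw would collapse all nodes to consensus
#' and leave nothing to estimate. A burn-in of 100 steps is generated and
#' discarded.
#'
#' @param structure a ground-truth `binary_network` (e.g.
#'   [star_adjacency()]); no node may be isolated.
#' @param gamma coupling constant in \eqn{[0, 1]}.
#' @param t_len number of samples to return (>= 7).
#' @param seed integer seed (dynamics sub-stream).
#' @param fs nominal sampling rate attached to the output (default 1 Hz).
#' @return A [ts_set()] of dimension N x `t_len`.
#' @export
coupled_dynamics <- function(structure, gamma, t_len, seed = 1L, fs = 1) {
  A <- binary_network(structure)
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must lie in [0, 1]")
  stopifnot(t_len >= 7)
  k <- colSums(A)
  if (any(k == 0))
    stop_bayesconn("zero_normaliser",
                   paste("isolated node(s):",
                         paste(which(k == 0) - 1L, collapse = ", ")))
  n <- nrow(A)
  W <- (1 - gamma) * diag(n) + gamma * t(t(unclass(A)) / k)
  burn <- 100L
  Xi <- with_substream(seed, "dynamics",
                       matrix(rnorm(n * (t_len + burn)), n, t_len + burn))
  X <- W %*% Xi
  ts_set(X[, (burn + 1):(burn + t_len), drop = FALSE], fs = fs,
         labels = paste0("node", seq_len(n) - 1L))
}

#' Relative topological error
#'
#' Mean absolute disagreement between a ground-truth and a reconstructed
#' adjacency matrix over the n(n-1) ordered off-diagonal pairs:
#' \eqn{e = \frac{1}{n(n-1)} \sum_{i \ne j} |a_{ij} - f_{ij}|}. 0 means
#' perfect recovery, 1 complete disagreement.
#'
#' @param truth,observed `binary_network`s (or 0/1 matrices) of equal size.
#' @return e in \eqn{[0, 1]}.
#' @export
relative_error <- function(truth, observed) {
  truth <- binary_network(truth)
  observed <- binary_network(observed)
  if (nrow(truth) != nrow(observed))
    stop_bayesconn("dimension", "truth and observed networks differ in size")
  n <- nrow(truth)
  sum(abs(unclass(truth) - unclass(observed))) / (n * (n - 1))
}

#' Canonical double-gamma haemodynamic response function
#'
#' The BOLD impulse response modelled as a positive gamma lobe peaking at
#' `peak_delay` seconds minus a scaled gamma undershoot peaking at
#' `undershoot_delay` seconds. Each lobe is parameterised by its mode:
#' shape = 1 + delay/dispersion, rate = 1/dispersion. The kernel is scaled
#' to unit peak.
#'
#' @param peak_delay main lobe mode in s (default 6).
#' @param undershoot_delay undershoot mode in s (default 16).
#' @param peak_dispersion,undershoot_dispersion lobe widths in s (default
#'   1).
#' @param undershoot_ratio relative undershoot amplitude (default 1/6).
#' @param duration kernel length in s (default 32).
#' @param fs simulation rate in Hz (default 10).
#' @return Numeric kernel sampled at `fs`, attribute `fs` attached.
#' @export
hrf_kernel <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, duration = 32, fs = 10) {
  stopifnot(peak_delay > 0, undershoot_delay > peak_delay, duration > 0,
            fs > 0, undershoot_ratio >= 0)
  t <- seq(0, duration, by = 1 / fs)
  main <- dgamma(t, shape = 1 + peak_delay / peak_dispersion,
                 rate = 1 / peak_dispersion)
  under <- dgamma(t, shape = 1 + undershoot_delay / undershoot_dispersion,
                  rate = 1 / undershoot_dispersion)
  h <- main - undershoot_ratio * under
  h <- h / max(h)
  structure(h, fs = fs)
}

#' Causal same-length convolution with a kernel
#'
#' Convolves each row of a channel-by-sample matrix with the kernel,
#' keeping the first T samples (causal filtering). Linear: zero input gives
#' zero output; a unit impulse reproduces the kernel.
#'
#' @param values numeric matrix (channels x samples) or vector.
#' @param kernel numeric kernel, e.g. [hrf_kernel()].
#' @return Matrix of the same dimension as `values`.
#' @export
hrf_convolve <- function(values, kernel) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  t_len <- ncol(values)
  stopifnot(length(kernel) < t_len)
  out <- t(apply(values, 1L, function(x) {
    convolve(x, rev(kernel), type = "open")[seq_len(t_len)]
  }))
  out
}

#' BOLD-like fMRI signal emulator
#'
#' Emulates the signal chain of an fMRI experiment on top of the coupled
#' noise map: (1) coupled neural dynamics via [coupled_dynamics()] (a
#' first-order vector-autoregressive mixing of innovations) plus additive
#' Gaussian observation noise at the given signal-to-noise ratio; (2)
#' per-channel convolution with the canonical double-gamma HRF; (3)
#' decimation by `downsample` to emulate the scanner repetition time
#' (default: 10 Hz simulation decimated x20, i.e. TR = 2 s).
#'
#' @param structure ground-truth `binary_network`.
#' @param gamma coupling constant in \eqn{[0, 1]}.
#' @param t_len number of simulation samples before down-sampling; must
#'   exceed the kernel length.
#' @param seed integer seed.
#' @param hrf kernel from [hrf_kernel()] (default canonical at 10 Hz).
#' @param snr ratio of neural signal variance to observation noise
#'   variance (default 10).
#' @param downsample integer decimation factor (>= 1, default 20).
#' @return A [ts_set()] of dimension N x `floor(t_len / downsample)`.
#' @export
fmri_emulate <- function(structure, gamma, t_len, seed = 1L,
                         hrf = hrf_kernel(), snr = 10, downsample = 20L) {
  downsample <- as.integer(downsample)
  stopifnot(downsample >= 1, snr > 0)
  if (length(hrf) >= t_len / downsample)
    stop("kernel duration must be shorter than the down-sampled series")
  neural <- coupled_dynamics(structure, gamma, t_len, seed = seed,
                             fs = attr(hrf, "fs") %||% 10)
  vals <- neural$values
  noise_sd <- sqrt(mean(apply(vals, 1L, function(x) var(x))) / snr)
  vals <- vals + with_substream(seed, "noise",
                                matrix(rnorm(length(vals), sd = noise_sd),
                                       nrow(vals), ncol(vals)))
  bold <- hrf_convolve(vals, as.numeric(hrf))
  keep <- seq(1L, ncol(bold), by = downsample)
  ts_set(bold[, keep, drop = FALSE], fs = neural$fs / downsample,
         labels = neural$labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative-error surface over coupling and series length
#'
#' Runs the reconstruction experiment on a grid of coupling constants and
#' series lengths, for the frequentist or the Bayesian method, and reports
#' the mean relative topological error per cell. Bayesian cells average
#' the error over the ensemble members.
#'
#' @param structure ground-truth `binary_network`.
#' @param gamma_grid,t_grid numeric grids of coupling constants and series
#'   lengths.
#' @param method `"frequentist"` or `"bayesian"`.
#' @param reps independent repetitions per cell (>= 1).
#' @param seed integer seed.
#' @param density link density used for thresholding; defaults to the
#'   ground truth's own density.
#' @param count Bayesian ensemble size per repetition (default 100).
#' @param model `"map"` for the plain coupled map, `"fmri"` for the BOLD
#'   emulator (then `t_grid` counts down-sampled output samples).
#' @return A tidy data frame (gamma, t_len, method, e_mean, e_sd, reps).
#' @export
length_sweep <- function(structure, gamma_grid, t_grid,
                         method = c("frequentist", "bayesian"), reps = 5L,
                         seed = 1L, density = NULL, count = 100L,
                         model = c("map", "fmri")) {
  method <- match.arg(method)
  model <- match.arg(model)
  stopifnot(reps >= 1)
  truth <- binary_network(structure)
  if (is.null(density)) density <- structure_density(truth)
  rows <- list()
  for (g in gamma_grid) {
    for (tl in t_grid) {
      es <- vapply(seq_len(reps), function(rep) {
        s <- substream_seed(seed + 1000L * rep, "generic")
        ts <- if (model == "map") {
          coupled_dynamics(truth, g, tl, seed = s)
        } else {
          fmri_emulate(truth, g, tl * 20L, seed = s)
        }
        if (method == "frequentist") {
          relative_error(truth, frequentist_network(ts, density))
        } else {
          ens <- bayesian_ensemble(ts, density, count = count, seed = s)
          mean(vapply(ens$networks, relative_error, numeric(1),
                      truth = truth))
        }
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(gamma = g, t_len = tl, method = method,
                   e_mean = mean(es), e_sd = if (reps > 1) sd(es) else 0,
                   reps = reps)
    }
  }
  do.call(rbind, rows)
}
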