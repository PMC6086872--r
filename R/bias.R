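#' Metric distribution over an ensemble
#'
#' Evaluates one topological metric on every member of a network ensemble,
#' keeping the finite values and counting the members on which the metric
#' is undefined (e.g. assortativity on a degree-regular member).
#'
#' @param ensemble a `network_ensemble` from [bayesian_ensemble()] or
#'   [fisher_ensemble()].
#' @param metric metric name, see [network_metrics()].
#' @param seed seed for stochastic metrics.
#' @param n_ref reference-graph count for small-worldness.
#' @return A list of class `metric_distribution` with `metric`, `samples`
#'   (finite values, one per valid member), `n_excluded`.
#' @export
ensemble_metric <- function(ensemble, metric, seed = 1L, n_ref = 20L) {
  stopifnot(inherits(ensemble, "network_ensemble"))
  vals <- vapply(seq_along(ensemble$networks), function(i) {
    network_metrics(ensemble$networks[[i]], metrics = metric,
                    seed = seed + i, n_ref = n_ref)[[1]]
  }, numeric(1))
  keep <- is.finite(vals)
  structure(list(metric = metric, samples = vals[keep],
                 n_excluded = sum(!keep)),
            class = "metric_distribution")
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf(
    "<metric_distribution> %s: %d samples (%d excluded), mean %.4f\n",
    x$metric, length(x$samples), x$n_excluded, mean(x$samples)))
  invisible(x)
}

#' Bias of a frequentist metric value against an ensemble
#'
#' The fraction of sampled (ensemble) metric values strictly smaller than
#' the frequentist one; ties count as not-smaller. A bias of 0.5 means the
#' frequentist value coincides with the median of the sampled
#' distribution; values near 1 indicate frequentist overestimation, values
#' near 0 underestimation.
#'
#' @param freq the frequentist (point-estimate) metric value.
#' @param samples a numeric vector of sampled metric values, or a
#'   `metric_distribution`.
#' @return Bias fraction in \eqn{[0, 1]}.
#' @export
metric_bias <- function(freq, samples) {
  if (inherits(samples, "metric_distribution")) samples <- samples$samples
  if (length(samples) == 0)
    stop_bayesconn("no_data", "bias needs at least one sampled value")
  mean(samples < freq)
}

#' Log2 frequentist/ensemble-mean ratio
#'
#' \eqn{\log_2(\mathrm{freq}/\mathrm{bayes})}: 0 means agreement, +1 a
#' factor-2 frequentist overestimation. Defined for strictly positive
#' values only.
#'
#' @param freq frequentist metric value (> 0).
#' @param bayes_mean ensemble mean metric value (> 0).
#' @return The log2 ratio.
#' @export
log2_ratio <- function(freq, bayes_mean) {
  if (!is.finite(freq) || !is.finite(bayes_mean) || freq <= 0 ||
      bayes_mean <= 0)
    stop_bayesconn("sign_domain",
                   "log2_ratio requires strictly positive values")
  log2(freq / bayes_mean)
}

#' Fraction of the frequentist error removed by a correction
#'
#' Treating the Bayesian ensemble mean as the reference, the frequentist
#' error is `|freq - bayes_mean|`; the correction recovers
#' \eqn{1 - |corrected - bayes| / |freq - bayes|} of it, clipped to
#' \eqn{[0, 1]}.
#'
#' @param freq frequentist metric value.
#' @param bayes_mean Bayesian ensemble mean (the reference).
#' @param corrected_mean corrected (e.g. Fisher-ensemble) mean.
#' @return Recovered fraction in \eqn{[0, 1]}.
#' @export
error_reduction <- function(freq, bayes_mean, corrected_mean) {
  if (freq == bayes_mean)
    stop_bayesconn("undefined_reduction",
                   "frequentist error is zero; reduction undefined")
  min(max(1 - abs(corrected_mean - bayes_mean) / abs(freq - bayes_mean),
          0), 1)
}

#' Entropy and bias as functions of link uncertainty
#'
#' The weight-noise toy experiment: ground-truth link weights (1 on true
#' links, 0 elsewhere) are perturbed with i.i.d. Gaussian noise of
#' standard deviation sigma, each perturbed weight matrix is thresholded
#' at the structure's true density, and the degree-distribution entropy of
#' the sampled networks is compared with the entropy of the noiseless
#' (frequentist) network. At sigma = 0 every sample equals the truth and
#' the bias is reported as 0.5 by convention (the distribution is
#' degenerate at the frequentist value).
#'
#' @param structure `"star"` or `"modular"` (or a `binary_network`).
#' @param sigma_grid non-negative noise levels.
#' @param count sampled networks per sigma (default 500).
#' @param seed integer seed.
#' @param n nodes when `structure` is given by name (default 10).
#' @return A data frame (sigma, mean_entropy, freq_entropy, bias).
#' @export
bias_vs_sigma <- function(structure = c("star", "modular"),
                          sigma_grid = seq(0, 0.5, by = 0.1), count = 500L,
                          seed = 1L, n = 10L) {
  if (is.character(structure)) {
    structure <- switch(match.arg(structure),
                        star = star_adjacency(n),
                        modular = modular_adjacency(n))
  }
  truth <- binary_network(structure)
  if (any(sigma_grid < 0)) stop("sigma must be non-negative")
  count <- as.integer(count)
  dens <- structure_density(truth)
  nn <- nrow(truth)
  idx <- upper_pairs(nn)
  w0 <- unclass(truth)[idx]
  freq_h <- degree_entropy(threshold_to_density(
    unclass(truth) * 1.0, dens))
  rows <- lapply(seq_along(sigma_grid), function(si) {
    sg <- sigma_grid[si]
    if (sg == 0) {
      return(data.frame(sigma = 0, mean_entropy = freq_h,
                        freq_entropy = freq_h, bias = 0.5))
    }
    Z <- with_substream(seed + si, "noise",
                        matrix(rnorm(length(w0) * count), length(w0),
                               count))
    nets <- threshold_weight_draws(w0 + sg * Z, nn, dens)
    hs <- vapply(nets, degree_entropy, numeric(1))
    data.frame(sigma = sg, mean_entropy = mean(hs), freq_entropy = freq_h,
               bias = mean(hs < freq_h))
  })
  do.call(rbind, rows)
}

#' Frequentist-vs-Bayesian bias report for a time-series set
#'
#' The full comparison pipeline: for every requested band and link
#' density, reconstruct the frequentist network and a Bayesian ensemble,
#' evaluate the requested metrics on both, and tabulate the bias, the log2
#' frequentist/Bayesian ratio (where both values are positive) and the
#' ensemble mean. The bias is reported as `NA` when fewer than 100 valid
#' ensemble values are available.
#'
#' @param ts a [ts_set()].
#' @param densities link densities (default the 0.30-0.50 ladder).
#' @param bands band names (default `"raw"`).
#' @param metrics metric names, see [network_metrics()].
#' @param count ensemble size (default 1000).
#' @param seed integer seed.
#' @param n_ref reference graphs for small-worldness (default 20).
#' @return A data frame of class `bias_report` with one row per (metric,
#'   density, band).
#' @export
bias_report <- function(ts, densities = seq(0.30, 0.50, by = 0.05),
                        bands = "raw",
                        metrics = c("efficiency", "degree_entropy",
                                    "clustering", "assortativity",
                                    "modularity", "small_worldness",
                                    "information_content"),
                        count = 1000L, seed = 1L, n_ref = 20L) {
  stopifnot(inherits(ts, "ts_set"))
  rows <- list()
  for (band in bands) {
    for (dens in densities) {
      freq <- frequentist_network(ts, dens, band = band)
      ens <- bayesian_ensemble(ts, dens, count = count, seed = seed,
                               band = band)
      fv <- network_metrics(freq, metrics = metrics, seed = seed,
                            n_ref = n_ref)
      for (m in metrics) {
        dist <- ensemble_metric(ens, m, seed = seed, n_ref = n_ref)
        nval <- length(dist$samples)
        emean <- if (nval > 0) mean(dist$samples) else NA_real_
        b <- if (nval >= 100 && is.finite(fv[[m]]))
          metric_bias(fv[[m]], dist) else NA_real_
        lr <- if (is.finite(fv[[m]]) && !is.na(emean) && fv[[m]] > 0 &&
                  emean > 0) log2(fv[[m]] / emean) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, density = dens, band = band,
          frequentist = unname(fv[[m]]), bayes_mean = emean, bias = b,
          log2_ratio = lr, n_samples = nval,
          n_excluded = dist$n_excluded)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bias_report", class(out))
  out
}

#' Serialise a bias report
#'
#' Writes the tidy table as tab-separated text and, optionally, as JSON.
#'
#' @param report a [bias_report()] data frame.
#' @param path output file path (`.json` extension switches to JSON).
#' @export
write_bias_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    write.table(report, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
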