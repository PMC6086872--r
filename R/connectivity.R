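#' Multivariate time-series container
#'
#' Bundles an N x T channel-by-sample matrix with its sampling rate and
#' channel labels. All downstream estimation (correlation matrices, band
#' filtering, network reconstruction) consumes this container.
#'
#' @param values numeric matrix, channels in rows, samples in columns. A
#'   plain vector is treated as a single channel.
#' @param fs sampling rate in Hz (positive).
#' @param labels optional character vector of channel names; defaults to
#'   `ch1, ch2, ...`.
#' @return An object of class `ts_set`.
#' @export
ts_set <- function(values, fs = 1, labels = NULL) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values)))
    stop("time series values must all be finite")
  if (nrow(values) < 2) stop("a ts_set needs at least 2 channels")
  if (ncol(values) < 7) stop("a ts_set needs at least 7 samples")
  if (!is.numeric(fs) || fs <= 0) stop("sampling rate must be positive")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(values)))
  stopifnot(length(labels) == nrow(values))
  rownames(values) <- labels
  structure(list(values = values, fs = fs, labels = as.character(labels)),
            class = "ts_set")
}

#' @export
print.ts_set <- function(x, ...) {
  cat(sprintf("<ts_set> %d channels x %d samples @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

#' @export
dim.ts_set <- function(x) dim(x$values)

#' Canonical EEG frequency bands
#'
#' Returns a band descriptor used by [bandpass_filter()]. The canonical
#' bands are alpha 8-13 Hz, beta1 13-20 Hz, beta2 20-30 Hz, gamma 30-50 Hz;
#' `"raw"` means no filtering.
#'
#' @param name one of `"raw"`, `"alpha"`, `"beta1"`, `"beta2"`, `"gamma"`.
#' @return A list of class `frequency_band` with `name`, `low`, `high` (Hz).
#' @export
frequency_band <- function(name = c("raw", "alpha", "beta1", "beta2",
                                    "gamma")) {
  name <- match.arg(name)
  lims <- switch(name,
                 raw   = c(NA_real_, NA_real_),
                 alpha = c(8, 13),
                 beta1 = c(13, 20),
                 beta2 = c(20, 30),
                 gamma = c(30, 50))
  structure(list(name = name, low = lims[1], high = lims[2]),
            class = "frequency_band")
}

#' Zero-phase band-pass filtering
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), i.e. zero phase distortion, so inter-channel lag
#' structure is preserved. The `"raw"` band returns the input unchanged.
#'
#' @param ts a [ts_set()].
#' @param band a [frequency_band()] or band name string.
#' @return A filtered `ts_set`.
#' @export
bandpass_filter <- function(ts, band) {
  stopifnot(inherits(ts, "ts_set"))
  if (is.character(band)) band <- frequency_band(band)
  stopifnot(inherits(band, "frequency_band"))
  if (band$name == "raw") return(ts)
  if (ts$fs <= 2 * band$high)
    stop_bayesconn("sampling_rate",
                   sprintf("band %s needs fs > %g Hz (got %g)", band$name,
                           2 * band$high, ts$fs))
  bf <- signal::butter(4, c(band$low, band$high) / (ts$fs / 2),
                       type = "pass")
  out <- t(apply(ts$values, 1L, function(x) signal::filtfilt(bf, x)))
  ts_set(out, fs = ts$fs, labels = ts$labels)
}

#' Pearson sample correlation of two series
#'
#' The classical frequentist point estimate of connectivity between two
#' channels.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Product-moment correlation in \eqn{[-1, 1]}.
#' @export
sample_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop_bayesconn("degenerate_series",
                   "sample correlation undefined for a zero-variance series")
  cor(x, y)
}

#' Frequentist correlation matrix of a time-series set
#'
#' Pairwise Pearson correlations mapped into a symmetric adjacency matrix;
#' the diagonal is set to zero (self-links excluded). With `use_abs = TRUE`
#' (the default) absolute values are stored, matching strength-based
#' thresholding.
#'
#' @param ts a [ts_set()].
#' @param use_abs store `|r|` instead of signed `r`.
#' @return An N x N symmetric numeric matrix with zero diagonal, of class
#'   `weight_matrix`, with attribute `semantics` `"abs-r"` or `"signed-r"`.
#' @export
correlation_matrix <- function(ts, use_abs = TRUE) {
  stopifnot(inherits(ts, "ts_set"))
  sds <- apply(ts$values, 1L, sd)
  if (any(sds == 0))
    stop_bayesconn("degenerate_series",
                   paste("zero-variance channel(s):",
                         paste(ts$labels[sds == 0], collapse = ", ")))
  R <- cor(t(ts$values))
  if (use_abs) R <- abs(R)
  diag(R) <- 0
  R <- (R + t(R)) / 2  # enforce exact symmetry against rounding
  structure(R, class = c("weight_matrix", class(R)),
            semantics = if (use_abs) "abs-r" else "signed-r")
}

#' Effective degrees of freedom of an autocorrelated pair
#'
#' For serially correlated series the nominal sample size n overstates the
#' information available for estimating their correlation. The effective
#' degrees of freedom are
#' \deqn{1/df \approx 1/n + (2/n) \sum_{\tau \ge 1}
#'   \varrho_{xx}(\tau)\,\varrho_{yy}(\tau),}
#' with \eqn{\varrho} the biased (divide-by-n) sample autocorrelations. The
#' lag sum is truncated at `lag_cap` and, further, at the first lag where
#' both autocorrelations fall inside the \eqn{\pm 2/\sqrt{n}} noise band,
#' which stabilises the estimate. For white noise df equals n (up to
#' estimation noise); positive autocorrelation lowers it. The result is
#' floored at just above 4 so the Fisher standard deviation
#' \eqn{1/\sqrt{df-3}} stays defined.
#'
#' @param x,y numeric vectors of equal length.
#' @param lag_cap maximum lag in the sum; default `min(n/4, 100)`.
#' @return A list of class `effective_df` with `df`, `n`, `lag_cap`.
#' @export
effective_df <- function(x, y, lag_cap = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (is.null(lag_cap)) lag_cap <- floor(min(n / 4, 100))
  lag_cap <- as.integer(lag_cap)
  stopifnot(lag_cap >= 1, lag_cap < n)
  ax <- acf(x, lag.max = lag_cap, plot = FALSE, demean = TRUE)$acf[-1]
  ay <- acf(y, lag.max = lag_cap, plot = FALSE, demean = TRUE)$acf[-1]
  noise <- 2 / sqrt(n)
  inside <- abs(ax) < noise & abs(ay) < noise
  cut <- if (any(inside)) which(inside)[1] - 1L else lag_cap
  s <- if (cut >= 1) sum(ax[seq_len(cut)] * ay[seq_len(cut)]) else 0
  inv <- 1 / n + (2 / n) * s
  df_floor <- 4 + 1e-9
  df <- if (inv <= 0) n else 1 / inv
  df <- max(df, df_floor)
  structure(list(df = df, n = n, lag_cap = lag_cap), class = "effective_df")
}

#' @export
print.effective_df <- function(x, ...) {
  cat(sprintf("<effective_df> df = %.2f of n = %d (lag cap %d)\n", x$df,
              x$n, x$lag_cap))
  invisible(x)
}

#' Fisher-z standard deviation
#'
#' The Fisher transform \eqn{Z(\rho) = \mathrm{arctanh}(\rho)} of a sample
#' correlation is approximately normal with standard deviation
#' \eqn{\sigma_Z = 1/\sqrt{df - 3}}.
#'
#' @param df effective degrees of freedom (> 3); an [effective_df()] object
#'   is also accepted.
#' @return \eqn{\sigma_Z}.
#' @export
fisher_sigma <- function(df) {
  if (inherits(df, "effective_df")) df <- df$df
  if (!is.numeric(df) || any(df <= 3))
    stop_bayesconn("insufficient_df",
                   "fisher_sigma requires df > 3")
  1 / sqrt(df - 3)
}

#' Fisher sampling law for a link weight
#'
#' Back-transforming the Fisher-z normal law gives the cheap surrogate for
#' the Bayesian posterior of a link weight: approximately normal with mean
#' `r` and standard deviation \eqn{\tanh(\sigma_Z)}. Sampling from it is
#' done by [fisher_ensemble()].
#'
#' @param r sample correlation in \eqn{[-1, 1]}.
#' @param df effective degrees of freedom (> 3).
#' @return A list of class `fisher_law` with `mean` and `sd`.
#' @export
fisher_weight_distribution <- function(r, df) {
  if (!is.numeric(r) || abs(r) > 1)
    stop_bayesconn("invalid_correlation", "r must lie in [-1, 1]")
  structure(list(mean = r, sd = tanh(fisher_sigma(df))),
            class = "fisher_law")
}

#' @export
print.fisher_law <- function(x, ...) {
  cat(sprintf("<fisher_law> N[mean %.4f, sd %.4f]\n", x$mean, x$sd))
  invisible(x)
}

# Pairwise effective-df matrix (upper-triangular symmetric, NA diagonal).
#' Pairwise effective degrees of freedom for all channel pairs
#'
#' @param ts a [ts_set()].
#' @param lag_cap see [effective_df()].
#' @return Symmetric N x N matrix of df values with `NA` diagonal.
#' @export
effective_df_matrix <- function(ts, lag_cap = NULL) {
  stopifnot(inherits(ts, "ts_set"))
  n <- nrow(ts$values)
  D <- matrix(NA_real_, n, n)
  idx <- upper_pairs(n)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    D[i, j] <- D[j, i] <- effective_df(ts$values[i, ], ts$values[j, ],
                                       lag_cap)$df
  }
  D
}
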