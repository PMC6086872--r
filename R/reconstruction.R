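#' Threshold a weight matrix to a fixed link density
#'
#' Retains the `ceiling(density * N(N-1)/2)` strongest node pairs as binary
#' links. Ties are broken deterministically by (weight descending, row
#' ascending, column ascending), so repeated calls give identical networks.
#'
#' @param W symmetric numeric matrix with zero diagonal (a
#'   [correlation_matrix()] output or any weight matrix).
#' @param density fraction of possible links to keep, in (0, 1].
#' @return An object of class `binary_network`: a 0/1 symmetric matrix with
#'   attributes `density` (achieved) and `density_requested`.
#' @export
threshold_to_density <- function(W, density) {
  if (!is.numeric(density) || length(density) != 1L || density <= 0 ||
      density > 1)
    stop_bayesconn("invalid_density", "density must lie in (0, 1]")
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  n <- nrow(W)
  idx <- upper_pairs(n)
  w <- W[idx]
  m <- ceiling(density * nrow(idx))
  ord <- order(-w, idx[, 1], idx[, 2])
  keep <- ord[seq_len(m)]
  A <- matrix(0L, n, n)
  A[idx[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  binary_network(A, density_requested = density)
}

#' Binary undirected network
#'
#' Wraps a 0/1 symmetric adjacency matrix with its achieved link density.
#'
#' @param A 0/1 symmetric matrix with zero diagonal.
#' @param density_requested the density that was asked of the thresholding
#'   step (defaults to the achieved density).
#' @return An object of class `binary_network`.
#' @export
binary_network <- function(A, density_requested = NULL) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  A <- matrix(as.integer(A != 0), nrow(A), ncol(A))
  if (any(A != t(A))) stop("adjacency matrix must be symmetric")
  diag(A) <- 0L
  ach <- sum(A) / (nrow(A) * (nrow(A) - 1))
  structure(A, class = c("binary_network", "matrix", "array"),
            density = ach,
            density_requested = if (is.null(density_requested)) ach else
              density_requested)
}

#' @export
print.binary_network <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<binary_network> %d nodes, %d links (density %.3f)\n", n,
              sum(x) / 2, attr(x, "density")))
  invisible(x)
}

as_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(unclass(A)[, , drop = FALSE],
                                      mode = "undirected", diag = FALSE)
}

#' Frequentist network reconstruction
#'
#' The classical pipeline: band-pass filter, pairwise Pearson correlation
#' (absolute value by default), threshold to the requested link density.
#' Fully deterministic.
#'
#' @param ts a [ts_set()].
#' @param density link density in (0, 1].
#' @param band a [frequency_band()] or name; default `"raw"`.
#' @param use_abs use `|r|` as link weight (default `TRUE`).
#' @return A `binary_network`.
#' @export
frequentist_network <- function(ts, density, band = "raw", use_abs = TRUE) {
  W <- correlation_matrix(bandpass_filter(ts, band), use_abs = use_abs)
  threshold_to_density(W, density)
}

new_ensemble <- function(networks, method, seed, density, source = NULL) {
  structure(list(networks = networks, method = method, seed = seed,
                 count = length(networks), density = density,
                 n_nodes = nrow(networks[[1]]), source = source),
            class = "network_ensemble")
}

#' @export
print.network_ensemble <- function(x, ...) {
  cat(sprintf(
    "<network_ensemble> %d %s networks, %d nodes, density %.3f, seed %d\n",
    x$count, x$method, x$n_nodes, x$density, x$seed))
  invisible(x)
}

# Sample a P x count matrix of link weights (rows = upper-triangle pairs)
# and threshold each column into a binary network.
threshold_weight_draws <- function(draws, n, density) {
  idx <- upper_pairs(n)
  m <- ceiling(density * nrow(idx))
  lapply(seq_len(ncol(draws)), function(c) {
    w <- draws[, c]
    ord <- order(-w, idx[, 1], idx[, 2])
    A <- matrix(0L, n, n)
    A[idx[ord[seq_len(m)], , drop = FALSE]] <- 1L
    binary_network(A + t(A), density_requested = density)
  })
}

#' Bayesian ensemble of reconstructed networks
#'
#' The uncertainty-aware counterpart of [frequentist_network()]: for every
#' channel pair the posterior of the correlation coefficient given its
#' sample correlation is computed once, `count` weights are drawn from it,
#' and each complete weight matrix is thresholded to the requested density,
#' yielding `count` binary networks whose spread reflects link-weight
#' uncertainty.
#'
#' @param ts a [ts_set()].
#' @param density link density in (0, 1].
#' @param count number of ensemble members (>= 1).
#' @param seed integer seed; identical seeds give bit-identical ensembles.
#' @param band a [frequency_band()] or name; default `"raw"`.
#' @param use_abs threshold on `|rho|` draws (default `TRUE`).
#' @param method posterior kernel, `"approximate"` (default) or `"exact"`.
#' @param grid_size posterior grid resolution.
#' @return A `network_ensemble` with `method = "bayesian"`.
#' @export
bayesian_ensemble <- function(ts, density, count = 1e4, seed = 1L,
                              band = "raw", use_abs = TRUE,
                              method = c("approximate", "exact"),
                              grid_size = 2001L) {
  method <- match.arg(method)
  stopifnot(count >= 1)
  count <- as.integer(count)
  tsf <- bandpass_filter(ts, band)
  R <- correlation_matrix(tsf, use_abs = FALSE)
  n_obs <- ncol(tsf$values)
  nn <- nrow(R)
  idx <- upper_pairs(nn)
  U <- with_substream(seed, "posterior_sampling",
                      matrix(runif(nrow(idx) * count), nrow(idx), count))
  draws <- matrix(NA_real_, nrow(idx), count)
  for (k in seq_len(nrow(idx))) {
    post <- correlation_posterior(R[idx[k, 1], idx[k, 2]], n_obs,
                                  method = method, grid_size = grid_size)
    draws[k, ] <- posterior_quantile(post, U[k, ])
  }
  if (use_abs) draws <- abs(draws)
  nets <- threshold_weight_draws(draws, nn, density)
  new_ensemble(nets, "bayesian", as.integer(seed), density,
               source = list(r_matrix = R, n = n_obs, band = band,
                             use_abs = use_abs, posterior = method))
}

#' Fisher-corrected ensemble of networks
#'
#' The cheap surrogate for [bayesian_ensemble()]: each link weight is drawn
#' from the back-transformed Fisher law \eqn{N[r, \tanh(\sigma_Z)]} with
#' \eqn{\sigma_Z = 1/\sqrt{df-3}} from the pairwise effective degrees of
#' freedom, and every sampled weight matrix is thresholded to the density
#' of the original frequentist network. Draws falling outside \eqn{[-1, 1]}
#' are clipped (the normal law has unbounded support; clipping preserves
#' ranking).
#'
#' @param r_matrix symmetric correlation (weight) matrix, e.g. from
#'   [correlation_matrix()].
#' @param df_matrix symmetric matrix of pairwise effective degrees of
#'   freedom ([effective_df_matrix()]), or a single number used for all
#'   pairs. All values must exceed 3.
#' @param density link density in (0, 1].
#' @param count number of ensemble members.
#' @param seed integer seed.
#' @param use_abs threshold on absolute sampled weights (default matches
#'   the `semantics` attribute of `r_matrix`, else `TRUE`).
#' @return A `network_ensemble` with `method = "fisher"`.
#' @export
fisher_ensemble <- function(r_matrix, df_matrix, density, count = 1e4,
                            seed = 1L, use_abs = NULL) {
  stopifnot(is.matrix(r_matrix), nrow(r_matrix) == ncol(r_matrix),
            count >= 1)
  count <- as.integer(count)
  nn <- nrow(r_matrix)
  if (length(df_matrix) == 1L) df_matrix <- matrix(df_matrix, nn, nn)
  idx <- upper_pairs(nn)
  dfv <- df_matrix[idx]
  if (any(dfv <= 3)) {
    bad <- idx[dfv <= 3, , drop = FALSE]
    stop_bayesconn("insufficient_df", paste0(
      "effective df <= 3 for pair(s): ",
      paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " ")))
  }
  if (is.null(use_abs)) {
    sem <- attr(r_matrix, "semantics")
    use_abs <- is.null(sem) || identical(sem, "abs-r")
  }
  rv <- r_matrix[idx]
  sdv <- tanh(1 / sqrt(dfv - 3))
  Z <- with_substream(seed, "fisher_sampling",
                      matrix(rnorm(length(rv) * count), length(rv), count))
  draws <- pmin(pmax(rv + sdv * Z, -1), 1)
  if (use_abs) draws <- abs(draws)
  nets <- threshold_weight_draws(draws, nn, density)
  new_ensemble(nets, "fisher", as.integer(seed), density,
               source = list(r_matrix = r_matrix, df_matrix = df_matrix,
                             use_abs = use_abs))
}
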