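#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor quantile rnorm runif sd var approx optimize
#'   integrate acf dgamma qnorm ks.test median convolve
#' @importFrom utils read.table write.table
NULL

# Named random sub-streams: every stochastic stage derives its own seed from
# the single user-visible seed, so that e.g. adding reference graphs to a run
# does not shift the draws of the posterior sampler.
SUBSTREAMS <- c(
  dynamics = 11L, posterior_sampling = 23L, fisher_sampling = 37L,
  louvain = 47L, reference_graphs = 59L, noise = 71L, generic = 83L
)

substream_seed <- function(seed, stream = "generic") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  off <- SUBSTREAMS[[match.arg(stream, names(SUBSTREAMS))]]
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 2654435 + as.numeric(off) * 40503 +
                h) %% 2147483629)
}

# Evaluate `expr` under a seeded RNG without disturbing the caller's RNG state.
with_substream <- function(seed, stream, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(substream_seed(seed, stream))
  expr
}

# Trapezoidal rule on an arbitrary ordered grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

log_trapz <- function(x, logy) {
  m <- max(logy)
  if (!is.finite(m)) return(-Inf)
  m + log(trapz(x, exp(logy - m)))
}

stop_bayesconn <- function(class, msg) {
  stop(structure(
    class = c(class, "bayesconn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}
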