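#' Global efficiency
#'
#' Inverse of the harmonic mean of the geodesic (unweighted shortest-path)
#' distances, \eqn{E = \frac{1}{n(n-1)} \sum_{i \ne j} 1/d_{ij}};
#' disconnected pairs contribute 0. Ranges from 0 (empty graph) to 1
#' (complete graph).
#'
#' @param A a `binary_network` or 0/1 symmetric adjacency matrix.
#' @return Efficiency in \eqn{[0, 1]}.
#' @export
net_efficiency <- function(A) {
  A <- binary_network(A)
  n <- nrow(A)
  stopifnot(n >= 2)
  D <- igraph::distances(as_igraph(A))
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Entropy of the degree distribution
#'
#' Shannon entropy (base 2) of the empirical distribution of node degrees,
#' \eqn{H = -\sum_k p(k) \log_2 p(k)}. H = 0 for any regular graph (all
#' degrees equal); larger values indicate degree heterogeneity, with
#' \eqn{\log_2 m} attained when m distinct degrees occur equally often.
#'
#' @param A a `binary_network` or 0/1 symmetric adjacency matrix.
#' @return Entropy in bits (>= 0).
#' @export
degree_entropy <- function(A) {
  A <- binary_network(A)
  p <- tabulate(rowSums(A) + 1L) / nrow(A)
  p <- p[p > 0]
  -sum(p * log2(p)) + 0  # "+ 0" normalises IEEE negative zero
}

#' Global clustering coefficient (transitivity)
#'
#' Three times the number of triangles over the number of connected
#' triples; 0 when the graph has no connected triple.
#'
#' @param A a `binary_network` or 0/1 symmetric adjacency matrix.
#' @return Transitivity in \eqn{[0, 1]}.
#' @export
net_clustering <- function(A) {
  A <- binary_network(A)
  stopifnot(nrow(A) >= 3)
  ct <- igraph::transitivity(as_igraph(A), type = "global")
  if (is.nan(ct)) 0 else ct
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees at the two ends of each link (over
#' the 2M ordered endpoint pairs). Undefined on degree-regular link
#' endpoints (zero variance): then `NaN` is returned with attribute
#' `undefined = TRUE`.
#'
#' @param A a `binary_network` or 0/1 symmetric adjacency matrix.
#' @return Assortativity coefficient, or flagged `NaN`.
#' @export
net_assortativity <- function(A) {
  A <- binary_network(A)
  if (sum(A) < 4) stop("assortativity needs at least 2 links")
  r <- suppressWarnings(igraph::assortativity_degree(as_igraph(A)))
  if (is.nan(r)) structure(NaN, undefined = TRUE) else r
}

#' Louvain modularity
#'
#' Newman-Girvan modularity \eqn{Q = \sum_c (e_{cc} - a_c^2)} of the
#' partition found by the Louvain algorithm. The Louvain pass consumes
#' randomness; it is run under a dedicated seeded sub-stream so repeated
#' calls with the same seed return the same partition.
#'
#' @param A a `binary_network` or 0/1 symmetric adjacency matrix with at
#'   least one link.
#' @param seed integer seed for the Louvain sub-stream.
#' @param resolution Louvain resolution parameter (default 1).
#' @param restarts independent Louvain runs; the best-Q partition is kept.
#'   Louvain is order-dependent and can stall in local optima on small
#'   graphs; a handful of seeded restarts removes that in practice.
#' @return A list of class `modularity_result` with `Q` and `partition`
#'   (integer community labels).
#' @export
net_modularity <- function(A, seed = 1L, resolution = 1, restarts = 10L) {
  A <- binary_network(A)
  if (sum(A) == 0)
    stop_bayesconn("no_links", "modularity undefined on an empty graph")
  g <- as_igraph(A)
  cl <- with_substream(seed, "louvain", {
    best <- NULL
    for (i in seq_len(max(1L, restarts))) {
      cand <- igraph::cluster_louvain(g, resolution = resolution)
      if (is.null(best) ||
          igraph::modularity(cand) > igraph::modularity(best))
        best <- cand
    }
    best
  })
  structure(list(Q = igraph::modularity(g, igraph::membership(cl)),
                 partition = as.integer(igraph::membership(cl))),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("<modularity_result> Q = %.4f over %d communities\n", x$Q,
              length(unique(x$partition))))
  invisible(x)
}

#' Small-worldness index
#'
#' \eqn{S = (C/\langle C_{rand}\rangle) / (L/\langle L_{rand}\rangle)}
#' where C and L are the global clustering coefficient and mean geodesic
#' distance of the giant component, and the reference averages are taken
#' over `n_ref` Erdos-Renyi G(N, M) graphs with the network's node and link
#' counts (their own giant components). S around 1 for random graphs,
#' above 1 for small-world graphs (high clustering, short paths).
#'
#' @param A a `binary_network` or 0/1 symmetric adjacency matrix whose
#'   giant component covers at least 90\% of nodes.
#' @param n_ref number of reference graphs (>= 10); default 100.
#' @param seed integer seed for the reference-graph sub-stream.
#' @return S (flagged `NaN` if the reference clustering averages to 0).
#' @export
small_worldness <- function(A, n_ref = 100L, seed = 1L) {
  A <- binary_network(A)
  stopifnot(n_ref >= 10)
  n <- nrow(A)
  g <- as_igraph(A)
  comp <- igraph::components(g)
  cover <- max(comp$csize) / n
  if (cover < 0.9)
    stop_bayesconn("fragmentation", sprintf(
      "giant component covers only %.0f%% of nodes (>= 90%% required)",
      100 * cover))
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  C <- igraph::transitivity(giant, type = "global")
  if (is.nan(C)) C <- 0
  L <- igraph::mean_distance(giant)
  m <- igraph::ecount(g)
  ref <- with_substream(seed, "reference_graphs", {
    vapply(seq_len(n_ref), function(i) {
      rg <- igraph::sample_gnm(n, m)
      rcomp <- igraph::components(rg)
      rgiant <- igraph::induced_subgraph(
        rg, which(rcomp$membership == which.max(rcomp$csize)))
      cr <- igraph::transitivity(rgiant, type = "global")
      c(if (is.nan(cr)) 0 else cr, igraph::mean_distance(rgiant))
    }, numeric(2))
  })
  Cr <- mean(ref[1, ]); Lr <- mean(ref[2, ])
  if (Cr == 0 || !is.finite(Lr) || Lr == 0)
    return(structure(NaN, undefined = TRUE))
  (C / Cr) / (L / Lr)
}

# Bernoulli entropy in bits.
bernoulli_entropy <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Information content of an adjacency matrix
#'
#' Quantifies the absence of regular (mesoscale) patterns: pairs of nodes
#' with the most similar connection patterns are merged greedily, one pair
#' per step, and the bits needed to reconstruct the difference between the
#' two merged rows are accumulated. At each step the candidate pair is the
#' one with the highest Hamming agreement between adjacency rows (excluding
#' the two merged columns; ties broken by lowest indices); the loss charged
#' is \eqn{L \cdot H_b(p)}, with L the compared length, p the disagreement
#' fraction and \eqn{H_b} the Bernoulli entropy. The merged node adopts the
#' union of the two neighbourhoods. Regular graphs (identical rows) cost 0
#' bits; random graphs, having no repeated patterns, are maximal.
#'
#' @param A a `binary_network` or 0/1 symmetric adjacency matrix.
#' @return Total bits lost over the N-1 merges (>= 0).
#' @export
information_content <- function(A) {
  A <- binary_network(A)
  M <- unclass(A) != 0
  total <- 0
  while (nrow(M) > 1) {
    nc <- nrow(M)
    best <- c(NA, NA); best_agree <- -1; best_p <- 0
    for (i in seq_len(nc - 1)) {
      for (j in seq((i + 1), nc)) {
        keep <- setdiff(seq_len(nc), c(i, j))
        L <- length(keep)
        d <- if (L > 0) sum(M[i, keep] != M[j, keep]) else 0L
        agree <- L - d
        if (agree > best_agree) {
          best_agree <- agree
          best <- c(i, j)
          best_p <- if (L > 0) d / L else 0
        }
      }
    }
    i <- best[1]; j <- best[2]
    L <- nc - 2
    total <- total + L * bernoulli_entropy(best_p)
    merged <- M[i, ] | M[j, ]
    M[i, ] <- merged
    M[, i] <- merged
    M[i, i] <- FALSE
    M <- M[-j, -j, drop = FALSE]
  }
  total
}

#' Compute a set of topological metrics on one network
#'
#' Convenience wrapper returning the seven supported metrics (or a subset)
#' as a named numeric vector. Metrics that are undefined on the given graph
#' (e.g. assortativity on a regular graph) come back as `NaN`.
#'
#' @param A a `binary_network` or adjacency matrix.
#' @param metrics character vector naming the metrics to compute.
#' @param seed seed for the stochastic metrics (Louvain, reference graphs).
#' @param n_ref reference-graph count for [small_worldness()].
#' @return Named numeric vector.
#' @export
network_metrics <- function(A,
                            metrics = c("efficiency", "degree_entropy",
                                        "clustering", "assortativity",
                                        "modularity", "small_worldness",
                                        "information_content"),
                            seed = 1L, n_ref = 100L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  A <- binary_network(A)
  vapply(metrics, function(m) {
    switch(m,
           efficiency = net_efficiency(A),
           degree_entropy = degree_entropy(A),
           clustering = net_clustering(A),
           assortativity = as.numeric(net_assortativity(A)),
           modularity = net_modularity(A, seed = seed)$Q,
           small_worldness = as.numeric(
             tryCatch(small_worldness(A, n_ref = n_ref, seed = seed),
                      bayesconn_error = function(e) NaN)),
           information_content = information_content(A))
  }, numeric(1))
}
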