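# Brute-force reference implementations used as independent oracles.
# All are written from the definitions, without igraph, so they share no
# code path with the package.

# All-pairs shortest paths by repeated breadth-first search.
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ] != 0)
        new <- nb[dist[nb] > d]
        dist[new] <- d
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  diag(D) <- 0
  D
}

bf_efficiency <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  inv <- ifelse(is.finite(D) & D > 0, 1 / D, 0)
  sum(inv) / (n * (n - 1))
}

bf_clustering <- function(A) {
  n <- nrow(A)
  tri <- 0
  triples <- 0
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    triples <- triples + k * (k - 1) / 2
    if (k >= 2) {
      for (a in seq_len(k - 1)) for (b in (a + 1):k)
        if (A[nb[a], nb[b]] != 0) tri <- tri + 1
    }
  }
  # tri counts each triangle once per apex = 3 times in total
  if (triples == 0) return(0)
  tri / triples
}

bf_assortativity <- function(A) {
  n <- nrow(A)
  di <- rowSums(A)
  xs <- c(); ys <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && A[i, j] != 0) { xs <- c(xs, di[i]); ys <- c(ys, di[j]) }
  }
  if (length(xs) < 2 || sd(xs) == 0 || sd(ys) == 0) return(NaN)
  suppressWarnings(cor(xs, ys))
}

bf_degree_entropy <- function(A) {
  p <- as.numeric(table(rowSums(A))) / nrow(A)
  -sum(p * log2(p))
}

# Newman-Girvan modularity of a given partition, from the definition.
bf_modularity_q <- function(A, membership) {
  m2 <- sum(A)   # 2M
  if (m2 == 0) return(NA_real_)
  q <- 0
  for (c in unique(membership)) {
    in_c <- membership == c
    e_cc <- sum(A[in_c, in_c]) / m2
    a_c <- sum(A[in_c, ]) / m2
    q <- q + e_cc - a_c^2
  }
  q
}

# Exhaustive modularity optimum over all set partitions (feasible to ~8
# nodes; Bell(8) = 4140).
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  prev <- all_partitions(n - 1)
  out <- list()
  for (p in prev) {
    k <- max(p)
    for (c in seq_len(k + 1)) out[[length(out) + 1L]] <- c(p, c)
  }
  out
}

bf_modularity_opt <- function(A) {
  best <- -Inf
  for (p in all_partitions(nrow(A)))
    best <- max(best, bf_modularity_q(A, p))
  best
}

# Enumerate adjacency matrices: all labelled graphs on n nodes (n <= 5),
# or `k` random ones for larger n.
all_graphs <- function(n) {
  np <- n * (n - 1) / 2
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lapply(0:(2^np - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(np)]
    A <- matrix(0L, n, n)
    A[idx] <- bits
    A + t(A)
  })
}

random_graphs <- function(n, k, p = 0.4, seed = 1) {
  set.seed(seed)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lapply(seq_len(k), function(i) {
    A <- matrix(0L, n, n)
    A[idx] <- rbinom(nrow(idx), 1, p)
    A + t(A)
  })
}

# Independent quadrature of the correlation-posterior kernels using
# stats::integrate / optimize (adaptive, no shared grid with the package).
oracle_exact_logkernel <- function(rho, r, n) {
  sapply(rho, function(p) {
    I <- integrate(function(u) exp(-(n - 1) * log(2 * cosh(u) - 2 * p * r)),
                   -40, 40, rel.tol = 1e-10)$value
    ((n - 1) / 2) * log1p(-p^2) + log(I)
  })
}

oracle_approx_density <- function(rho, r, n) {
  logk <- function(p) ((n - 1) / 2) * log1p(-p^2) -
    (n - 1.5) * log1p(-p * r)
  shift <- max(logk(rho))
  z <- integrate(function(p) exp(logk(p) - shift), -1, 1,
                 rel.tol = 1e-9)$value
  exp(logk(rho) - shift) / z
}

# Posterior mass below a cut, by adaptive quadrature of the approximate
# kernel.
oracle_approx_mass_below <- function(cut, r, n) {
  logk <- function(p) ((n - 1) / 2) * log1p(-p^2) -
    (n - 1.5) * log1p(-p * r)
  shift <- logk(r)
  lo <- integrate(function(p) exp(logk(p) - shift), -1, cut,
                  rel.tol = 1e-12)$value
  tot <- lo + integrate(function(p) exp(logk(p) - shift), cut, 1,
                        rel.tol = 1e-12)$value
  lo / tot
}

trapz_test <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Total-variation distance between two densities tabulated on one grid.
tv_distance <- function(grid, d1, d2) {
  dd <- abs(d1 - d2)
  sum((dd[-1] + dd[-length(dd)]) * diff(grid) / 2) / 2
}

make_star_matrix <- function(n) {
  A <- matrix(0L, n, n)
  A[1, -1] <- 1L; A[-1, 1] <- 1L
  A
}
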