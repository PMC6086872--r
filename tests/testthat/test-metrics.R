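test_that("efficiency matches hand-derived values", {
  K5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(net_efficiency(K5), 1)
  expect_equal(net_efficiency(matrix(0, 4, 4)), 0)
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 1; P3 <- P3 + t(P3)
  expect_equal(net_efficiency(P3), 5 / 6)
})

test_that("degree entropy is zero on regular graphs and maximal when uniform", {
  ring <- diag(10)[, c(2:10, 1)]; ring <- ring + t(ring)
  expect_equal(degree_entropy(ring), 0)
  expect_equal(degree_entropy(matrix(1, 6, 6) - diag(6)), 0)
  expect_equal(degree_entropy(make_star_matrix(5)),
               -(0.8 * log2(0.8) + 0.2 * log2(0.2)))
  # two distinct degrees, equal counts -> log2(2) = 1 bit
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 3] <- A[3, 4] <- 1; A <- A + t(A)
  expect_equal(degree_entropy(A), 1)
  # permutation invariance
  set.seed(5)
  B <- random_graphs(7, 1, p = 0.5)[[1]]
  perm <- sample(7)
  expect_equal(degree_entropy(B), degree_entropy(B[perm, perm]))
})

test_that("clustering matches triangle/triple enumeration", {
  expect_equal(net_clustering(matrix(1, 5, 5) - diag(5)), 1)
  expect_equal(net_clustering(make_star_matrix(6)), 0)
  # 4-cycle plus one chord: 2 triangles, 8 connected triples
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- A[4, 1] <- A[1, 3] <- 1
  A <- A + t(A)
  expect_equal(net_clustering(A), 3 * 2 / 8)
})

test_that("assortativity is -1 on stars and flagged on regular graphs", {
  expect_equal(as.numeric(net_assortativity(make_star_matrix(6))), -1)
  r <- net_assortativity(matrix(1, 5, 5) - diag(5))
  expect_true(is.nan(r))
  expect_true(attr(r, "undefined"))
  # two disjoint cliques of different sizes: endpoints correlate positively
  A <- matrix(0, 7, 7)
  A[1:4, 1:4] <- 1; A[5:7, 5:7] <- 1; diag(A) <- 0
  expect_gt(as.numeric(net_assortativity(A)), 0)
})

test_that("metrics agree with brute-force oracles on enumerated small graphs", {
  graphs <- c(all_graphs(4), all_graphs(5),
              random_graphs(6, 120, p = 0.4, seed = 61),
              random_graphs(7, 120, p = 0.35, seed = 71))
  for (A in graphs) {
    expect_equal(net_efficiency(A), bf_efficiency(A), tolerance = 1e-12)
    expect_equal(net_clustering(A), bf_clustering(A), tolerance = 1e-12)
    expect_equal(degree_entropy(A), bf_degree_entropy(A),
                 tolerance = 1e-12)
    if (sum(A) >= 4) {
      got <- as.numeric(net_assortativity(A))
      want <- bf_assortativity(A)
      if (is.nan(want)) expect_true(is.nan(got))
      else expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("louvain modularity matches the definitional sum and near-optimum", {
  two4 <- matrix(0, 8, 8)
  two4[1:4, 1:4] <- 1; two4[5:8, 5:8] <- 1; diag(two4) <- 0
  res <- net_modularity(two4, seed = 1)
  expect_equal(res$Q, 0.5)
  expect_equal(res$Q, bf_modularity_q(two4, res$partition))
  expect_equal(bf_modularity_opt(two4), 0.5)

  expect_lte(net_modularity(matrix(1, 6, 6) - diag(6), seed = 1)$Q, 1e-12)
  expect_error(net_modularity(matrix(0, 4, 4)), class = "no_links")
  r1 <- net_modularity(two4, seed = 7)
  r2 <- net_modularity(two4, seed = 7)
  expect_identical(r1$partition, r2$partition)

  for (A in random_graphs(6, 15, p = 0.45, seed = 66)) {
    if (sum(A) == 0) next
    res <- net_modularity(A, seed = 3)
    expect_equal(res$Q, bf_modularity_q(A, res$partition),
                 tolerance = 1e-12)
    opt <- bf_modularity_opt(A)
    if (opt > 0) expect_gte(res$Q, 0.95 * opt)
  }
})

test_that("small-worldness is ~1 for random graphs and >1 for WS rings", {
  set.seed(101)
  er <- igraph::as_adjacency_matrix(igraph::sample_gnp(100, 0.1),
                                    sparse = FALSE)
  s_er <- small_worldness(er, n_ref = 50, seed = 5)
  expect_lt(abs(s_er - 1), 0.2)

  ws <- igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 100, 3, 0.1), sparse = FALSE)
  expect_gt(small_worldness(ws, n_ref = 50, seed = 5), 1)

  s10 <- small_worldness(ws, n_ref = 10, seed = 6)
  s100 <- small_worldness(ws, n_ref = 100, seed = 6)
  expect_lt(abs(s10 - s100) / s100, 0.25)

  frag <- matrix(0, 10, 10)
  frag[1:5, 1:5] <- 1; frag[6:10, 6:10] <- 1; diag(frag) <- 0
  expect_error(small_worldness(frag), class = "fragmentation")
})

test_that("information content is zero for regular patterns, high for random", {
  expect_equal(information_content(matrix(1, 8, 8) - diag(8)), 0)
  expect_equal(information_content(make_star_matrix(10)), 0)
  set.seed(31)
  ics <- vapply(random_graphs(10, 10, p = 0.2, seed = 31),
                information_content, numeric(1))
  expect_gt(mean(ics), information_content(make_star_matrix(10)))
  expect_true(all(ics >= 0))
})

test_that("efficiency and clustering rise monotonically toward the complete graph", {
  set.seed(77)
  n <- 8
  A <- make_star_matrix(n)  # connected seed graph
  effs <- net_efficiency(A)
  cls <- net_clustering(A)
  pairs <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    A[pairs[k, 1], pairs[k, 2]] <- A[pairs[k, 2], pairs[k, 1]] <- 1
    effs <- c(effs, net_efficiency(A))
    cls <- c(cls, net_clustering(A))
  }
  expect_true(all(diff(effs) >= -1e-12))
  expect_equal(effs[length(effs)], 1)
  expect_equal(cls[length(cls)], 1)
})

test_that("network_metrics returns the full named vector", {
  st <- make_star_matrix(10)
  v <- network_metrics(st, seed = 2, n_ref = 10)
  expect_named(v, c("efficiency", "degree_entropy", "clustering",
                    "assortativity", "modularity", "small_worldness",
                    "information_content"))
  expect_equal(unname(v["clustering"]), 0)
  expect_equal(unname(v["assortativity"]), -1)
})
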