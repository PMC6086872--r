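test_that("density thresholding keeps the strongest pairs deterministically", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, 0.2, 0.8, 0.5, 0.1, 0.7)  # (1,2)(1,3)(2,3)(1,4)(2,4)(3,4)
  W <- W + t(W)
  full <- threshold_to_density(W, 1)
  expect_equal(sum(full) / 2, 6)
  top3 <- threshold_to_density(W, 0.5)
  expect_equal(sum(top3) / 2, 3)
  # top 3 weights by hand: 0.9 (1,2), 0.8 (2,3), 0.7 (3,4)
  expect_equal(top3[1, 2], 1L)
  expect_equal(top3[2, 3], 1L)
  expect_equal(top3[3, 4], 1L)
  expect_equal(top3[1, 4], 0L)
  # idempotence up to tie-breaking: thresholding a binary network again
  again <- threshold_to_density(unclass(top3) * 1.0, attr(top3, "density"))
  expect_equal(unclass(again), unclass(top3))
  expect_error(threshold_to_density(W, 0), class = "invalid_density")
  achieved <- attr(threshold_to_density(W, 0.4), "density")
  expect_lte(abs(achieved - 0.4), 1 / 6 + 1e-12)
})

test_that("frequentist reconstruction recovers the star and is deterministic", {
  st <- star_adjacency(10)
  ts <- coupled_dynamics(st, 0.5, 1e4, seed = 3)
  net <- frequentist_network(ts, 9 / 45)
  expect_lt(relative_error(st, net), 0.05)
  expect_identical(unclass(frequentist_network(ts, 9 / 45)), unclass(net))
  two <- ts_set(matrix(rnorm(2 * 50), 2), fs = 1)
  expect_equal(sum(frequentist_network(two, 1)) / 2, 1)
})

test_that("bayesian ensembles are reproducible and respect the density", {
  st <- star_adjacency(8)
  ts <- coupled_dynamics(st, 0.5, 64, seed = 5)
  ens <- bayesian_ensemble(ts, 0.25, count = 150, seed = 9)
  expect_equal(ens$count, 150)
  dens <- vapply(ens$networks, function(m) attr(m, "density"), numeric(1))
  expect_true(all(abs(dens - attr(ens$networks[[1]], "density")) < 1e-12))
  npairs <- 8 * 7 / 2
  expect_true(all(abs(dens - 0.25) <= 1 / npairs + 1e-12))
  # short series: link uncertainty generates distinct topologies
  keys <- vapply(ens$networks, function(m) paste(m, collapse = ""),
                 character(1))
  expect_gt(length(unique(keys)), 1)
  ens2 <- bayesian_ensemble(ts, 0.25, count = 150, seed = 9)
  expect_identical(lapply(ens$networks, unclass),
                   lapply(ens2$networks, unclass))
})

test_that("a degenerate all-identical input collapses the bayesian ensemble", {
  base <- sin(seq_len(40)) + rnorm(40)
  ts <- ts_set(rbind(base, base, base), fs = 1)
  ens <- bayesian_ensemble(ts, 1, count = 50, seed = 2)
  keys <- vapply(ens$networks, function(m) paste(m, collapse = ""),
                 character(1))
  expect_equal(length(unique(keys)), 1)
  expect_equal(sum(ens$networks[[1]]) / 2, 3)  # complete graph on 3 nodes
})

test_that("ensemble agreement with the frequentist network grows with series length", {
  st <- star_adjacency(10)
  frac_equal <- vapply(c(64, 512, 4096), function(tl) {
    ts <- coupled_dynamics(st, 0.5, tl, seed = 13)
    freq <- frequentist_network(ts, 0.2)
    ens <- bayesian_ensemble(ts, 0.2, count = 100, seed = 13)
    mean(vapply(ens$networks,
                function(m) identical(unclass(m), unclass(freq)),
                logical(1)))
  }, numeric(1))
  expect_true(all(diff(frac_equal) >= 0))
  expect_gt(frac_equal[3], frac_equal[1])
})

test_that("fisher ensembles degenerate to the frequentist network at huge df", {
  st <- star_adjacency(10)
  ts <- coupled_dynamics(st, 0.5, 256, seed = 7)
  R <- correlation_matrix(ts)
  freq <- threshold_to_density(R, 0.2)
  ens <- fisher_ensemble(R, 1e6, 0.2, count = 50, seed = 3)
  expect_true(all(vapply(ens$networks,
                         function(m) identical(unclass(m), unclass(freq)),
                         logical(1))))
  expect_error(fisher_ensemble(R, 3, 0.2, count = 5, seed = 1),
               class = "insufficient_df")
  e1 <- fisher_ensemble(R, effective_df_matrix(ts), 0.2, count = 40,
                        seed = 4)
  e2 <- fisher_ensemble(R, effective_df_matrix(ts), 0.2, count = 40,
                        seed = 4)
  expect_identical(lapply(e1$networks, unclass),
                   lapply(e2$networks, unclass))
})

test_that("fisher and bayesian ensembles give overlapping metric spreads", {
  st <- star_adjacency(10)
  ts <- coupled_dynamics(st, 0.5, 256, seed = 17)
  bay <- bayesian_ensemble(ts, 0.2, count = 200, seed = 17)
  fis <- fisher_ensemble(correlation_matrix(ts), effective_df_matrix(ts),
                         0.2, count = 200, seed = 17)
  hb <- ensemble_metric(bay, "degree_entropy")$samples
  hf <- ensemble_metric(fis, "degree_entropy")$samples
  qb <- quantile(hb, c(0.25, 0.75))
  qf <- quantile(hf, c(0.25, 0.75))
  expect_true(qb[1] <= qf[2] && qf[1] <= qb[2])
})
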