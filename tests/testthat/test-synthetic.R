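test_that("ground-truth structures have the advertised shape", {
  st <- star_adjacency(10)
  deg <- sort(rowSums(st), decreasing = TRUE)
  expect_equal(deg, c(9, rep(1, 9)))
  expect_equal(sum(st) / 2, 9)
  expect_identical(unclass(st), t(unclass(st)))
  expect_equal(sum(diag(st)), 0L)
  expect_equal(sum(star_adjacency(3)) / 2, 2)
  expect_error(star_adjacency(2), class = "too_small")

  mod <- modular_adjacency(10)
  expect_equal(unname(rowSums(mod)), rep(4, 10))
  expect_equal(sum(unclass(mod)[1:5, 6:10]), 0)
  expect_error(modular_adjacency(7), class = "too_small")
})

test_that("uncoupled dynamics are white noise; coupling creates structure", {
  st <- star_adjacency(10)
  ts0 <- coupled_dynamics(st, 0, 1e4, seed = 8)
  W <- correlation_matrix(ts0)
  expect_lt(mean(W[upper.tri(W)]), 0.05)
  # fixed seed -> bit-identical series
  expect_identical(coupled_dynamics(st, 0.3, 100, seed = 5)$values,
                   coupled_dynamics(st, 0.3, 100, seed = 5)$values)
  expect_error(coupled_dynamics(binary_network(matrix(0, 3, 3) +
                                                 rbind(c(0, 1, 0),
                                                       c(1, 0, 0),
                                                       c(0, 0, 0))),
                                0.5, 100),
               class = "zero_normaliser")
})

test_that("over-coupling produces spurious all-to-all connectivity", {
  st <- star_adjacency(10)
  es <- vapply(1:8, function(seed) {
    ts <- coupled_dynamics(st, 0.95, 4096, seed = seed)
    relative_error(st, frequentist_network(ts, 0.2))
  }, numeric(1))
  expect_gt(mean(es > 0), 0.9)
})

test_that("coupled dynamics are variance-stationary after burn-in", {
  st <- star_adjacency(10)
  ts <- coupled_dynamics(st, 0.5, 4096, seed = 12)
  h1 <- apply(ts$values[, 1:2048], 1, var)
  h2 <- apply(ts$values[, 2049:4096], 1, var)
  expect_lt(max(abs(h1 - h2) / h1), 0.2)
})

test_that("relative error counts ordered disagreements", {
  st <- star_adjacency(10)
  expect_equal(relative_error(st, st), 0)
  comp <- binary_network(1 - unclass(st) - diag(10))
  expect_equal(relative_error(st, comp), 1)
  # one hub link dropped, one peripheral link added: 4 ordered mismatches
  A <- unclass(st)
  A[1, 2] <- A[2, 1] <- 0L
  A[3, 4] <- A[4, 3] <- 1L
  expect_equal(relative_error(st, binary_network(A)), 4 / 90)
  # symmetry and relabelling invariance
  expect_equal(relative_error(binary_network(A), st), 4 / 90)
  perm <- c(3, 1, 4, 2, 5, 9, 10, 6, 8, 7)
  expect_equal(relative_error(binary_network(unclass(st)[perm, perm]),
                              binary_network(A[perm, perm])), 4 / 90)
  expect_error(relative_error(st, star_adjacency(5)), class = "dimension")
})

test_that("the HRF kernel has a main lobe at the peak delay and an undershoot", {
  h <- hrf_kernel()
  fs <- attr(h, "fs")
  expect_equal(max(h), 1)
  peak_t <- (which.max(h) - 1) / fs
  expect_equal(peak_t, 6, tolerance = 1 / fs + 1e-9)
  expect_lt(min(h), 0)                         # undershoot exists
  expect_gt(which.min(h), which.max(h))        # ... and comes later
})

test_that("HRF convolution is linear and reproduces the kernel for impulses", {
  h <- hrf_kernel()
  zero <- matrix(0, 2, 500)
  expect_equal(hrf_convolve(zero, h), zero)
  imp <- matrix(0, 2, 500); imp[1, 10] <- 1
  out <- hrf_convolve(imp, as.numeric(h))
  peak_idx <- which.max(out[1, ])
  expect_equal(peak_idx, 10 + which.max(h) - 1, tolerance = 1)
  expect_equal(max(out[1, ]), 1, tolerance = 1e-6)
  expect_equal(out[2, ], rep(0, 500), tolerance = 1e-12)
})

test_that("fMRI emulation preserves the coupling structure", {
  st <- star_adjacency(10)
  ts <- fmri_emulate(st, 0.5, 2e4, seed = 3)
  expect_equal(ncol(ts$values), 1000)
  e_coupled <- relative_error(st, frequentist_network(ts, 0.2))
  ts0 <- fmri_emulate(st, 0, 2e4, seed = 3)
  e_null <- relative_error(st, frequentist_network(ts0, 0.2))
  expect_lt(e_coupled, e_null)
})

test_that("length sweeps show convergence and the Bayesian lag", {
  st <- star_adjacency(10)
  fr <- length_sweep(st, 0.5, c(64, 512, 4096), method = "frequentist",
                     reps = 6, seed = 2)
  expect_true(all(diff(fr$e_mean) <= 0.02))
  expect_lt(fr$e_mean[3], fr$e_mean[1] + 1e-12)

  ba <- length_sweep(st, 0.5, 256, method = "bayesian", reps = 4,
                     seed = 2, count = 80)
  fr256 <- length_sweep(st, 0.5, 256, method = "frequentist", reps = 4,
                        seed = 2)
  expect_gte(ba$e_mean, fr256$e_mean)

  base <- length_sweep(st, 0, c(64, 1024), method = "frequentist",
                       reps = 4, seed = 3)
  # gamma = 0: nothing to find; error stays at the density-mismatch floor
  expect_true(all(base$e_mean > 0.2))
})
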