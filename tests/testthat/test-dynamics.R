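test_that("normalized Hill factors have the stated closed-form values", {
  # basal normalization: u = 1 maps to 1 for any K, n, sign
  for (K in c(0.1, 1, 7)) {
    for (n in 1:4) {
      expect_equal(hill_term(1, K, n, 1), 1)
      expect_equal(hill_term(1, K, n, -1), 1)
    }
  }
  # activation saturates at K^n + 1
  expect_equal(hill_term(1e9, 1, 1, 1), 2, tolerance = 1e-6)
  # repression closed form
  expect_equal(hill_term(3, 1, 1, -1), 0.5)
  expect_error(hill_term(-1, 1, 1, 1), "nonnegative")
  expect_error(hill_term(1, -2, 1, 1), "positive")
  expect_error(hill_term(1, 1, 0.5, 1), "n must be")
})

test_that("flat input leaves every motif exactly at basal", {
  grid <- tiny_grid()
  flat <- matrix(1, length(grid), 2)
  for (seed in 1:10) {
    combo <- random_combo(seed)
    s <- simulate_motif(combo$motif, combo$params, flat, grid)
    expect_lt(max(abs(s$Z - 1)), 1e-6)
    expect_lt(max(abs(s$Y - 1)), 1e-6)
  }
})

test_that("an unconnected downstream node stays flat and states stay nonnegative", {
  grid <- tiny_grid()
  x <- pulse_trace()
  p <- default_truth_params()
  # no incoming links to Z at all (only the hidden node is driven): the raw
  # structure is non-canonical, but the dynamics must still hold Z at 1
  m <- signed_motif(c(XY = 1, XZ = 0, YY = 0, YZ = 0, ZY = 0, ZZ = 0))
  s <- simulate_motif(m, p, x, grid)
  expect_equal(as.numeric(s$Z), rep(1, length(grid)), tolerance = 1e-12)
  # nonnegativity for a batch of random motifs on a positive pulse
  for (seed in 11:20) {
    combo <- random_combo(seed)
    s <- simulate_motif(combo$motif, combo$params, x, grid)
    if (all(s$ok)) {
      expect_true(all(s$Y >= 0) && all(s$Z >= 0))
      expect_equal(s$Y[1, 1], 1)
      expect_equal(s$Z[1, 1], 1)
    }
  }
})

test_that("the IFFL adapts: transient rise, damping, post-pulse undershoot", {
  grid <- tiny_grid()
  x <- pulse_trace()
  s <- simulate_motif(motif_library("IFFL"), default_truth_params(), x, grid)
  z <- as.numeric(s$Z)
  off_idx <- which(grid >= 6)[1]
  expect_gt(max(z[seq_len(off_idx)]), 1.5)       # transient rise
  expect_lt(z[off_idx], max(z[seq_len(off_idx)]))  # damped before pulse end
  expect_lt(min(z[off_idx:length(z)]), 0.95)     # undershoots below basal
  expect_equal(z[length(z)], 1, tolerance = 0.1) # returns toward basal
})

test_that("a positive cascade delays the half-maximal response relative to direct activation", {
  grid <- tiny_grid()
  x <- pulse_trace()
  p <- default_truth_params()
  direct <- signed_motif(c(XY = 0, XZ = 1, YY = 0, YZ = 0, ZY = 0, ZZ = 0))
  z_cas <- as.numeric(simulate_motif(motif_library("cascade"), p, x, grid)$Z)
  z_dir <- as.numeric(simulate_motif(direct, p, x, grid)$Z)
  half_time <- function(z) {
    half <- 1 + (max(z) - 1) / 2
    grid[which(z >= half)[1]]
  }
  expect_gt(half_time(z_cas), half_time(z_dir))
})

test_that("fixed-step RK4 agrees with an adaptive reference integrator within 1%", {
  skip_if_not_installed("deSolve")
  grid <- tiny_grid()
  x <- pulse_trace()
  for (seed in 21:30) {
    combo <- random_combo(seed)
    s <- simulate_motif(combo$motif, combo$params, x, grid, refine = 4)
    if (!all(s$ok)) next
    ref <- lsoda_reference(combo$motif, combo$params, x, grid)
    rel <- max(abs(s$Z - ref$Z) / pmax(abs(ref$Z), 1))
    expect_lt(rel, 0.01)
  }
})

test_that("simulation validates its inputs", {
  grid <- tiny_grid()
  p <- default_truth_params()
  m <- motif_library("IFFL")
  expect_error(simulate_motif(m, p, pulse_trace()[-1], grid), "time grid")
  expect_error(simulate_motif(m, p, -pulse_trace(), grid), "positive")
  expect_error(simulate_motif(m, p, pulse_trace(), rev(grid)), "increasing")
})
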