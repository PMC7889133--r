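test_that("parameter sampling respects count, bounds and the seed contract", {
  cfg <- run_config(n_params = 500)
  ps <- sample_parameters(500, cfg, seed = 1)
  expect_identical(nrow(ps$K), 500L)
  expect_true(all(ps$K >= 0.1 & ps$K <= 10))
  expect_true(all(ps$n %in% 1:4))
  expect_true(all(ps$alpha_Y >= 0.05 & ps$alpha_Y <= 2))
  expect_true(all(ps$alpha_Z >= 0.05 & ps$alpha_Z <= 2))
  expect_identical(sample_parameters(500, cfg, seed = 1), ps)
  expect_false(identical(sample_parameters(500, cfg, seed = 2)$K, ps$K))
  expect_error(sample_parameters(0, cfg), "count")
  expect_error(run_config(K_bounds = c(10, 0.1)), "bounds")
  # extraction round-trip
  p7 <- param_set(ps, 7)
  expect_s3_class(p7, "parameter_set")
  expect_identical(unname(p7$K), unname(ps$K[7, ]))
})

test_that("the error score matches its closed-form examples", {
  tt <- 0:10
  z <- matrix(3, 11, 1)
  expect_equal(error_score(z, z, tt), 0)
  expect_equal(error_score(z, matrix(1, 11, 1), tt), 2)
  # two cells with per-cell scores 1 and 3 average to 2
  obs <- cbind(rep(2, 11), rep(4, 11))
  expect_equal(error_score(obs, matrix(1, 11, 2), tt), 2)
  expect_error(error_score(z, matrix(1, 10, 1), tt), "mismatch")
})

test_that("the error score is a pseudometric on trace matrices", {
  tt <- seq(0, 5, 0.5)
  set.seed(99)
  for (rep in 1:10) {
    a <- matrix(exp(rnorm(33)), 11, 3)
    b <- matrix(exp(rnorm(33)), 11, 3)
    c <- matrix(exp(rnorm(33)), 11, 3)
    expect_equal(error_score(a, b, tt), error_score(b, a, tt))
    expect_equal(error_score(a, a, tt), 0)
    expect_lte(error_score(a, c, tt),
               error_score(a, b, tt) + error_score(b, c, tt) + 1e-12)
  }
})

test_that("baseline error equals the flat predictor and any unconnected simulation", {
  tt <- 0:10
  expect_equal(baseline_error(matrix(1, 11, 2), tt), 0)
  expect_equal(baseline_error(matrix(3, 11, 1), tt), 2)
  # simulation oracle: an unconnected graph's output scores exactly E0
  ts <- generate_dataset("IFFL", n_cells = 4, seed = 21)
  unconnected <- signed_motif(c(XY = 1, XZ = 0, YY = 0, YZ = 0, ZY = 0, ZZ = 0))
  sim <- simulate_motif(unconnected, default_truth_params(), ts$X, ts$time)
  expect_equal(error_score(ts$Z, sim$Z, ts$time),
               baseline_error(ts$Z, ts$time))
})

test_that("score_all is deterministic, pairs cells correctly, and caps at E0", {
  ts <- generate_dataset("IFFL", n_cells = 4, seed = 22, refine = 2)
  cfg <- run_config(n_params = 40, refine = 2)
  ps <- sample_parameters(40, cfg, seed = 23)
  motifs <- structure(list(
    motif_library("IFFL"), motif_library("cascade"),
    signed_motif(c(0, 1, 0, 0, 0, 1)), signed_motif(c(0, -1, 0, 0, 0, 0))
  ), class = "motif_set")
  b1 <- score_all(ts, motifs, ps, cfg)
  b2 <- score_all(ts, motifs, ps, cfg)
  expect_identical(b1$combos, b2$combos)
  expect_true(all(b1$combos$error <= b1$E0 + 1e-12))
  expect_identical(nrow(b1$combos), 160L)
  # permuting the motif order permutes, but preserves, the error multiset
  b3 <- score_all(ts, structure(motifs[c(3, 1, 4, 2)], class = "motif_set"),
                  ps, cfg)
  expect_equal(sort(b3$combos$error), sort(b1$combos$error))
})

test_that("the generating combo scores ~zero and lands in the top set", {
  ts <- generate_dataset("IFFL", n_cells = 5, seed = 30, refine = 2)
  cfg <- run_config(n_params = 150, refine = 2)
  ps <- sample_parameters(150, cfg, seed = 31)
  ps <- motiftrace:::append_param(ps, default_truth_params())
  motifs <- enumerate_motifs()
  b <- rank_board(score_all(ts, motifs, ps, cfg))
  iffl_idx <- which(apply(b$motif_signs, 1, paste, collapse = ",") ==
                      "1,1,0,-1,0,0")
  truth_row <- which(b$combos$motif == iffl_idx & b$combos$param == 151L)
  expect_lt(b$combos$error[truth_row], 1e-6)
  expect_true(truth_row %in% b$top)
})

test_that("elbow detection matches a brute-force slope scan and handles degenerate input", {
  # linear rise to rank k, then exactly flat
  k <- 200
  e <- c(seq(0, 1, length.out = k), rep(1, 300))
  w <- 5
  elbow <- find_elbow(e, slope_fraction = 0.10, window = w)
  # brute-force oracle: recompute windowed slopes directly
  s <- (e[(1 + w):length(e)] - e[1:(length(e) - w)]) / w
  imax <- which.max(s)
  expected <- imax + which(s[(imax + 1):length(s)] < 0.10 * s[imax])[1]
  expect_identical(elbow, expected)
  expect_true(abs(elbow - k) <= w + 1)
  # all-equal errors: no informative elbow
  expect_warning(r <- find_elbow(rep(2, 50)), "no informative elbow")
  expect_identical(r, 1L)
  # slope_fraction = 1 cuts immediately after the max-slope rank
  e2 <- c(0, 0.1, 0.5, 0.6, 0.65, 0.66, 0.66, 0.66)
  expect_identical(find_elbow(e2, slope_fraction = 1, window = 1), 3L)
  expect_error(find_elbow(c(1, 2)), "at least 3")
  expect_error(find_elbow(c(2, 1, 3)), "sorted")
})
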