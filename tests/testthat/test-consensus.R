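test_that("link-wise consensus takes modal signs with modal-fraction confidence", {
  iffl <- as.vector(unclass(motif_library("IFFL")))
  # singleton top set: consensus is that motif with full confidence
  cm <- consensus_motif(matrix(iffl, 1))
  expect_identical(unname(cm$signs), iffl)
  expect_identical(unname(cm$confidence), rep(1, 6))
  # {+, +, -} on the first link -> consensus + with confidence 2/3
  signs <- rbind(iffl, iffl, c(-1L, iffl[-1]))
  cm2 <- consensus_motif(signs)
  expect_identical(unname(cm2$signs[1]), 1L)
  expect_equal(unname(cm2$confidence[1]), 2 / 3)
  # tie between two categories breaks toward absent and is reported
  tied <- rbind(c(1L, 1L, 0L, -1L, 0L, 0L), c(0L, 1L, 0L, -1L, 0L, 0L))
  cm3 <- consensus_motif(tied)
  expect_identical(unname(cm3$signs[1]), 0L)
  expect_true("XY" %in% cm3$ties)
  expect_error(consensus_motif(matrix(integer(0), 0, 6)), "empty top set")
  # confidences never fall below 1/3 and are invariant to duplication
  expect_true(all(cm2$confidence >= 1 / 3))
  cm_dup <- consensus_motif(rbind(signs, signs, signs))
  expect_identical(cm_dup$signs, cm2$signs)
  expect_equal(cm_dup$confidence, cm2$confidence)
})

test_that("the confidence-weighted distance matches its closed forms and complements similarity", {
  iffl <- motif_library("IFFL")
  perfect <- consensus_motif(matrix(unclass(iffl), 1))
  expect_equal(motif_distance(perfect, iffl), 0)
  # all six links wrong with confidence 1
  wrong <- list(signs = -unclass(iffl) + (unclass(iffl) == 0L),
                confidence = rep(1, 6), ties = character(0), n_top = 1L)
  class(wrong) <- "consensus_motif"
  expect_equal(motif_distance(wrong, iffl), 6)
  # 5 matches at 0.8, one mismatch at 0.6
  partial <- list(signs = c(unclass(iffl)[1:5], 1L),
                  confidence = c(rep(0.8, 5), 0.6),
                  ties = character(0), n_top = 1L)
  names(partial$signs) <- names(partial$confidence) <- names(unclass(iffl))
  class(partial) <- "consensus_motif"
  expect_equal(motif_distance(partial, iffl), 5 * 0.2 + 0.6)
  # distance + matched-confidence similarity = 6 identically
  set.seed(13)
  for (rep in 1:20) {
    cm <- list(signs = sample(c(-1L, 0L, 1L), 6, replace = TRUE),
               confidence = runif(6, 1 / 3, 1), ties = character(0), n_top = 1L)
    names(cm$signs) <- names(cm$confidence) <- motiftrace:::MOTIF_LINKS
    class(cm) <- "consensus_motif"
    match <- cm$signs == unclass(iffl)
    similarity <- sum(ifelse(match, cm$confidence, 1 - cm$confidence))
    expect_equal(motif_distance(cm, iffl) + similarity, 6)
  }
})

test_that("Monte-Carlo significance behaves like its null model", {
  iffl <- motif_library("IFFL")
  # perfect consensus: no random graph ties or beats D = 0
  s0 <- significance(0, iffl, n_random = 10000, seed = 1)
  expect_equal(s0$p_value, 1 / 10001)
  # worst case is effectively always beaten
  s6 <- significance(6, iffl, n_random = 1000, seed = 1)
  expect_gt(s6$p_value, 0.999)
  # monotone nondecreasing in D over a shared random-graph sample
  base <- significance(0, iffl, n_random = 2000, seed = 5)
  ps <- vapply(seq(0, 6, by = 0.5), function(D) {
    (1 + sum(base$D_rand <= D)) / (1 + base$n_random)
  }, numeric(1))
  expect_true(all(diff(ps) >= 0))
  expect_identical(significance(1, iffl, n_random = 500, seed = 9)$D_rand,
                   significance(2, iffl, n_random = 500, seed = 9)$D_rand)
  expect_error(significance(1, iffl, n_random = 50), "at least 100")
})

test_that("shuffling pairs yields a derangement and preserves the traces", {
  ts <- generate_dataset("IFFL", n_cells = 12, seed = 40)
  sh <- shuffle_pairs(ts, seed = 41)
  expect_true(all(sh$pairing != seq_len(12)))
  expect_identical(sort(sh$pairing), 1:12)
  # multisets of traces and population means are untouched
  expect_identical(sh$X, ts$X)
  expect_identical(sh$Z, ts$Z)
  expect_identical(rowMeans(motiftrace:::paired_Z(sh)),
                   rowMeans(motiftrace:::paired_Z(ts)))
  # two cells admit exactly one derangement: the swap
  two <- ts[1:2]
  expect_identical(shuffle_pairs(two, seed = 1)$pairing, c(2L, 1L))
  expect_error(shuffle_pairs(ts[1], seed = 1), "at least 2")
})

test_that("zero-variance fixed-time correlation is flagged rather than computed", {
  ts <- generate_dataset("IFFL", n_cells = 4, amplitude_cv = 0, delay_sd = 0,
                         seed = 2)
  expect_warning(r <- fixed_time_correlation(ts, 2.5, seed = 3),
                 "zero cross-cell variance")
  expect_true(is.na(r$paired))
})

test_that("a linearly dependent downstream trace gives perfect paired correlation", {
  ts <- generate_dataset("IFFL", n_cells = 10, seed = 44)
  ts$Z <- 2 * ts$X
  r <- fixed_time_correlation(ts, 2.5, seed = 45)
  expect_equal(r$paired, 1)
})
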