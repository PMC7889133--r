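test_that("raw sign space and canonical enumeration have the expected sizes", {
  # 3 signs on each of 6 links
  expect_identical(3^6, 729)
  all_motifs <- enumerate_motifs()
  expect_length(all_motifs, 402)
  expect_length(enumerate_motifs("XZ"), 2)
  expect_error(enumerate_motifs(character(0)), "nothing to enumerate")
  expect_error(enumerate_motifs("XX"), "unknown links")
})

test_that("enumeration is deterministic, order-stable and duplicate-free", {
  a <- motif_matrix(enumerate_motifs())
  b <- motif_matrix(enumerate_motifs())
  expect_identical(a, b)
  expect_identical(anyDuplicated(a), 0L)
  # lexicographic order over sign vectors, -1 < 0 < +1
  expect_identical(a, a[do.call(order, asplit(a, 2)), ])
})

test_that("canonicalize applies Y-collapse, rejects trivial structures, and is idempotent", {
  # empty motif is trivial
  expect_null(canonicalize(rep(0L, 6)))
  # IFFL is already canonical
  iffl <- motif_library("IFFL")
  expect_identical(unclass(canonicalize(iffl)), unclass(iffl))
  # Y->Z absent: Y-touching links collapse, X->Z skeleton survives
  m <- canonicalize(c(XY = 1, XZ = 1, YY = 0, YZ = 0, ZY = 1, ZZ = 0))
  expect_identical(unname(unclass(m)), c(0L, 1L, 0L, 0L, 0L, 0L))
  # Y with no input collapses even though Y->Z is present
  m2 <- canonicalize(c(XY = 0, XZ = -1, YY = 1, YZ = 1, ZY = 0, ZZ = 0))
  expect_identical(unname(unclass(m2)), c(0L, -1L, 0L, 0L, 0L, 0L))
  # pure-Y structure is trivial after collapse
  expect_null(canonicalize(c(XY = 1, XZ = 0, YY = 1, YZ = 0, ZY = 0, ZZ = 0)))
  # idempotence over the full raw space
  grids <- rep(list(c(-1L, 0L, 1L)), 6)
  raw <- unname(as.matrix(expand.grid(grids)))
  for (i in seq_len(nrow(raw))) {
    c1 <- canonicalize(raw[i, ])
    if (is.null(c1)) next
    c2 <- canonicalize(c1)
    expect_identical(unclass(c2), unclass(c1))
  }
  expect_error(signed_motif(c(2, 0, 0, 0, 0, 0)), "signs must be")
})

test_that("collapsed raw assignments are output-equivalent to their canonical form", {
  # simulation oracle: raw vs canonical give identical Z under shared
  # parameters and identical upstream input
  grid <- tiny_grid()
  x <- pulse_trace()
  set.seed(7)
  n_checked <- 0
  while (n_checked < 20) {
    raw <- sample(c(-1L, 0L, 1L), 6, replace = TRUE)
    canon <- canonicalize(raw)
    if (is.null(canon)) next
    p <- parameter_set(K = exp(runif(6, log(0.1), log(10))),
                       n = sample(1:4, 6, replace = TRUE),
                       alpha_Y = runif(1, 0.1, 1), alpha_Z = runif(1, 0.1, 1))
    z_raw <- simulate_motif(signed_motif(raw), p, x, grid)$Z
    z_can <- simulate_motif(canon, p, x, grid)$Z
    expect_equal(z_raw, z_can, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("heat-column conversion is a round-trip bijection on all canonical motifs", {
  expect_identical(
    unname(motif_to_heatcolumn(motif_library("IFFL"))),
    c(1L, 1L, 0L, -1L, 0L, 0L)
  )
  # all-positive cascade X -> Y -> Z
  expect_identical(
    unname(motif_to_heatcolumn(motif_library("cascade"))),
    c(1L, 0L, 0L, 1L, 0L, 0L)
  )
  for (m in enumerate_motifs()) {
    expect_identical(unclass(heatcolumn_to_motif(motif_to_heatcolumn(m))),
                     unclass(m))
  }
  expect_error(heatcolumn_to_motif(c(1, 0, 0)), "6 entries")
})

test_that("motif serialization round-trips through the line format", {
  path <- withr::local_tempfile(fileext = ".txt")
  motifs <- structure(list(motif_library("IFFL"), motif_library("cascade")),
                      class = "motif_set")
  write_motifs(motifs, path)
  back <- read_motifs(path)
  expect_identical(motif_matrix(back), motif_matrix(motifs))
  expect_identical(attr(back[[1]], "label"), "IFFL")
})
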