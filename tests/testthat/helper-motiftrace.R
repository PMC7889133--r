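# Shared fixture builders; everything is generated in code at test time.

# Small default grid for fast simulations.
tiny_grid <- function() seq(0, 15, by = 0.1)

# A deterministic square pulse on the tiny grid.
pulse_trace <- function(amplitude = 5, on = 2, off = 6, grid = tiny_grid()) {
  ifelse(grid >= on & grid < off, amplitude, 1)
}

# Random canonical motif + in-bounds parameter set under a local seed.
random_combo <- function(seed) {
  motifs <- enumerate_motifs()
  set.seed(seed)
  m <- motifs[[sample.int(length(motifs), 1)]]
  p <- parameter_set(K = exp(runif(6, log(0.1), log(10))),
                     n = sample(1:4, 6, replace = TRUE),
                     alpha_Y = exp(runif(1, log(0.05), log(2))),
                     alpha_Z = exp(runif(1, log(0.05), log(2))))
  list(motif = m, params = p)
}

# Independent reference integration of the motif dynamics with an adaptive
# high-accuracy solver (deSolve::lsoda), written directly from the model
# definition: dY = aY (prod hill - Y), dZ = aZ (prod hill - Z), X interpolated.
# Used only as an oracle against the package's fixed-step RK4 path.
lsoda_reference <- function(motif, params, x, grid) {
  xf <- stats::approxfun(grid, x, rule = 2)
  s <- unclass(motif)
  h <- function(u, l) {
    if (s[[l]] == 0) return(1)
    hill_term(u, params$K[[l]], params$n[[l]], s[[l]])
  }
  rhs <- function(t, state, parms) {
    xx <- xf(t)
    FY <- h(xx, "XY") * h(state[1], "YY") * h(state[2], "ZY")
    FZ <- h(xx, "XZ") * h(state[1], "YZ") * h(state[2], "ZZ")
    list(c(params$alpha_Y * (FY - state[1]),
           params$alpha_Z * (FZ - state[2])))
  }
  out <- deSolve::lsoda(c(Y = 1, Z = 1), grid, rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-9)
  list(Y = out[, "Y"], Z = out[, "Z"])
}

# A small trace set with hand-picked values for IO/error-score tests.
toy_traces <- function(n_cells = 3, nT = 11) {
  grid <- seq(0, 10, length.out = nT)
  set.seed(42)
  X <- matrix(exp(runif(nT * n_cells, -0.5, 1.5)), nT, n_cells)
  Z <- matrix(exp(runif(nT * n_cells, -0.5, 1.5)), nT, n_cells)
  trace_set(grid, X, Z)
}
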