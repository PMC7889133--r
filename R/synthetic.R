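#' Generate heterogeneous single-cell upstream pulses
#'
#' Emulates a population of cells receiving the same step stimulus with
#' cell-to-cell variation in pulse height and onset delay: the population-mean
#' signal is a rapid `base_amplitude`-fold rise above basal after a
#' `delay_mean`-minute delay, returning to basal at `off_time` minutes. Per
#' cell, the amplitude is lognormal (`A = base_amplitude * exp(e)`, `e ~
#' N(0, s)` with `s` chosen so the amplitude coefficient of variation equals
#' `amplitude_cv`) and the delay is normal with sd `delay_sd`, truncated at 0.
#'
#' @param n_cells Number of cells (default 50).
#' @param base_amplitude Median pulse height, fold change (default 5).
#' @param delay_mean Mean onset delay, min (default 2).
#' @param off_time Time at which every pulse returns to basal, min (default 6);
#'   must exceed `delay_mean`.
#' @param amplitude_cv Coefficient of variation of the amplitude (default 0.2).
#' @param delay_sd Standard deviation of the onset delay, min (default 0.5).
#' @param grid Time grid, min (default 0 to 15 by 0.1).
#' @param seed Integer seed; fixed seed gives a bit-identical draw.
#' @return Matrix (time points x cells) of upstream fold changes with
#'   attributes `time`, `amplitude` and `delay`.
#' @examples
#' x <- generate_upstream(n_cells = 5, seed = 1)
#' dim(x)
#' @export
generate_upstream <- function(n_cells = 50L, base_amplitude = 5,
                              delay_mean = 2, off_time = 6,
                              amplitude_cv = 0.2, delay_sd = 0.5,
                              grid = seq(0, 15, by = 0.1), seed = NULL) {
  stopifnot(n_cells >= 1L, base_amplitude > 0, delay_mean >= 0,
            amplitude_cv >= 0, delay_sd >= 0)
  if (off_time <= delay_mean) {
    stop("off_time must exceed delay_mean (the pulse must have positive width)")
  }
  draws <- with_seed(seed, {
    sigma <- sqrt(log(1 + amplitude_cv^2))  # lognormal CV identity
    amp <- base_amplitude * exp(stats::rnorm(n_cells, 0, sigma))
    delay <- delay_mean + stats::rnorm(n_cells, 0, delay_sd)
    while (any(delay < 0)) {  # truncated-normal delay: redraw negatives
      k <- delay < 0
      delay[k] <- delay_mean + stats::rnorm(sum(k), 0, delay_sd)
    }
    list(amp = amp, delay = delay)
  })
  X <- vapply(seq_len(n_cells), function(c) {
    ifelse(grid >= draws$delay[c] & grid < off_time, draws$amp[c], 1)
  }, numeric(length(grid)))
  attr(X, "time") <- grid
  attr(X, "amplitude") <- draws$amp
  attr(X, "delay") <- draws$delay
  X
}

#' Default ground-truth parameters for synthetic data
#'
#' The parameter set used to turn upstream pulses into downstream responses
#' when none is supplied: `K = 2` fold change and `n = 2` on every link,
#' `alpha_Y = 0.3` and `alpha_Z = 1` per minute. One shared
#' threshold/coefficient keeps the truth inside the default Monte-Carlo
#' sampling bounds; `alpha_Y < alpha_Z` gives the hidden node the slower
#' accumulation that makes IFFL adaptation and cascade delay visible on a
#' 15-minute window.
#'
#' @return A [parameter_set].
#' @export
default_truth_params <- function() {
  parameter_set(K = 2, n = 2, alpha_Y = 0.3, alpha_Z = 1)
}

#' Generate a synthetic paired single-cell dataset from a known motif
#'
#' Draws heterogeneous upstream pulses with [generate_upstream] and pushes each
#' cell's pulse through the ground-truth motif's dynamics ([simulate_motif]) to
#' obtain its downstream response. The X-to-Z map is deterministic -- no output
#' noise is added -- so each cell's Z is exactly what the motif predicts for
#' its own X, and the pairing is the identity.
#'
#' @param truth Ground-truth motif: a library label (`"IFFL"`, `"cascade"`,
#'   `"feedback"`, `"CFFL"`, see [motif_library]) or a `signed_motif`.
#' @param n_cells Number of cells (default 50).
#' @param truth_params `parameter_set` for the ground truth (default: `K = 2`,
#'   `n = 2`, `alpha_Y = 0.3`, `alpha_Z = 1` per minute).
#' @param seed Integer seed for the upstream draw.
#' @param refine RK4 refinement used to produce Z (default 4).
#' @inheritParams generate_upstream
#' @return A `trace_set` whose `source` is the truth label and whose `config`
#'   records the generator settings and seed.
#' @examples
#' ts <- generate_dataset("IFFL", n_cells = 10, seed = 1)
#' ts
#' @export
generate_dataset <- function(truth = "IFFL", n_cells = 50L,
                             base_amplitude = 5, delay_mean = 2, off_time = 6,
                             amplitude_cv = 0.2, delay_sd = 0.5,
                             grid = seq(0, 15, by = 0.1),
                             truth_params = default_truth_params(),
                             seed = NULL, refine = 4L) {
  motif <- if (inherits(truth, "signed_motif")) truth else motif_library(truth)
  label <- attr(motif, "label")
  if (is.null(label)) label <- paste0("motif(", format(motif), ")")
  X <- generate_upstream(n_cells = n_cells, base_amplitude = base_amplitude,
                         delay_mean = delay_mean, off_time = off_time,
                         amplitude_cv = amplitude_cv, delay_sd = delay_sd,
                         grid = grid, seed = seed)
  sim <- simulate_motif(motif, truth_params, X, grid, refine = refine)
  if (!all(sim$ok)) stop("ground-truth simulation left the representable range")
  cfg <- list(truth = label, truth_signs = unname(unclass(motif)),
              n_cells = n_cells, base_amplitude = base_amplitude,
              delay_mean = delay_mean, off_time = off_time,
              amplitude_cv = amplitude_cv, delay_sd = delay_sd,
              grid = range(grid), dt = diff(grid[1:2]),
              truth_params = unclass(truth_params), seed = seed,
              refine = refine)
  trace_set(grid, X, sim$Z, source = label, config = cfg)
}
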