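#' Normalized Hill regulatory factor on the fold-change scale
#'
#' Hill-Langmuir factor rescaled so that the basal state `u = 1` maps to 1,
#' which makes the all-basal state an exact fixed point of the motif dynamics.
#' Activation: `h+(u) = u^n (K^n + 1) / (K^n + u^n)`; repression:
#' `h-(u) = (K^n + 1) / (K^n + u^n)`. As `u` grows, activation saturates at
#' `K^n + 1` and repression decays to 0; both equal 1 at `u = 1`.
#'
#' @param u Regulator level in fold change over basal (`>= 0`); vectorized.
#' @param K Hill threshold in fold-change units (`> 0`).
#' @param n Hill coefficient (`>= 1`).
#' @param sign `+1` for activation, `-1` for repression.
#' @return Positive numeric of the same length as `u`.
#' @examples
#' hill_term(1, K = 2, n = 3, sign = 1)    # 1: basal normalization
#' hill_term(3, K = 1, n = 1, sign = -1)   # 0.5
#' @export
hill_term <- function(u, K, n, sign) {
  if (any(u < 0)) stop("regulator fold change must be nonnegative")
  if (K <= 0) stop("Hill threshold K must be positive")
  if (n < 1) stop("Hill coefficient n must be >= 1")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 (activation) or -1 (repression)")
  Kn <- K^n
  un <- u^n
  if (sign > 0) un * (Kn + 1) / (Kn + un) else (Kn + 1) / (Kn + un)
}

#' Construct a parameter set for one motif simulation
#'
#' Every link carries a Hill threshold `K` (fold-change units) and coefficient
#' `n`; each dynamic node carries a relaxation rate (`alpha_Y`, `alpha_Z`, per
#' minute). Parameters attached to absent links are simply ignored by the
#' dynamics, so a full set can be shared across motifs.
#'
#' @param K Numeric length 6 (or scalar, recycled): per-link thresholds in the
#'   fixed link order `XY, XZ, YY, YZ, ZY, ZZ`; all `> 0`.
#' @param n Integer length 6 (or scalar, recycled): per-link Hill coefficients,
#'   all `>= 1`.
#' @param alpha_Y,alpha_Z Relaxation rates (1/min), `> 0`.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(K, n, alpha_Y, alpha_Z) {
  K <- rep_len(as.numeric(K), 6L)
  n <- rep_len(as.integer(n), 6L)
  if (any(K <= 0)) stop("all Hill thresholds K must be positive")
  if (any(n < 1)) stop("all Hill coefficients n must be >= 1")
  if (alpha_Y <= 0 || alpha_Z <= 0) stop("relaxation rates must be positive")
  names(K) <- names(n) <- MOTIF_LINKS
  structure(list(K = K, n = n, alpha_Y = as.numeric(alpha_Y),
                 alpha_Z = as.numeric(alpha_Z)),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Parameter set:\n  K: ", paste(signif(x$K, 3), collapse = " "),
      "\n  n: ", paste(x$n, collapse = " "),
      "\n  alpha_Y: ", x$alpha_Y, " /min  alpha_Z: ", x$alpha_Z, " /min\n",
      sep = "")
  invisible(x)
}

# Upstream values at half-step resolution on the refined integration grid.
# Linear interpolation between samples, clamped at the trace endpoints.
# Returns a matrix [(2 * refine * (nT - 1) + 1) x nCells].
upstream_halfgrid <- function(x, time, refine) {
  x <- as.matrix(x)
  nT <- length(time)
  if (nrow(x) != nT) stop("upstream trace rows must match the time grid")
  # half-step query times, per interval
  tq <- unlist(lapply(seq_len(nT - 1L), function(i) {
    h <- (time[i + 1L] - time[i]) / (2L * refine)
    time[i] + h * seq_len(2L * refine) - h  # left edge .. just before right
  }), use.names = FALSE)
  tq <- c(tq, time[nT])
  apply(x, 2L, function(col) {
    stats::approx(time, col, xout = tq, rule = 2)$y
  })
}

#' Simulate a motif's downstream response to upstream traces
#'
#' Integrates the fold-change dynamics
#' \deqn{dY/dt = \alpha_Y (F_Y - Y), \quad dZ/dt = \alpha_Z (F_Z - Z)}
#' where `F_Y` and `F_Z` are products of normalized Hill factors over the
#' node's incoming nonzero links ([hill_term]), `X(t)` is exogenous (linearly
#' interpolated between samples) and `Y(0) = Z(0) = 1`. A node with no incoming
#' links has `F = 1` and rests at basal. Integration is fixed-step classic RK4
#' on the data's time grid refined by `refine` sub-steps per interval, which
#' vectorizes cheaply across cells and parameter sets.
#'
#' Numerical guards: states are clipped below at `1e-9`; if any state exceeds
#' `1e6` or becomes non-finite the affected cell is flagged invalid (the
#' returned `ok` flag), never an error -- downstream scoring assigns such
#' combinations the worst (baseline) error.
#'
#' @param motif A `signed_motif`.
#' @param params A `parameter_set`.
#' @param x Upstream trace(s) in fold change: numeric vector (one cell) or
#'   matrix with one column per cell, sampled on `time`. All values `> 0`.
#' @param time Strictly increasing numeric time grid (minutes).
#' @param refine Integer sub-steps per grid interval (default 4).
#' @return A `sim_result`: list with `time`, matrices `Y` and `Z` (rows =
#'   time points, columns = cells), and logical `ok` per cell.
#' @examples
#' tt <- seq(0, 15, 0.1)
#' x <- ifelse(tt >= 2 & tt < 6, 5, 1)
#' p <- parameter_set(K = 2, n = 2, alpha_Y = 0.3, alpha_Z = 1)
#' s <- simulate_motif(motif_library("IFFL"), p, x, tt)
#' range(s$Z)  # transient rise then undershoot below basal
#' @export
simulate_motif <- function(motif, params, x, time, refine = 4L) {
  if (!inherits(motif, "signed_motif")) motif <- signed_motif(motif)
  stopifnot(inherits(params, "parameter_set"))
  x <- as.matrix(x)
  if (length(time) < 2L || is.unsorted(time, strictly = TRUE)) {
    stop("time must be a strictly increasing grid with >= 2 points")
  }
  if (nrow(x) != length(time)) stop("x must be sampled on the given time grid")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("upstream traces must be finite and strictly positive fold changes")
  }
  refine <- as.integer(refine)
  stopifnot(refine >= 1L)
  xh <- upstream_halfgrid(x, time, refine)
  out <- rk4_trajectories(unclass(motif), xh, as.numeric(time), refine,
                          params$K, params$n, params$alpha_Y, params$alpha_Z)
  structure(list(time = time, Y = out$Y, Z = out$Z, ok = out$ok),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Motif simulation: ", ncol(x$Z), " cell(s), ",
      length(x$time), " time points (",
      x$time[1], "-", x$time[length(x$time)], " min), ",
      sum(!x$ok), " invalid\n", sep = "")
  invisible(x)
}
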