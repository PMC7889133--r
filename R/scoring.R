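#' Monte-Carlo sample of bounded parameter sets
#'
#' Draws independent parameter sets for the motif dynamics: per-link Hill
#' thresholds `K` log-uniform on `K_bounds`, per-link integer Hill
#' coefficients uniform on `n_bounds`, and relaxation rates log-uniform on
#' `alpha_bounds`. Parameters are sampled for all six links, so one draw can
#' be shared across every motif (each motif reads only the entries for its
#' nonzero links); this shared-draw design keeps motif ranking comparable
#' rather than confounded by per-motif sampling luck.
#'
#' @param count Number of parameter sets (default 40000).
#' @param config A [run_config] supplying the bounds.
#' @param seed Integer seed; the same seed reproduces the draw exactly.
#' @return A `parameter_sample`: list with matrices `K` (`count x 6`), `n`
#'   (`count x 6`) and vectors `alpha_Y`, `alpha_Z`, plus the bounds and seed.
#' @export
sample_parameters <- function(count = 40000L, config = run_config(),
                              seed = NULL) {
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("count must be >= 1")
  kb <- config$K_bounds
  nb <- config$n_bounds
  ab <- config$alpha_bounds
  out <- with_seed(seed, {
    logu <- function(m, lo, hi) exp(matrix(stats::runif(m, log(lo), log(hi)), ncol = 6L))
    K <- logu(count * 6L, kb[1], kb[2])
    n <- matrix(sample.int(nb[2] - nb[1] + 1L, count * 6L, replace = TRUE) +
                  nb[1] - 1L, ncol = 6L)
    aY <- exp(stats::runif(count, log(ab[1]), log(ab[2])))
    aZ <- exp(stats::runif(count, log(ab[1]), log(ab[2])))
    list(K = K, n = n, alpha_Y = aY, alpha_Z = aZ)
  })
  colnames(out$K) <- colnames(out$n) <- MOTIF_LINKS
  structure(c(out, list(bounds = list(K = kb, n = nb, alpha = ab),
                        seed = seed)),
            class = "parameter_sample")
}

#' @export
print.parameter_sample <- function(x, ...) {
  cat("Monte-Carlo parameter sample: ", nrow(x$K), " sets",
      if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"), "\n", sep = "")
  invisible(x)
}

#' @rdname sample_parameters
#' @param ps A `parameter_sample`.
#' @param i Index of the set to extract.
#' @return `param_set` returns the `i`-th draw as a [parameter_set].
#' @export
param_set <- function(ps, i) {
  parameter_set(K = ps$K[i, ], n = ps$n[i, ],
                alpha_Y = ps$alpha_Y[i], alpha_Z = ps$alpha_Z[i])
}

# Append one extra parameter set (used to inject a known truth into a search).
append_param <- function(ps, p) {
  ps$K <- rbind(ps$K, p$K)
  ps$n <- rbind(ps$n, p$n)
  ps$alpha_Y <- c(ps$alpha_Y, p$alpha_Y)
  ps$alpha_Z <- c(ps$alpha_Z, p$alpha_Z)
  ps
}

#' Trace-matching error score
#'
#' The error between observed and predicted downstream responses is the mean
#' over cells of the time-averaged absolute fold-change difference: per cell,
#' the trapezoidal integral of `|Z - Z'|` over the grid divided by the trace
#' duration; units are fold change per cell per unit time.
#'
#' @param observed,predicted Numeric matrices (time points x cells) on the
#'   same grid, or vectors for a single cell.
#' @param time The shared time grid (minutes).
#' @return Nonnegative scalar.
#' @examples
#' tt <- 0:10
#' error_score(matrix(3, 11, 1), matrix(1, 11, 1), tt)  # 2
#' @export
error_score <- function(observed, predicted, time) {
  observed <- as.matrix(observed)
  predicted <- as.matrix(predicted)
  if (!identical(dim(observed), dim(predicted))) {
    stop("observed and predicted traces differ in dimension (grid mismatch)")
  }
  if (nrow(observed) != length(time)) {
    stop("trace rows must match the time grid")
  }
  d <- abs(observed - predicted)
  dt <- diff(time)
  w <- c(dt / 2, 0) + c(0, dt / 2)  # trapezoid weights
  mean(colSums(d * w)) / (time[length(time)] - time[1])
}

#' Baseline (worst-possible) error of a dataset
#'
#' The error score of the flat basal predictor `Z' == 1`, i.e. the output of
#' an unconnected motif with no signaling input to Z. Ranked combo errors
#' asymptote to this value, and it is the score assigned to combinations whose
#' integration fails.
#'
#' @param observed Observed downstream traces (time points x cells).
#' @param time Time grid.
#' @return Nonnegative scalar `E0`.
#' @export
baseline_error <- function(observed, time) {
  observed <- as.matrix(observed)
  error_score(observed, matrix(1, nrow(observed), ncol(observed)), time)
}

#' Score every motif/parameter combination against a dataset
#'
#' For each motif and each Monte-Carlo parameter set, simulates the predicted
#' downstream response `Z'` per cell (driven by that cell's own upstream trace
#' under the current pairing) and computes the [error_score] against the
#' observed `Z`. Combinations whose integration leaves the representable range
#' are flagged invalid and assigned the baseline error `E0`; valid errors are
#' capped at `E0`, the worst possible score (the flat-line output of an
#' unconnected motif), so the ranked error curve ends on the `E0` asymptote.
#'
#' @param traces A `trace_set`.
#' @param motifs A `motif_set` (default: all 402 canonical motifs).
#' @param params A `parameter_sample` from [sample_parameters].
#' @param config A [run_config]; supplies the RK4 refinement and elbow
#'   settings used by downstream steps.
#' @param progress Emit a progress message every `progress` motifs (0 = quiet).
#' @return A `score_board`: list with the combo table (`motif`, `param`,
#'   `error`, `valid`), the motif sign matrix, `E0`, and the inputs needed for
#'   elbow selection.
#' @export
score_all <- function(traces, motifs = enumerate_motifs(), params,
                      config = run_config(), progress = 0L) {
  stopifnot(inherits(traces, "trace_set"), inherits(params, "parameter_sample"))
  if (length(motifs) == 0L) stop("no motifs to score")
  nP <- nrow(params$K)
  nM <- length(motifs)
  Zp <- paired_Z(traces)
  E0 <- baseline_error(Zp, traces$time)
  xh <- upstream_halfgrid(traces$X, traces$time, config$refine)

  err <- matrix(NA_real_, nP, nM)
  ok <- matrix(TRUE, nP, nM)
  t0 <- proc.time()[["elapsed"]]
  for (j in seq_len(nM)) {
    res <- rk4_score(unclass(motifs[[j]]), xh, Zp, traces$time, config$refine,
                     params$K, params$n, params$alpha_Y, params$alpha_Z)
    e <- res$error
    v <- res$valid
    e[!v] <- E0
    e[e > E0] <- E0
    err[, j] <- e
    ok[, j] <- v
    if (progress > 0L && (j %% progress == 0L || j == nM)) {
      message(sprintf("scored motif %d/%d (%.1fs elapsed, %d invalid combos)",
                      j, nM, proc.time()[["elapsed"]] - t0, sum(!ok[, seq_len(j)])))
    }
  }
  combos <- data.frame(
    motif = rep(seq_len(nM), each = nP),
    param = rep(seq_len(nP), times = nM),
    error = as.vector(err),
    valid = as.vector(ok)
  )
  structure(list(combos = combos, motif_signs = motif_matrix(motifs),
                 E0 = E0, n_motifs = nM, n_params = nP, config = config),
            class = "score_board")
}

#' @export
print.score_board <- function(x, ...) {
  cat("Score board: ", x$n_motifs, " motifs x ", x$n_params,
      " parameter sets = ", nrow(x$combos), " combos\n",
      "  baseline error E0 = ", signif(x$E0, 4),
      "; invalid combos: ", sum(!x$combos$valid), "\n", sep = "")
  invisible(x)
}

#' Persist a score board as TSV plus a JSON summary
#'
#' Writes one row per motif/parameter combination -- the six-sign motif
#' vector, the parameter values for that draw, the (capped) error and the
#' validity flag -- and, optionally, a JSON summary with the baseline error,
#' elbow rank and top-set size.
#'
#' @param board A `score_board`, ranked or not (it is ranked on the fly for
#'   the summary).
#' @param params The `parameter_sample` the board was scored with.
#' @param path Output TSV path.
#' @param summary_path Optional JSON summary path.
#' @return `path`, invisibly.
#' @export
write_scoreboard <- function(board, params, path, summary_path = NULL) {
  stopifnot(inherits(board, "score_board"), inherits(params, "parameter_sample"))
  cb <- board$combos
  signs <- board$motif_signs[cb$motif, , drop = FALSE]
  colnames(signs) <- paste0("sign_", MOTIF_LINKS)
  K <- params$K[cb$param, , drop = FALSE]
  colnames(K) <- paste0("K_", MOTIF_LINKS)
  n <- params$n[cb$param, , drop = FALSE]
  colnames(n) <- paste0("n_", MOTIF_LINKS)
  tab <- data.frame(signs, K, n,
                    alpha_Y = params$alpha_Y[cb$param],
                    alpha_Z = params$alpha_Z[cb$param],
                    error = cb$error, valid = cb$valid)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path)) {
    if (is.null(board$elbow_rank)) board <- rank_board(board)
    jsonlite::write_json(
      list(E0 = board$E0, elbow_rank = board$elbow_rank,
           top_set_size = length(board$top), n_motifs = board$n_motifs,
           n_params = board$n_params, invalid = sum(!cb$valid)),
      summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Elbow of the ranked error curve
#'
#' Sorted ascending, combo errors rise from the best fits toward the `E0`
#' asymptote. The well-performing set is cut at the elbow: using windowed
#' first differences `s_i = (e[i+w] - e[i]) / w` over the ranked errors, find
#' the rank of maximum slope, then return the first subsequent rank whose
#' slope falls below `slope_fraction` of that maximum. Combos ranked before
#' the returned rank form the top set.
#'
#' @param errors Numeric vector of errors sorted ascending (length >= 3).
#' @param slope_fraction Fraction of the maximum slope (default 0.10).
#' @param window Rank window `w` for the differences; default `max(1,
#'   floor(N/1000))`.
#' @return The elbow rank (integer in `[1, N]`). If all errors are equal there
#'   is no informative elbow: rank 1 is returned with a warning.
#' @export
find_elbow <- function(errors, slope_fraction = 0.10, window = NULL) {
  N <- length(errors)
  if (N < 3L) stop("need at least 3 sorted errors")
  if (is.unsorted(errors)) stop("errors must be sorted ascending")
  if (slope_fraction <= 0 || slope_fraction > 1) {
    stop("slope_fraction must lie in (0, 1]")
  }
  w <- if (is.null(window)) max(1L, N %/% 1000L) else as.integer(window)
  w <- min(w, N - 1L)
  s <- (errors[(1L + w):N] - errors[1L:(N - w)]) / w
  imax <- which.max(s)
  if (s[imax] <= 0) {
    warning("all errors equal; no informative elbow (returning rank 1)")
    return(1L)
  }
  after <- which(s[(imax + 1L):length(s)] < slope_fraction * s[imax])
  if (length(after) == 0L) return(N)  # slope never levels off
  imax + after[1L]
}

#' Rank a score board and select the top set
#'
#' Sorts all combo errors ascending, finds the elbow ([find_elbow]) at the
#' configured slope fraction, and marks the combos ranked before it as the
#' well-performing (top) set.
#'
#' @param board A `score_board` from [score_all].
#' @return The board with added elements `order` (ranking permutation),
#'   `elbow_rank` and `top` (combo row indices in rank order).
#' @export
rank_board <- function(board) {
  stopifnot(inherits(board, "score_board"))
  ord <- order(board$combos$error)
  elbow <- find_elbow(board$combos$error[ord],
                      slope_fraction = board$config$elbow_fraction,
                      window = board$config$elbow_window)
  board$order <- ord
  board$elbow_rank <- elbow
  board$top <- ord[seq_len(max(1L, elbow - 1L))]
  board
}
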