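# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched. A NULL seed uses (and advances) the global
# stream, so explicit seeds remain the reproducible path.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive a child seed from a base seed and a stream index, staying inside the
# 32-bit signed integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + k * 7919) %% 2147483629)
}

#' Engine configuration for a full inference run
#'
#' Bundles the tunable settings of the inference engine with their defaults:
#' 40,000 Monte-Carlo parameter sets, Hill thresholds log-uniform on
#' `[0.1, 10]` fold change, integer Hill coefficients 1--4, relaxation rates
#' log-uniform on `[0.05, 2]` per minute, a 10% elbow slope fraction, and
#' 50%/80% confidence flags.
#'
#' @param n_params Number of Monte-Carlo parameter sets (default 40000).
#' @param K_bounds,alpha_bounds Length-2 positive bounds (log-uniform draws).
#' @param n_bounds Length-2 integer bounds for the Hill coefficient.
#' @param elbow_fraction Slope fraction for elbow detection, in (0, 1).
#' @param elbow_window Rank window for slope smoothing; `NULL` = `max(1, N/1000)`.
#' @param conf_thresholds Confidence flag levels, each in (0, 1).
#' @param refine RK4 sub-steps per data interval.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(n_params = 40000L,
                       K_bounds = c(0.1, 10),
                       n_bounds = c(1L, 4L),
                       alpha_bounds = c(0.05, 2),
                       elbow_fraction = 0.10,
                       elbow_window = NULL,
                       conf_thresholds = c(0.5, 0.8),
                       refine = 4L) {
  stopifnot(n_params >= 1L)
  check_bounds <- function(b, name, positive = TRUE) {
    if (length(b) != 2L || b[1] > b[2]) stop(name, " bounds must be c(lo, hi) with lo <= hi")
    if (positive && b[1] <= 0) stop(name, " bounds must be positive")
  }
  check_bounds(K_bounds, "K")
  check_bounds(n_bounds, "n", positive = FALSE)
  if (n_bounds[1] < 1L) stop("Hill coefficient bounds must be >= 1")
  check_bounds(alpha_bounds, "alpha")
  if (elbow_fraction <= 0 || elbow_fraction >= 1) {
    stop("elbow_fraction must lie in (0, 1)")
  }
  if (any(conf_thresholds <= 0 | conf_thresholds >= 1)) {
    stop("confidence thresholds must lie in (0, 1)")
  }
  structure(list(n_params = as.integer(n_params),
                 K_bounds = as.numeric(K_bounds),
                 n_bounds = as.integer(n_bounds),
                 alpha_bounds = as.numeric(alpha_bounds),
                 elbow_fraction = elbow_fraction,
                 elbow_window = elbow_window,
                 conf_thresholds = sort(conf_thresholds),
                 refine = as.integer(refine)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Inference engine configuration:\n",
      "  parameter sets: ", x$n_params, "\n",
      "  K in [", x$K_bounds[1], ", ", x$K_bounds[2], "] (log-uniform), ",
      "n in {", x$n_bounds[1], "..", x$n_bounds[2], "}, ",
      "alpha in [", x$alpha_bounds[1], ", ", x$alpha_bounds[2], "] /min\n",
      "  elbow slope fraction: ", x$elbow_fraction,
      ", confidence flags: ", paste(x$conf_thresholds, collapse = "/"), "\n",
      "  RK4 refinement: x", x$refine, "\n", sep = "")
  invisible(x)
}
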