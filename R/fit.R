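#' Infer the signaling motif underlying paired single-cell traces
#'
#' The main fitting function. Given a paired trace set it (1) enumerates the
#' candidate signed motifs, (2) draws one shared bank of bounded Monte-Carlo
#' parameter sets, (3) simulates every motif/parameter combination per cell
#' and scores it against the observed downstream traces, (4) cuts the ranked
#' error curve at its elbow to define the well-performing set, and (5)
#' summarises that set as a consensus motif with per-link confidences. If a
#' reference motif is supplied (or known from the data's provenance), the
#' confidence-weighted distance to it and a Monte-Carlo significance are also
#' computed.
#'
#' @param traces A `trace_set` ([trace_set], [read_traces], [generate_dataset]).
#' @param motifs Candidate `motif_set` (default: all 402 canonical motifs).
#' @param config A [run_config] with engine settings.
#' @param ref Optional reference `signed_motif` for distance/significance; if
#'   `NULL` and the traces carry a known ground truth, that truth is used.
#' @param seed Integer seed governing the parameter draw and the significance
#'   null sample.
#' @param n_random Random graphs for the significance test (0 to skip).
#' @param progress Progress message period in motifs (0 = quiet).
#' @param keep_board Keep the full score board in the fit (default TRUE;
#'   set `FALSE` to save memory, retaining only the ranked error curve).
#' @return An object of class `motif_infer` with components `consensus`,
#'   `board` (ranked score board), `sorted_errors`, `E0`, `elbow_rank`,
#'   `distance`, `significance`, `config` and `seed`. Methods: [print],
#'   [summary], [coef], [plot], [predict], [residuals].
#' @examples
#' \donttest{
#' ts <- generate_dataset("IFFL", n_cells = 10, seed = 1)
#' fit <- motif_infer(ts, config = run_config(n_params = 200, refine = 1),
#'                    seed = 1, n_random = 1000)
#' fit
#' }
#' @export
motif_infer <- function(traces, motifs = enumerate_motifs(),
                        config = run_config(), ref = NULL, seed = NULL,
                        n_random = 10000L, progress = 0L, keep_board = TRUE) {
  stopifnot(inherits(traces, "trace_set"))
  params <- sample_parameters(config$n_params, config,
                              seed = child_seed(seed, 1L))
  board <- score_all(traces, motifs, params, config, progress = progress)
  board <- rank_board(board)
  cons <- consensus_motif(board)

  if (is.null(ref) && !is.null(traces$config$truth_signs)) {
    ref <- signed_motif(traces$config$truth_signs, label = traces$source)
  }
  dist <- sig <- NULL
  if (!is.null(ref)) {
    dist <- motif_distance(cons, ref)
    if (n_random > 0L) {
      sig <- significance(dist, ref, n_random = n_random,
                          seed = child_seed(seed, 2L))
    }
  }

  # best-fitting single combo, for prediction and residuals
  best_row <- board$order[1L]
  best <- list(motif = motifs[[board$combos$motif[best_row]]],
               params = param_set(params, board$combos$param[best_row]),
               error = board$combos$error[best_row])

  fit <- list(consensus = cons,
              sorted_errors = board$combos$error[board$order],
              E0 = board$E0,
              elbow_rank = board$elbow_rank,
              top_size = length(board$top),
              best = best,
              ref = ref,
              distance = dist,
              significance = sig,
              config = config,
              seed = seed,
              traces = traces,
              params_seed = child_seed(seed, 1L))
  if (keep_board) {
    fit$board <- board
    fit$params <- params
  }
  structure(fit, class = "motif_infer")
}

#' @export
print.motif_infer <- function(x, ...) {
  cat("Signaling-motif inference fit\n")
  cat("  data: ", length(x$traces$cells), " cells (", x$traces$source, ")\n",
      sep = "")
  cat("  search: ", length(x$sorted_errors), " combos; E0 = ",
      signif(x$E0, 4), "; top set = ", x$top_size,
      " (elbow rank ", x$elbow_rank, ")\n", sep = "")
  print(x$consensus)
  if (!is.null(x$distance)) {
    cat("  distance to ", if (!is.null(attr(x$ref, "label")))
      attr(x$ref, "label") else "reference", ": ", signif(x$distance, 4),
      if (!is.null(x$significance))
        paste0(" (p = ", signif(x$significance$p_value, 3), ")"),
      "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.motif_infer <- function(object, ...) {
  flags <- vapply(object$config$conf_thresholds, function(th) {
    paste(names(confident_links(object$consensus, th)), collapse = ",")
  }, character(1))
  names(flags) <- paste0(">", 100 * object$config$conf_thresholds, "%")
  s <- list(consensus = object$consensus,
            confident = flags,
            E0 = object$E0,
            best_error = object$best$error,
            elbow_rank = object$elbow_rank,
            top_size = object$top_size,
            distance = object$distance,
            p_value = if (!is.null(object$significance))
              object$significance$p_value else NULL,
            n_combos = length(object$sorted_errors))
  class(s) <- "summary.motif_infer"
  s
}

#' @export
print.summary.motif_infer <- function(x, ...) {
  print(x$consensus)
  cat("Confident links: ",
      paste(names(x$confident), x$confident, sep = ": ", collapse = " | "),
      "\n", sep = "")
  cat("Combos: ", x$n_combos, "; best error ", signif(x$best_error, 4),
      "; E0 ", signif(x$E0, 4), "; top set ", x$top_size, "\n", sep = "")
  if (!is.null(x$distance)) {
    cat("Distance to reference: ", signif(x$distance, 4),
        if (!is.null(x$p_value)) paste0(" (p = ", signif(x$p_value, 3), ")"),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.motif_infer <- function(object, ...) {
  object$consensus$signs
}

#' Plot the ranked error curve of a motif-inference fit
#'
#' Errors of all motif/parameter combinations in ascending rank order, with
#' the baseline (worst-possible) error `E0` as a horizontal asymptote and the
#' elbow rank that cuts the well-performing set as a vertical line.
#'
#' @param x A `motif_infer` fit.
#' @param ... Passed to [graphics::plot].
#' @export
plot.motif_infer <- function(x, ...) {
  e <- x$sorted_errors
  graphics::plot(seq_along(e), e, type = "l", xlab = "rank",
                 ylab = "error (fold change / cell / min)",
                 main = "Ranked combo errors", ...)
  graphics::abline(h = x$E0, lty = 2, col = "grey40")
  graphics::abline(v = x$elbow_rank, lty = 3, col = "red")
  graphics::legend("bottomright", bty = "n", lty = c(2, 3),
                   col = c("grey40", "red"),
                   legend = c("baseline E0", "elbow"))
  invisible(x)
}

#' Predict downstream responses from a fitted motif
#'
#' Simulates the best-scoring (motif, parameter) combination of the fit on
#' upstream traces -- by default the training traces.
#'
#' @param object A `motif_infer` fit.
#' @param newdata Optional `trace_set` (its X traces are used).
#' @param ... Unused.
#' @return A `sim_result` with the predicted `Z'` trajectories.
#' @export
predict.motif_infer <- function(object, newdata = NULL, ...) {
  ts <- if (is.null(newdata)) object$traces else newdata
  simulate_motif(object$best$motif, object$best$params, ts$X, ts$time,
                 refine = object$config$refine)
}

#' @export
residuals.motif_infer <- function(object, ...) {
  pred <- predict(object)
  paired_Z(object$traces) - pred$Z
}
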