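#' Paired versus shuffled-pairs inference comparison
#'
#' Runs the full inference pipeline (score, elbow, consensus, distance to a
#' reference motif) on the data as paired, and on independently deranged
#' pairings, with `n_replicates` replicates per condition. Paired replicates
#' differ only in their Monte-Carlo parameter draw; shuffled replicates
#' additionally draw a fresh derangement. Because a derangement leaves the
#' trace multisets untouched, the population-mean X and Z trajectories are
#' bit-identical between conditions -- only the cell-level coupling differs.
#'
#' @param t A `trace_set`.
#' @param ref Reference `signed_motif` distances are measured against; default
#'   the data's ground truth if recorded.
#' @param n_replicates Replicates per condition (default 10).
#' @param motifs Candidate `motif_set`.
#' @param config A [run_config].
#' @param seed Integer base seed; replicate seeds are derived from it.
#' @param progress Passed to [score_all].
#' @return A data frame with columns `condition` (`"paired"`/`"shuffled"`),
#'   `replicate`, `distance` and `seed`.
#' @export
paired_vs_shuffled <- function(t, ref = NULL, n_replicates = 10L,
                               motifs = enumerate_motifs(),
                               config = run_config(), seed = NULL,
                               progress = 0L) {
  stopifnot(inherits(t, "trace_set"))
  if (is.null(ref)) {
    if (is.null(t$config$truth_signs)) stop("no reference motif available")
    ref <- signed_motif(t$config$truth_signs, label = t$source)
  }
  one <- function(ts, rep_seed) {
    fit <- motif_infer(ts, motifs = motifs, config = config, ref = ref,
                       seed = rep_seed, n_random = 0L, progress = progress,
                       keep_board = FALSE)
    fit$distance
  }
  rows <- lapply(seq_len(n_replicates), function(r) {
    sp <- child_seed(seed, 10L + r)   # paired replicate: fresh parameter draw
    ss <- child_seed(seed, 100L + r)  # shuffled replicate
    shuffled <- shuffle_pairs(t, seed = child_seed(seed, 1000L + r))
    data.frame(condition = c("paired", "shuffled"),
               replicate = r,
               distance = c(one(t, sp), one(shuffled, ss)),
               seed = c(if (is.null(sp)) NA_integer_ else sp,
                        if (is.null(ss)) NA_integer_ else ss))
  })
  do.call(rbind, rows)
}

#' Subsampling analysis: inference quality versus number of cells
#'
#' For each requested sample size, draws `n_replicates` random subsets of
#' cells without replacement, runs the full pipeline on each, and records the
#' confidence-weighted distance to the reference motif together with whether
#' every link confident above 50% carries the correct reference sign (the
#' correct-submotif readout).
#'
#' @param t A `trace_set`.
#' @param ref Reference `signed_motif`; default the recorded ground truth.
#' @param sizes Integer sample sizes (default 5 to the full population in
#'   steps of 5); each must be between 2 and the number of cells.
#' @param n_replicates Replicates per size (default 5).
#' @param motifs Candidate `motif_set`.
#' @param config A [run_config].
#' @param seed Integer base seed.
#' @param progress Passed to [score_all].
#' @return A data frame with columns `size`, `replicate`, `distance`,
#'   `correct_submotif`.
#' @export
subsample_analysis <- function(t, ref = NULL,
                               sizes = seq(5L, n_cells(t), by = 5L),
                               n_replicates = 5L,
                               motifs = enumerate_motifs(),
                               config = run_config(), seed = NULL,
                               progress = 0L) {
  stopifnot(inherits(t, "trace_set"))
  if (any(sizes < 2L)) stop("subsample sizes must be at least 2 cells")
  if (max(sizes) > n_cells(t)) stop("subsample size exceeds the population")
  if (is.null(ref)) {
    if (is.null(t$config$truth_signs)) stop("no reference motif available")
    ref <- signed_motif(t$config$truth_signs, label = t$source)
  }
  rows <- list()
  for (s in seq_along(sizes)) {
    for (r in seq_len(n_replicates)) {
      sub_seed <- child_seed(seed, 10000L + 100L * s + r)
      idx <- with_seed(sub_seed, sort(sample.int(n_cells(t), sizes[s])))
      fit <- motif_infer(t[idx], motifs = motifs, config = config, ref = ref,
                         seed = child_seed(seed, 20000L + 100L * s + r),
                         n_random = 0L, progress = progress,
                         keep_board = FALSE)
      over50 <- confident_links(fit$consensus, 0.5)
      correct <- all(over50 == unclass(ref)[names(over50)])
      rows[[length(rows) + 1L]] <-
        data.frame(size = sizes[s], replicate = r, distance = fit$distance,
                   correct_submotif = correct)
    }
  }
  do.call(rbind, rows)
}

#' Export an inference report as JSON
#'
#' Writes the consensus sign vector and confidences, the links flagged at the
#' configured confidence thresholds, the distance and p-value when available,
#' the engine configuration, seeds, and a content hash of the input traces.
#'
#' @param fit A `motif_infer` fit.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path) {
  stopifnot(inherits(fit, "motif_infer"))
  flags <- lapply(fit$config$conf_thresholds, function(th) {
    as.list(confident_links(fit$consensus, th))
  })
  names(flags) <- paste0("over_", 100 * fit$config$conf_thresholds)
  report <- list(
    consensus = list(links = MOTIF_LINKS,
                     signs = unname(fit$consensus$signs),
                     confidence = unname(fit$consensus$confidence),
                     ties = fit$consensus$ties),
    confident_links = flags,
    top_set_size = fit$top_size,
    elbow_rank = fit$elbow_rank,
    baseline_error = fit$E0,
    best_error = fit$best$error,
    distance = fit$distance,
    p_value = if (!is.null(fit$significance)) fit$significance$p_value,
    n_random = if (!is.null(fit$significance)) fit$significance$n_random,
    seed = fit$seed,
    config = unclass(fit$config),
    input_hash = trace_hash(fit$traces),
    n_cells = length(fit$traces$cells),
    source = fit$traces$source
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Cheap content hash of a trace set (sum-based fingerprint; enough to tie a
# report to its input without a digest dependency).
trace_hash <- function(ts) {
  v <- c(ts$time, ts$X, paired_Z(ts))
  sprintf("%.0f", sum(v * seq_along(v)) %% 1e15)
}
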