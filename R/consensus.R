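#' Consensus motif over the well-performing set
#'
#' For each of the six links independently, the consensus sign is the modal
#' sign across the top motif/parameter combinations and the confidence is the
#' modal fraction (how often that sign appears). With three categories the
#' confidence can never fall below 1/3. Ties are broken toward 0 (absent) and
#' reported in the result.
#'
#' @param top A ranked `score_board` (see [rank_board]), in which case the
#'   elbow-selected top set is used, or an integer sign matrix with one row
#'   per top combo and the six link columns.
#' @return A `consensus_motif`: list with `signs` (named length-6 vector),
#'   `confidence` (named, in `[1/3, 1]`), `ties` (links whose mode was tied),
#'   and `n_top` (number of combos used).
#' @examples
#' consensus_motif(rbind(c(1,1,0,-1,0,0), c(1,1,0,-1,0,0), c(-1,1,0,-1,0,0)))
#' @export
consensus_motif <- function(top) {
  if (inherits(top, "score_board")) {
    if (is.null(top$top)) top <- rank_board(top)
    signs <- top$motif_signs[top$combos$motif[top$top], , drop = FALSE]
  } else {
    signs <- as.matrix(top)
  }
  if (nrow(signs) == 0L) stop("empty top set: nothing to form a consensus over")
  if (ncol(signs) != 6L) stop("sign matrix must have 6 link columns")
  cons <- integer(6L)
  conf <- numeric(6L)
  ties <- character(0)
  for (l in seq_len(6L)) {
    counts <- c(`-1` = sum(signs[, l] == -1L),
                `0`  = sum(signs[, l] == 0L),
                `1`  = sum(signs[, l] == 1L))
    best <- max(counts)
    modal <- as.integer(names(counts)[counts == best])
    cons[l] <- if (0L %in% modal) 0L else modal[1L]  # ties break toward absent
    conf[l] <- best / nrow(signs)
    if (sum(counts == best) > 1L) ties <- c(ties, MOTIF_LINKS[l])
  }
  names(cons) <- names(conf) <- MOTIF_LINKS
  structure(list(signs = cons, confidence = conf, ties = ties,
                 n_top = nrow(signs)),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat("Consensus motif over", x$n_top, "well-performing combos:\n")
  sym <- c("-", ".", "+")[x$signs + 2L]
  flag <- ifelse(x$confidence > 0.8, "**",
                 ifelse(x$confidence > 0.5, "*", ""))
  for (l in seq_len(6L)) {
    cat(sprintf("  %s  %s  confidence %5.1f%% %s\n",
                MOTIF_LINK_LABELS[l], sym[l], 100 * x$confidence[l], flag[l]))
  }
  if (length(x$ties)) cat("  (tied mode at:", paste(x$ties, collapse = ", "), ")\n")
  invisible(x)
}

#' Links flagged at a confidence threshold
#'
#' @param x A `consensus_motif`.
#' @param threshold Confidence threshold in (0, 1), e.g. 0.5 or 0.8.
#' @return Named sign vector restricted to links with confidence above the
#'   threshold.
#' @export
confident_links <- function(x, threshold = 0.5) {
  stopifnot(inherits(x, "consensus_motif"))
  x$signs[x$confidence > threshold]
}

#' Confidence-weighted distance from a consensus motif to a reference
#'
#' Each link contributes `1 - confidence` when the consensus sign matches the
#' reference and `confidence` when it does not, so confidently correct links
#' contribute ~0 and confidently wrong links ~1; the total lies in `[0, 6]`.
#' At confidence 1 on every link this reduces to the Hamming distance between
#' sign vectors. The complementary "similarity" (sum of matched confidences,
#' counting `1 - confidence` on mismatches) satisfies distance + similarity =
#' 6 identically.
#'
#' @param c A `consensus_motif`.
#' @param ref The reference `signed_motif` (canonical).
#' @return Numeric distance in `[0, 6]`.
#' @export
motif_distance <- function(c, ref) {
  stopifnot(inherits(c, "consensus_motif"))
  if (!inherits(ref, "signed_motif")) ref <- signed_motif(ref)
  match <- c$signs == unclass(ref)
  sum(ifelse(match, 1 - c$confidence, c$confidence))
}

#' Monte-Carlo significance of a consensus-to-reference distance
#'
#' Compares the observed distance to the distances of random consensus graphs:
#' each link's sign is drawn uniformly from `{-1, 0, +1}` and its confidence
#' uniformly from `[1/3, 1]` (the modal fraction of three categories cannot be
#' smaller). The p-value uses the add-one correction
#' `p = (1 + #\{D_rand <= D\}) / (1 + n_random)`, so it is never exactly 0.
#'
#' @param D Observed distance (from [motif_distance]).
#' @param ref The reference `signed_motif` the distance was measured against.
#' @param n_random Number of random graphs (default 10000, minimum 100).
#' @param seed Integer seed.
#' @return A `significance_result`: list with `D`, `p_value`, `n_random`,
#'   `seed` and the sampled null distances `D_rand`.
#' @export
significance <- function(D, ref, n_random = 10000L, seed = NULL) {
  if (!inherits(ref, "signed_motif")) ref <- signed_motif(ref)
  n_random <- as.integer(n_random)
  if (n_random < 100L) stop("n_random must be at least 100")
  D_rand <- with_seed(seed, {
    signs <- matrix(sample(c(-1L, 0L, 1L), n_random * 6L, replace = TRUE),
                    ncol = 6L)
    conf <- matrix(stats::runif(n_random * 6L, 1 / 3, 1), ncol = 6L)
    match <- sweep(signs, 2L, unclass(ref), `==`)
    rowSums(ifelse(match, 1 - conf, conf))
  })
  structure(list(D = D, p_value = (1 + sum(D_rand <= D)) / (1 + n_random),
                 n_random = n_random, seed = seed, D_rand = D_rand),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat("Distance to reference D = ", signif(x$D, 4),
      ";  Monte-Carlo p = ", signif(x$p_value, 3),
      "  (", x$n_random, " random graphs",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), ")\n", sep = "")
  invisible(x)
}
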