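#' Construct a paired single-cell trace set
#'
#' Holds per-cell upstream (X) and downstream (Z) fold-change traces on a
#' shared time grid, plus the pairing between them. The pairing is a
#' permutation: cell `i`'s upstream trace is paired with the downstream trace
#' in column `pairing[i]`. For measured (or freshly simulated) data the
#' pairing is the identity; [shuffle_pairs] replaces it with a derangement.
#'
#' @param time Strictly increasing time grid (minutes).
#' @param X,Z Numeric matrices (time points x cells) of fold changes, `> 0`.
#' @param cells Optional character cell identifiers (default `cell_001`, ...).
#' @param pairing Integer permutation of the cells (default identity).
#' @param source Provenance tag: a ground-truth motif label for synthetic data
#'   or `"experimental"`.
#' @param config Optional list recording how the data were generated.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(time, X, Z, cells = NULL, pairing = NULL,
                      source = "experimental", config = NULL) {
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  attributes(X) <- list(dim = dim(X))  # drop generator metadata
  attributes(Z) <- list(dim = dim(Z))
  n <- ncol(X)
  if (length(time) < 2L || is.unsorted(time, strictly = TRUE)) {
    stop("time must be a strictly increasing grid")
  }
  if (!identical(dim(X), dim(Z))) stop("X and Z must have identical dimensions")
  if (nrow(X) != length(time)) stop("trace rows must match the time grid")
  if (any(!is.finite(X)) || any(X <= 0) || any(!is.finite(Z)) || any(Z <= 0)) {
    stop("all fold-change values must be finite and strictly positive")
  }
  if (is.null(cells)) cells <- sprintf("cell_%03d", seq_len(n))
  if (length(cells) != n || anyDuplicated(cells)) {
    stop("cells must be ", n, " unique identifiers")
  }
  if (is.null(pairing)) pairing <- seq_len(n)
  pairing <- as.integer(pairing)
  if (!identical(sort(pairing), seq_len(n))) {
    stop("pairing must be a permutation of 1..", n)
  }
  colnames(X) <- colnames(Z) <- cells
  structure(list(time = as.numeric(time), X = X, Z = Z, cells = cells,
                 pairing = pairing, source = source, config = config),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("Paired single-cell trace set (", x$source, "): ",
      length(x$cells), " cells, ", length(x$time), " time points (",
      x$time[1], "-", x$time[length(x$time)], " min)",
      if (any(x$pairing != seq_along(x$pairing))) ", shuffled pairing", "\n",
      sep = "")
  invisible(x)
}

#' @export
#' @rdname trace_set
#' @param x A `trace_set`.
n_cells <- function(x) length(x$cells)

# Downstream traces aligned to each cell's upstream trace under the current
# pairing (column i is the Z paired with X[, i]).
paired_Z <- function(ts) ts$Z[, ts$pairing, drop = FALSE]

#' Shuffle the pairing between upstream and downstream traces
#'
#' Replaces the pairing by a uniformly sampled derangement, so every cell's
#' upstream signal is matched with the downstream response of a *different*
#' cell. The traces themselves are untouched: population-mean X and Z
#' trajectories (and the multisets of traces) are exactly preserved -- only the
#' cell-level coupling is destroyed.
#'
#' @param t A `trace_set` with at least 2 cells.
#' @param seed Integer seed for the derangement draw.
#' @return A `trace_set` with a fixed-point-free pairing.
#' @export
shuffle_pairs <- function(t, seed = NULL) {
  stopifnot(inherits(t, "trace_set"))
  n <- n_cells(t)
  if (n < 2L) stop("shuffling requires at least 2 cells")
  perm <- with_seed(seed, {
    repeat {
      p <- sample.int(n)
      if (all(p != seq_len(n))) break
    }
    p
  })
  out <- t
  out$pairing <- t$pairing[perm]
  out
}

#' Cross-cell correlation of X and Z at a fixed time
#'
#' Pearson correlation, across cells, between the upstream and (paired)
#' downstream fold changes at a single query time -- the in-silico analogue of
#' staining a population for X and Z at one time point. Returned for both the
#' actual pairing and a deranged pairing; paired synthetic data show a positive
#' correlation that vanishes when the cells are shuffled.
#'
#' @param t A `trace_set`.
#' @param t_query Query time (snapped to the nearest grid sample).
#' @param seed Seed for the derangement used in the shuffled value.
#' @return List with `time` (the snapped time), `paired` and `shuffled`
#'   correlations. With zero cross-cell variance the correlation is undefined
#'   and `NA` is returned with a warning.
#' @export
fixed_time_correlation <- function(t, t_query, seed = NULL) {
  stopifnot(inherits(t, "trace_set"))
  i <- which.min(abs(t$time - t_query))
  x <- t$X[i, ]
  z <- paired_Z(t)[i, ]
  zs <- paired_Z(shuffle_pairs(t, seed = seed))[i, ]
  if (stats::sd(x) == 0 || stats::sd(z) == 0) {
    warning("zero cross-cell variance at t = ", t$time[i],
            "; correlation undefined")
    return(list(time = t$time[i], paired = NA_real_, shuffled = NA_real_))
  }
  list(time = t$time[i],
       paired = stats::cor(x, z),
       shuffled = stats::cor(x, zs))
}

#' Read and write paired trace sets as long-format CSV
#'
#' One observation per row with header `cell_id,time_min,channel,fold_change`;
#' `channel` is `X` or `Z`. On write, the downstream trace stored under each
#' `cell_id` is the one paired with that cell's upstream trace, so the realized
#' pairing round-trips as the identity. Values are serialized with 9
#' significant digits.
#'
#' Reading validates that every cell carries both channels on one shared grid
#' and that all values are positive, with row-level diagnostics.
#'
#' @param t A `trace_set`.
#' @param path CSV file path.
#' @param source Provenance tag attached to the trace set on read.
#' @return `read_traces` returns a `trace_set`; `write_traces` returns `path`
#'   invisibly.
#' @export
write_traces <- function(t, path) {
  stopifnot(inherits(t, "trace_set"))
  Zp <- paired_Z(t)
  n <- n_cells(t)
  nT <- length(t$time)
  df <- data.frame(
    cell_id = rep(rep(t$cells, each = nT), 2L),
    time_min = rep(t$time, 2L * n),
    channel = rep(c("X", "Z"), each = nT * n),
    fold_change = sprintf("%.9g", c(t$X, Zp)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path, source = "experimental") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_min", "channel", "fold_change")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!df$channel %in% c("X", "Z"))
  if (length(bad)) {
    stop("row ", bad[1] + 1L, ": channel must be X or Z, got '",
         df$channel[bad[1]], "'")
  }
  bad <- which(!is.finite(df$fold_change) | df$fold_change <= 0)
  if (length(bad)) {
    stop("row ", bad[1] + 1L, " (cell ", df$cell_id[bad[1]],
         "): fold_change must be positive and finite")
  }
  cells <- unique(df$cell_id)
  grid <- sort(unique(df$time_min))
  key <- paste(df$cell_id, df$channel)
  split_rows <- split(seq_len(nrow(df)), key)
  get_trace <- function(cell, ch) {
    rows <- split_rows[[paste(cell, ch)]]
    if (is.null(rows)) stop("cell ", cell, " is missing channel ", ch)
    rows <- rows[order(df$time_min[rows])]
    if (!isTRUE(all.equal(df$time_min[rows], grid))) {
      stop("cell ", cell, " channel ", ch,
           " is not sampled on the shared time grid (ragged grid)")
    }
    df$fold_change[rows]
  }
  X <- vapply(cells, get_trace, numeric(length(grid)), ch = "X")
  Z <- vapply(cells, get_trace, numeric(length(grid)), ch = "Z")
  trace_set(grid, X, Z, cells = cells, source = source)
}

#' Subset a trace set by cells
#'
#' @param x A `trace_set`.
#' @param i Cell indices or identifiers.
#' @param ... Unused.
#' @return A `trace_set` over the selected cells, with the pairing restricted
#'   accordingly (each retained cell keeps its paired downstream trace).
#' @export
`[.trace_set` <- function(x, i, ...) {
  idx <- if (is.character(i)) match(i, x$cells) else seq_along(x$cells)[i]
  if (anyNA(idx)) stop("unknown cells in subset")
  Zp <- paired_Z(x)[, idx, drop = FALSE]
  trace_set(x$time, x$X[, idx, drop = FALSE], Zp,
            cells = x$cells[idx], source = x$source, config = x$config)
}
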