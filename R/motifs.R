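#' @useDynLib motiftrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed link order used everywhere: signs are stored as a length-6 integer
# vector in this order. X receives no inputs, so only these six links exist.
MOTIF_LINKS <- c("XY", "XZ", "YY", "YZ", "ZY", "ZZ")
MOTIF_LINK_LABELS <- c(
  XY = "X->Y", XZ = "X->Z", YY = "Y->Y",
  YZ = "Y->Z", ZY = "Z->Y", ZZ = "Z->Z"
)

#' Construct a signed three-node motif
#'
#' A signed motif over the nodes X (measured upstream signal), Y (hidden
#' intermediate) and Z (measured downstream response) assigns each of the six
#' permitted directed links -- X->Y, X->Z, Y->Y, Y->Z, Z->Y, Z->Z -- a sign:
#' `+1` (activation), `-1` (repression) or `0` (absent). Links into X are not
#' part of the model: X is exogenous and already reports on its own dynamics.
#'
#' @param signs Integer vector of length 6 with values in `-1, 0, +1`, in the
#'   fixed link order `XY, XZ, YY, YZ, ZY, ZZ`. A named vector is reordered by
#'   name.
#' @param label Optional character label (e.g. `"IFFL"`).
#' @return An object of class `signed_motif`: a named length-6 integer vector.
#' @examples
#' signed_motif(c(XY = 1, XZ = 1, YY = 0, YZ = -1, ZY = 0, ZZ = 0), "IFFL")
#' @export
signed_motif <- function(signs, label = NULL) {
  if (length(signs) != 6L) {
    stop("a signed motif needs exactly 6 link signs (",
         paste(MOTIF_LINKS, collapse = ", "), ")")
  }
  if (!is.null(names(signs))) {
    if (!setequal(names(signs), MOTIF_LINKS)) {
      stop("link names must be exactly: ", paste(MOTIF_LINKS, collapse = ", "))
    }
    signs <- signs[MOTIF_LINKS]
  }
  if (anyNA(signs) || !all(signs %in% c(-1L, 0L, 1L))) {
    stop("link signs must be -1, 0 or +1")
  }
  signs <- as.integer(signs)
  names(signs) <- MOTIF_LINKS
  structure(signs, class = "signed_motif", label = label)
}

#' @export
print.signed_motif <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Signed motif", if (!is.null(lab)) paste0(" [", lab, "]"), ":\n", sep = "")
  sym <- c("-", ".", "+")[unclass(x) + 2L]
  cat(paste0("  ", MOTIF_LINK_LABELS, " ", sym, collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' @export
format.signed_motif <- function(x, ...) {
  paste(unclass(x), collapse = ",")
}

#' Canonicalize a raw sign assignment
#'
#' Only X and Z are observed, so two sign assignments are redundant when they
#' produce identical Z dynamics for every input and every shared-parameter
#' choice. Canonicalization applies, in order:
#'
#' 1. *Y-relevance collapse*: if Y does not feed Z (`YZ = 0`), or Y receives no
#'    input (`XY = 0` and `ZY = 0`, so Y sits at its basal fixed point forever),
#'    then Y cannot shape Z; all four Y-touching links are zeroed and the motif
#'    collapses to its two-node X/Z skeleton.
#' 2. *Triviality rejection*: if, after the collapse, X cannot influence Z
#'    (`XZ = 0` and not both `XY` and `YZ` nonzero), the structure carries no
#'    signal and is rejected.
#'
#' @param raw A `signed_motif` or a length-6 sign vector (order
#'   `XY, XZ, YY, YZ, ZY, ZZ`).
#' @return The canonical `signed_motif`, or `NULL` if the structure is trivial
#'   (X cannot influence Z).
#' @examples
#' canonicalize(c(1, 1, 0, -1, 0, 0))        # IFFL: already canonical
#' canonicalize(c(1, 1, 0, 0, 1, 0))         # Y irrelevant: collapses to X->Z
#' canonicalize(c(0, 0, 0, 0, 0, 0))         # empty: NULL
#' @export
canonicalize <- function(raw) {
  m <- if (inherits(raw, "signed_motif")) raw else signed_motif(raw)
  s <- unclass(m)
  # Y-relevance: Y must feed Z and must itself receive signal from X or Z
  if (s[["YZ"]] == 0L || (s[["XY"]] == 0L && s[["ZY"]] == 0L)) {
    s[c("XY", "YY", "YZ", "ZY")] <- 0L
  }
  # reachability: X must influence Z directly or through Y
  if (s[["XZ"]] == 0L && !(s[["XY"]] != 0L && s[["YZ"]] != 0L)) {
    return(NULL)
  }
  signed_motif(s, label = attr(m, "label"))
}

#' Enumerate all canonical signed motifs
#'
#' Walks every sign assignment over the permitted links (3 signs per link),
#' canonicalizes each, and returns the distinct canonical structures in
#' lexicographic order over the sign vector (signs ordered `-1 < 0 < +1`).
#' Over the default six-link universe this yields exactly 402 motifs from the
#' 729 raw assignments.
#'
#' @param edge_set Character vector of permitted links, a subset of
#'   `c("XY","XZ","YY","YZ","ZY","ZZ")`. Links not listed are held at 0.
#' @return A `motif_set`: a list of `signed_motif` objects with a deterministic,
#'   order-stable layout.
#' @examples
#' length(enumerate_motifs())          # 402
#' length(enumerate_motifs("XZ"))      # 2: activation and repression
#' @export
enumerate_motifs <- function(edge_set = MOTIF_LINKS) {
  if (length(edge_set) == 0L) stop("nothing to enumerate: empty edge_set")
  if (!all(edge_set %in% MOTIF_LINKS)) {
    stop("unknown links: ", paste(setdiff(edge_set, MOTIF_LINKS), collapse = ", "))
  }
  edge_set <- unique(edge_set)
  grids <- rep(list(c(-1L, 0L, 1L)), length(edge_set))
  names(grids) <- edge_set
  raw <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))

  full <- matrix(0L, nrow(raw), 6L, dimnames = list(NULL, MOTIF_LINKS))
  full[, edge_set] <- raw
  canon <- matrix(NA_integer_, nrow(raw), 6L, dimnames = list(NULL, MOTIF_LINKS))
  keep <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    m <- canonicalize(full[i, ])
    if (!is.null(m)) {
      canon[i, ] <- unclass(m)
      keep[i] <- TRUE
    }
  }
  canon <- canon[keep, , drop = FALSE]
  canon <- canon[!duplicated(canon), , drop = FALSE]
  ord <- do.call(order, lapply(seq_len(6L), function(j) canon[, j]))
  canon <- canon[ord, , drop = FALSE]
  motifs <- lapply(seq_len(nrow(canon)), function(i) signed_motif(canon[i, ]))
  structure(motifs, class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat("Set of", length(x), "canonical signed motifs\n")
  invisible(x)
}

#' Stack a motif set into a sign matrix
#'
#' @param x A `motif_set` or list of `signed_motif`s.
#' @return Integer matrix, one row per motif, columns in the fixed link order.
#' @export
motif_matrix <- function(x) {
  m <- do.call(rbind, lapply(x, unclass))
  colnames(m) <- MOTIF_LINKS
  m
}

#' Convert a motif to its heat-map column and back
#'
#' The heat-map representation of a motif is the ordered sign vector over the
#' fixed link order `XY, XZ, YY, YZ, ZY, ZZ` (rendered in figures as a column
#' of black/red/white rectangles). The two functions are inverse bijections on
#' canonical motifs.
#'
#' @param m A `signed_motif`.
#' @return `motif_to_heatcolumn`: named integer vector of length 6.
#' @examples
#' motif_to_heatcolumn(motif_library("IFFL"))  # c(1, 1, 0, -1, 0, 0)
#' @export
motif_to_heatcolumn <- function(m) {
  if (!inherits(m, "signed_motif")) m <- signed_motif(m)
  v <- unclass(m)
  attributes(v) <- list(names = MOTIF_LINKS)
  v
}

#' @rdname motif_to_heatcolumn
#' @param v Sign vector of length 6 in the fixed link order.
#' @param label Optional label for the reconstructed motif.
#' @return `heatcolumn_to_motif`: the `signed_motif`.
#' @export
heatcolumn_to_motif <- function(v, label = NULL) {
  if (length(v) != 6L) stop("heat column must have exactly 6 entries")
  signed_motif(v, label = label)
}

#' Reference library of ground-truth motifs
#'
#' Four classic three-node motifs used as simulation ground truths:
#' * `IFFL` -- incoherent feedforward loop: X activates Y and Z, Y represses Z;
#'   produces an adaptive pulse that overshoots below basal when the input ends.
#' * `cascade` -- X activates Y, Y activates Z; delays the output.
#' * `feedback` -- X activates Z, Z activates Y, Y activates Z; persistence.
#' * `CFFL` -- coherent feedforward loop: X activates Y and Z, Y activates Z;
#'   delays onset but not offset.
#'
#' @param name One of `"IFFL"`, `"cascade"`, `"feedback"`, `"CFFL"`; if missing,
#'   the whole named list is returned.
#' @return A `signed_motif`, or a named list of all four.
#' @export
motif_library <- function(name) {
  lib <- list(
    IFFL     = signed_motif(c(XY = 1, XZ = 1, YY = 0, YZ = -1, ZY = 0, ZZ = 0), "IFFL"),
    cascade  = signed_motif(c(XY = 1, XZ = 0, YY = 0, YZ = 1,  ZY = 0, ZZ = 0), "cascade"),
    feedback = signed_motif(c(XY = 0, XZ = 1, YY = 0, YZ = 1,  ZY = 1, ZZ = 0), "feedback"),
    CFFL     = signed_motif(c(XY = 1, XZ = 1, YY = 0, YZ = 1,  ZY = 0, ZZ = 0), "CFFL")
  )
  if (missing(name)) return(lib)
  if (!name %in% names(lib)) {
    stop("unknown motif '", name, "'; library: ", paste(names(lib), collapse = ", "))
  }
  lib[[name]]
}

#' Read and write motif sets as plain text
#'
#' One motif per line: the six comma-separated link signs in the fixed order
#' `XY, XZ, YY, YZ, ZY, ZZ`, optionally followed by a comma and a label.
#'
#' @param x A `motif_set` or list of `signed_motif`s.
#' @param path File path.
#' @return `read_motifs` returns a `motif_set`; `write_motifs` returns `path`
#'   invisibly.
#' @export
write_motifs <- function(x, path) {
  lines <- vapply(x, function(m) {
    lab <- attr(m, "label")
    paste(c(unclass(m), lab), collapse = ",")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_motifs
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  motifs <- lapply(lines, function(ln) {
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 6L) stop("motif line has fewer than 6 fields: ", ln)
    signs <- suppressWarnings(as.integer(parts[1:6]))
    if (anyNA(signs)) stop("non-integer sign in motif line: ", ln)
    lab <- if (length(parts) >= 7L && nzchar(parts[7])) parts[7] else NULL
    signed_motif(signs, label = lab)
  })
  structure(motifs, class = "motif_set")
}
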