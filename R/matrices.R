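#' @title Positional matrices with per-position alphabets
#'
#' @description
#' The package's positional containers store one named numeric vector per
#' position rather than a rectangular array, so each position may carry its
#' own alphabet (e.g. substitution-type strings at a mutation site, single
#' bases at the flanks). Rectangular inputs simply produce identical
#' alphabets at every position.
#'
#' Three concrete classes share this layout:
#' \describe{
#'   \item{`edl_counts`}{non-negative integer counts per (position, symbol).}
#'   \item{`edl_probs`}{per-position probability simplex vectors, plus an
#'     `effective_count` per position recording the precision of the values
#'     (the observed total for counts-derived probabilities).}
#'   \item{`edl_scores`}{signed per-symbol heights with `mode`
#'     (`"edlogo"`, `"wkl"`, `"standard"`, `"raw"`) and `centering`
#'     (`"smallest"`, `"conventional"`, `"largest"`, `"none"`) metadata.}
#' }
#'
#' Symbols are matched case-sensitively as exact strings; there is no
#' DNA/RNA aliasing (`"U"` and `"T"` are distinct), because symbols may be
#' arbitrary strings where aliasing would be unsafe.
#'
#' @name edl-matrices
NULL

check_alphabet <- function(symbols, where = "alphabet") {
  if (length(symbols) == 0L)
    stop_validation(sprintf("%s: alphabet is empty", where))
  symbols <- as.character(symbols)
  if (anyNA(symbols) || any(!nzchar(trimws(symbols))))
    stop_validation(sprintf("%s: empty or whitespace-only symbol", where))
  if (anyDuplicated(symbols))
    stop_validation(sprintf(
      "%s: duplicate symbol '%s'", where, symbols[duplicated(symbols)][1L]))
  symbols
}

# values: list of named numeric vectors, one per position (insertion order
# of names defines the alphabet order).
new_positional <- function(values, positions, class, what) {
  if (!is.list(values) || length(values) == 0L)
    stop_validation(sprintf("%s: need a non-empty list of named vectors", what))
  if (is.null(positions)) positions <- names(values)
  if (is.null(positions)) positions <- as.character(seq_along(values))
  positions <- as.character(positions)
  if (length(positions) != length(values))
    stop_validation(sprintf("%s: %d positions for %d value vectors",
                            what, length(positions), length(values)))
  if (anyDuplicated(positions))
    stop_validation(sprintf("%s: duplicate position label '%s'",
                            what, positions[duplicated(positions)][1L]))
  values <- lapply(seq_along(values), function(j) {
    v <- values[[j]]
    syms <- check_alphabet(names(v), sprintf("%s, position %s", what, positions[j]))
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop_validation(sprintf("%s, position %s: non-finite or missing value",
                              what, positions[j]))
    v <- as.numeric(v)
    names(v) <- syms
    v
  })
  names(values) <- positions
  structure(list(positions = positions, values = values),
            class = c(class, "edl_matrix"))
}

#' Construct a count matrix
#'
#' @param values A list with one named numeric vector per position (names are
#'   the symbols, in alphabet order), or a numeric matrix with symbols as row
#'   names and positions as column names.
#' @param positions Optional position labels; defaults to the list/column
#'   names, else `1..L`.
#' @return An `edl_counts` object.
#' @examples
#' count_matrix(matrix(c(3, 1, 0, 0, 0, 4), 2,
#'                     dimnames = list(c("A", "B"), NULL)))
#' @export
count_matrix <- function(values, positions = NULL) {
  if (is.matrix(values)) values <- matrix_to_list(values)
  x <- new_positional(values, positions, "edl_counts", "count matrix")
  for (j in seq_along(x$values)) {
    v <- x$values[[j]]
    if (any(v < 0))
      stop_validation(sprintf("count matrix, position %s: negative count",
                              x$positions[j]))
    r <- round(v)
    if (any(abs(v - r) > 1e-9))
      stop_validation(sprintf(
        "count matrix, position %s: non-integral count %.6g",
        x$positions[j], v[which.max(abs(v - r))]))
    x$values[[j]] <- r
  }
  x
}

#' Construct a probability matrix
#'
#' Each position's values must be non-negative and sum to 1 within `1e-6`;
#' they are renormalized to sum to exactly 1.
#'
#' @inheritParams count_matrix
#' @param effective_count Positive number (recycled per position) recording
#'   the precision of the probabilities; used when a stabilizer needs to
#'   convert probabilities back to counts. Default 1000, i.e. values trusted
#'   to about three decimal places.
#' @return An `edl_probs` object.
#' @export
probability_matrix <- function(values, positions = NULL, effective_count = 1000) {
  if (is.matrix(values)) values <- matrix_to_list(values)
  x <- new_positional(values, positions, "edl_probs", "probability matrix")
  if (any(effective_count <= 0) || anyNA(effective_count))
    stop_validation("probability matrix: effective_count must be positive")
  for (j in seq_along(x$values)) {
    v <- x$values[[j]]
    if (any(v < 0))
      stop_validation(sprintf("probability matrix, position %s: negative value",
                              x$positions[j]))
    s <- sum(v)
    if (abs(s - 1) > 1e-6)
      stop_validation(sprintf(
        "probability matrix, position %s: values sum to %.8g, not 1",
        x$positions[j], s))
    x$values[[j]] <- v / s
  }
  x$effective_count <- rep_len(as.numeric(effective_count), length(x$values))
  x
}

#' Construct a score matrix
#'
#' Signed per-symbol heights. Mostly produced by the scoring functions, but a
#' direct constructor is exported so externally derived quantities (e.g. a
#' position-specific scoring matrix) can be median-centered with
#' [median_center()].
#'
#' @inheritParams count_matrix
#' @param mode One of `"raw"`, `"edlogo"`, `"wkl"`, `"standard"`.
#' @param centering One of `"none"`, `"smallest"`, `"conventional"`,
#'   `"largest"`.
#' @return An `edl_scores` object.
#' @export
score_matrix <- function(values, positions = NULL,
                         mode = c("raw", "edlogo", "wkl", "standard"),
                         centering = c("none", "smallest", "conventional", "largest")) {
  if (is.matrix(values)) values <- matrix_to_list(values)
  if (is.numeric(values) && !is.null(names(values))) values <- list(values)
  x <- new_positional(values, positions, "edl_scores", "score matrix")
  x$mode <- match.arg(mode)
  x$centering <- match.arg(centering)
  x
}

matrix_to_list <- function(m) {
  if (is.null(rownames(m)))
    stop_validation("matrix input needs row names (symbols)")
  out <- lapply(seq_len(ncol(m)), function(j) stats::setNames(m[, j], rownames(m)))
  names(out) <- colnames(m)
  out
}

#' @export
print.edl_matrix <- function(x, ...) {
  kind <- class(x)[1L]
  cat(sprintf("<%s> %d position(s)\n", kind, length(x$positions)))
  if (!is.null(x$mode))
    cat(sprintf("  mode: %s, centering: %s\n", x$mode, x$centering))
  for (j in seq_along(x$positions)) {
    v <- x$values[[j]]
    cat(sprintf("  [%s] %s\n", x$positions[j],
                paste(sprintf("%s=%.4g", names(v), v), collapse = " ")))
  }
  invisible(x)
}

#' Position labels and per-position alphabets
#'
#' @param x A positional matrix.
#' @param position A position label (single string) for `alphabet()`.
#' @return `position_labels()` the character vector of labels;
#'   `alphabet()` the symbol order at one position.
#' @export
position_labels <- function(x) x$positions

#' @rdname position_labels
#' @export
alphabet <- function(x, position) names(position_values(x, position))

position_values <- function(x, position) {
  j <- match(as.character(position), x$positions)
  if (is.na(j))
    stop_lookup(sprintf("unknown position '%s'", position))
  x$values[[j]]
}

is_rectangular <- function(x) {
  a1 <- names(x$values[[1L]])
  all(vapply(x$values, function(v) identical(names(v), a1), logical(1)))
}

#' @method as.matrix edl_matrix
#' @export
as.matrix.edl_matrix <- function(x, ...) {
  if (!is_rectangular(x))
    stop_validation("per-position alphabets differ; no rectangular form")
  m <- vapply(x$values, identity, numeric(length(x$values[[1L]])))
  m <- matrix(m, nrow = length(x$values[[1L]]),
              dimnames = list(names(x$values[[1L]]), x$positions))
  m
}

#' @method as.data.frame edl_matrix
#' @export
as.data.frame.edl_matrix <- function(x, ...) {
  data.frame(
    position = rep(x$positions, lengths(x$values)),
    symbol = unlist(lapply(x$values, names), use.names = FALSE),
    value = unlist(x$values, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Background distributions
#'
#' A background is the reference distribution `q` against which enrichment
#' and depletion are measured. It may be the preset `"uniform"` (resolved
#' against each position's alphabet at scoring time), a single shared named
#' probability vector, or a full [probability_matrix()] aligned position by
#' position with the foreground.
#'
#' @param x `"uniform"`, a named numeric probability vector, or an
#'   `edl_probs` object.
#' @return An `edl_background` object.
#' @examples
#' background("uniform")
#' background(c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
#' @export
background <- function(x = "uniform") {
  if (inherits(x, "edl_background")) return(x)
  if (inherits(x, "edl_probs"))
    return(structure(list(kind = "matrix", matrix = x), class = "edl_background"))
  if (is.character(x) && length(x) == 1L) {
    if (x != "uniform")
      stop_validation(sprintf("unknown background preset '%s'", x))
    return(structure(list(kind = "preset", preset = "uniform"),
                     class = "edl_background"))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    check_alphabet(names(x), "background")
    if (any(x < 0)) stop_validation("background: negative probability")
    s <- sum(x)
    if (abs(s - 1) > 1e-6)
      stop_validation(sprintf("background probabilities sum to %.8g, not 1", s))
    return(structure(list(kind = "shared", vector = x / s),
                     class = "edl_background"))
  }
  stop_validation("background must be \"uniform\", a named vector, or an edl_probs")
}

#' @export
print.edl_background <- function(x, ...) {
  cat(sprintf("<edl_background> %s\n", x$kind))
  invisible(x)
}

# Align a background to the foreground's positions/alphabets; returns a list
# of named q vectors parallel to fg$positions. Positivity is *not* enforced
# here; the scoring functions reject q_i <= 0 with advice to stabilize.
resolve_background <- function(q, fg) {
  q <- background(q)
  lapply(seq_along(fg$positions), function(j) {
    syms <- names(fg$values[[j]])
    pos <- fg$positions[j]
    v <- switch(q$kind,
      preset = stats::setNames(rep(1 / length(syms), length(syms)), syms),
      shared = {
        if (!all(syms %in% names(q$vector)))
          stop_validation(sprintf(
            "background lacks symbol(s) %s required at position %s",
            paste(setdiff(syms, names(q$vector)), collapse = ", "), pos))
        w <- q$vector[syms]
        w / sum(q$vector)
      },
      matrix = {
        qv <- position_values(q$matrix, pos)
        if (!setequal(names(qv), syms))
          stop_validation(sprintf(
            "background alphabet differs from foreground at position %s", pos))
        qv[syms]
      })
    names(v) <- syms
    v
  })
}

#' Convert counts to maximum-likelihood probabilities
#'
#' The ML estimate of the symbol probability at a position is its count
#' divided by the position total `m`; the position total becomes that
#' position's `effective_count` unless overridden.
#'
#' @param counts An `edl_counts` object.
#' @param effective_count Optional positive number overriding the recorded
#'   precision.
#' @return An `edl_probs` object.
#' @examples
#' cm <- count_matrix(list(`1` = c(A = 33, C = 33, G = 33, T = 1)))
#' normalize_counts(cm)
#' @export
normalize_counts <- function(counts, effective_count = NULL) {
  stopifnot(inherits(counts, "edl_counts"))
  totals <- vapply(counts$values, sum, numeric(1))
  if (any(totals <= 0))
    stop_validation(sprintf(
      "position %s has zero total count; cannot normalize",
      counts$positions[which(totals <= 0)[1L]]))
  vals <- lapply(seq_along(counts$values), function(j) counts$values[[j]] / totals[j])
  names(vals) <- counts$positions
  ec <- if (is.null(effective_count)) totals else {
    if (any(effective_count <= 0))
      stop_validation("effective_count override must be positive")
    rep_len(effective_count, length(totals))
  }
  probability_matrix(vals, counts$positions, effective_count = ec)
}
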