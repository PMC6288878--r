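# Readers and writers for delimited count/probability/score tables, JASPAR
# position frequency matrices, and FASTA sequence sets.
#
# Delimited dialect: field separator auto-detected from the header line (tab
# if present, else comma); lines starting with "#" are comments. Rectangular
# tables carry symbols on one axis and position labels on the other; a
# three-column long table (position, symbol, value) is recognized by its
# header and supports per-position alphabets.

read_clean_lines <- function(source) {
  lines <- if (length(source) > 1L || grepl("\n", source[1], fixed = TRUE)) {
    unlist(strsplit(source, "\n", fixed = TRUE))
  } else readLines(source, warn = FALSE)
  lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
}

detect_sep <- function(header) if (grepl("\t", header, fixed = TRUE)) "\t" else ","

parse_delimited <- function(source, what) {
  lines <- read_clean_lines(source)
  if (length(lines) < 2L)
    stop_format(sprintf("%s: need a header line and at least one data row", what))
  sep <- detect_sep(lines[1L])
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop_format(sprintf("%s: ragged table (row widths %s)", what,
                        paste(unique(widths), collapse = ", ")))
  m <- do.call(rbind, cells)
  m[] <- trimws(m)
  m
}

cells_to_numeric <- function(x, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v))
    stop_format(sprintf("%s: non-numeric cell '%s'", what, x[which(is.na(v))[1L]]))
  v
}

# Long layout: header is (position, symbol, <value column>).
is_long_table <- function(m) {
  ncol(m) == 3L && tolower(m[1L, 1L]) == "position" && tolower(m[1L, 2L]) == "symbol"
}

long_to_values <- function(m, what) {
  pos <- m[-1L, 1L]
  sym <- m[-1L, 2L]
  val <- cells_to_numeric(m[-1L, 3L], what)
  labels <- unique(pos)
  vals <- lapply(labels, function(p) {
    i <- pos == p
    if (anyDuplicated(sym[i]))
      stop_validation(sprintf("%s: duplicate symbol at position %s", what, p))
    stats::setNames(val[i], sym[i])
  })
  names(vals) <- labels
  vals
}

rect_to_values <- function(m, orientation, what) {
  if (orientation == "rows-are-positions") {
    m <- t(m)
    m[1L, 1L] <- ""
  }
  syms <- m[-1L, 1L]
  labels <- m[1L, -1L]
  if (anyDuplicated(syms))
    stop_validation(sprintf("%s: duplicate symbol row '%s'",
                            what, syms[duplicated(syms)][1L]))
  body <- m[-1L, -1L, drop = FALSE]
  vals <- lapply(seq_along(labels), function(j)
    stats::setNames(cells_to_numeric(body[, j], what), syms))
  names(vals) <- labels
  vals
}

#' Read a delimited count table
#'
#' @param source Path to a file, or a character vector of lines.
#' @param orientation `"rows-are-symbols"` (default; columns are positions)
#'   or `"rows-are-positions"`. Ignored for long-format tables whose header
#'   is `position, symbol, count`.
#' @return An `edl_counts` object. Cells must be integral after rounding at
#'   `1e-9`; negative cells and duplicate symbols are rejected.
#' @export
read_count_table <- function(source,
                             orientation = c("rows-are-symbols", "rows-are-positions")) {
  orientation <- match.arg(orientation)
  m <- parse_delimited(source, "count table")
  vals <- if (is_long_table(m)) long_to_values(m, "count table")
          else rect_to_values(m, orientation, "count table")
  count_matrix(vals)
}

#' Read a delimited probability table
#'
#' @inheritParams read_count_table
#' @param effective_count Precision proxy attached to the probabilities
#'   (default 1000: trusted to about three decimal places).
#' @return An `edl_probs` object; each position is renormalized to sum to 1.
#' @export
read_probability_table <- function(source,
                                   orientation = c("rows-are-symbols", "rows-are-positions"),
                                   effective_count = 1000) {
  orientation <- match.arg(orientation)
  m <- parse_delimited(source, "probability table")
  vals <- if (is_long_table(m)) long_to_values(m, "probability table")
          else rect_to_values(m, orientation, "probability table")
  vals <- lapply(vals, function(v) {
    if (any(v < 0)) stop_validation("probability table: negative value")
    if (sum(v) <= 0) stop_validation("probability table: position sums to zero")
    v / sum(v)
  })
  probability_matrix(vals, effective_count = effective_count)
}

#' Read a background vector or matrix
#'
#' A two-column table (`symbol`, `prob`) gives a shared background vector; a
#' rectangular or long probability table gives a position-specific
#' background.
#'
#' @inheritParams read_count_table
#' @return An `edl_background` object.
#' @export
read_background <- function(source) {
  m <- parse_delimited(source, "background")
  if (ncol(m) == 2L && !is_long_table(m)) {
    syms <- m[-1L, 1L]
    v <- cells_to_numeric(m[-1L, 2L], "background")
    return(background(stats::setNames(v / sum(v), syms)))
  }
  background(read_probability_table(m_to_lines(m)))
}

m_to_lines <- function(m) apply(m, 1L, paste, collapse = "\t")

#' Read a JASPAR-style position frequency matrix
#'
#' Expects a header line starting with `>`, then one line per base of the
#' form `A [ 3 0 5 ... ]` (brackets optional), bases in file order. Positions
#' are labeled `1..L`.
#'
#' @param source Path to a file, or a character vector of lines.
#' @return An `edl_counts` object with the file's base order as alphabet.
#' @export
read_jaspar_pfm <- function(source) {
  lines <- read_clean_lines(source)
  if (length(lines) == 0L || !startsWith(lines[1L], ">"))
    stop_format("JASPAR PFM: missing '>' header line")
  rows <- lines[-1L]
  if (length(rows) < 4L)
    stop_format(sprintf("JASPAR PFM: expected 4 base rows, found %d", length(rows)))
  syms <- character(0)
  vals <- list()
  for (ln in rows[seq_len(4L)]) {
    mt <- regmatches(ln, regexec("^\\s*(\\S+)\\s+(.*)$", ln))[[1L]]
    rest <- if (length(mt) == 3L) trimws(gsub("[][]", " ", mt[3L])) else ""
    if (!nzchar(rest))
      stop_format(sprintf("JASPAR PFM: cannot parse row '%s'", ln))
    syms <- c(syms, mt[2L])
    vals <- c(vals, list(cells_to_numeric(strsplit(rest, "\\s+")[[1L]],
                                          "JASPAR PFM")))
  }
  if (!setequal(syms, c("A", "C", "G", "T")))
    stop_format(sprintf("JASPAR PFM: base rows are (%s), expected A, C, G, T",
                        paste(syms, collapse = ", ")))
  L <- unique(lengths(vals))
  if (length(L) != 1L)
    stop_format("JASPAR PFM: unequal row lengths")
  counts <- lapply(seq_len(L), function(j)
    stats::setNames(vapply(vals, `[[`, numeric(1), j), syms))
  count_matrix(counts, positions = as.character(seq_len(L)))
}

#' Count symbols per column of an aligned sequence set
#'
#' Reads FASTA (or takes a character vector of equal-length sequences),
#' tokenizes each sequence into one symbol per column, and counts symbols at
#' each column. The alphabet at each position is the set of tokens observed
#' there, in order of first appearance, so per-position totals equal the
#' number of sequences.
#'
#' @param seqs Path to a FASTA file, or a character vector of sequences.
#' @param tokenizer `"single-char"` (default) or `"delimiter"` for sequences
#'   whose symbols are multi-character strings joined by `delimiter`.
#' @param delimiter Token separator for the delimiter tokenizer.
#' @return An `edl_counts` object.
#' @examples
#' counts_from_sequences(c("NAS", "NGS", "NAT"))
#' @export
counts_from_sequences <- function(seqs, tokenizer = c("single-char", "delimiter"),
                                  delimiter = ",") {
  tokenizer <- match.arg(tokenizer)
  if (length(seqs) == 1L && file.exists(seqs)) {
    ss <- Biostrings::readBStringSet(seqs)
    seqs <- as.character(ss)
  }
  seqs <- as.character(seqs)
  if (length(seqs) == 0L)
    stop_validation("no sequences supplied")
  toks <- if (tokenizer == "single-char") strsplit(seqs, "", fixed = TRUE)
          else strsplit(seqs, delimiter, fixed = TRUE)
  L <- unique(lengths(toks))
  if (length(L) != 1L)
    stop_validation(sprintf("sequences have unequal lengths (%s)",
                            paste(sort(L), collapse = ", ")))
  if (L == 0L) stop_validation("sequences are empty")
  counts <- lapply(seq_len(L), function(j) {
    col <- vapply(toks, `[[`, character(1), j)
    lev <- unique(col)
    stats::setNames(as.numeric(table(factor(col, levels = lev))), lev)
  })
  count_matrix(counts, positions = as.character(seq_len(L)))
}

#' Write a positional matrix to a delimited file
#'
#' Matrices with one shared alphabet are written as a rectangular
#' tab-separated table (symbols as rows, positions as columns); matrices with
#' per-position alphabets are written in long format (`position`, `symbol`,
#' `value`). Score matrices carry their mode and centering in `#` comment
#' lines, which [read_score_table()] restores.
#'
#' @param x An `edl_counts`, `edl_probs` or `edl_scores` object.
#' @param file Path to write; a character vector of lines is returned
#'   invisibly either way.
#' @export
write_matrix <- function(x, file = NULL) {
  stopifnot(inherits(x, "edl_matrix"))
  header <- character(0)
  if (inherits(x, "edl_scores"))
    header <- c(sprintf("# mode: %s", x$mode),
                sprintf("# centering: %s", x$centering))
  if (is_rectangular(x)) {
    m <- as.matrix(x)
    body <- c(paste(c("symbol", colnames(m)), collapse = "\t"),
              vapply(seq_len(nrow(m)), function(i)
                paste(c(rownames(m)[i], format_num(m[i, ])), collapse = "\t"),
                character(1)))
  } else {
    df <- as.data.frame(x)
    body <- c("position\tsymbol\tvalue",
              sprintf("%s\t%s\t%s", df$position, df$symbol, format_num(df$value)))
  }
  lines <- c(header, body)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

format_num <- function(v) {
  out <- vapply(v, function(z) {
    if (z == round(z) && abs(z) < 1e15) sprintf("%d", as.integer(round(z)))
    else sprintf("%.12g", z)
  }, character(1))
  out
}

#' Read a score table written by [write_matrix()]
#'
#' @inheritParams read_count_table
#' @return An `edl_scores` object with mode/centering restored from the
#'   comment header (defaulting to raw/none when absent).
#' @export
read_score_table <- function(source,
                             orientation = c("rows-are-symbols", "rows-are-positions")) {
  orientation <- match.arg(orientation)
  raw <- if (length(source) > 1L || grepl("\n", source[1], fixed = TRUE)) {
    unlist(strsplit(source, "\n", fixed = TRUE))
  } else readLines(source, warn = FALSE)
  mode <- sub("^# mode:\\s*", "", grep("^# mode:", raw, value = TRUE))
  centering <- sub("^# centering:\\s*", "", grep("^# centering:", raw, value = TRUE))
  m <- parse_delimited(raw, "score table")
  vals <- if (is_long_table(m)) long_to_values(m, "score table")
          else rect_to_values(m, orientation, "score table")
  score_matrix(vals,
               mode = if (length(mode)) mode[1L] else "raw",
               centering = if (length(centering)) centering[1L] else "none")
}
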