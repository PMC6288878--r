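#' @title Enrichment-depletion scoring
#'
#' @description
#' At one position, let `p = (p_1, ..., p_n)` be the probabilities of the
#' `n` permitted symbols and `q` the corresponding background probabilities.
#' The raw enrichment of symbol `i` is the log ratio
#' `rtilde_i = log2(p_i / q_i)`; the plotted height is the median-centered
#' value `r_i = rtilde_i - median(rtilde)`. Subtracting the median makes the
#' stack as short as possible: among all height vectors of the form
#' `log2(p/q) + k` (the constant `k` is unidentifiable because only ratios
#' matter), the median-centered one minimizes the total stack height
#' `sum(|r_i|)` — the most parsimonious picture of the position.
#'
#' With an even number of symbols every centering constant between the two
#' central order statistics achieves the same minimal stack height, so three
#' centering rules are offered: `"smallest"` (lower central order statistic;
#' favors an enrichment reading, the default), `"conventional"` (their mean;
#' preserves the mirror symmetry between `p`-vs-`q` and `q`-vs-`p` plots) and
#' `"largest"` (upper central order statistic; favors a depletion reading).
#'
#' @name edlogo-scoring
NULL

center_rules <- c("smallest", "conventional", "largest")

# Centering constant for one position: the middle order statistic when n is
# odd; for even n, an endpoint or the midpoint of the closed interval of
# minimizers [s_(n/2), s_(n/2+1)].
center_constant <- function(v, rule) {
  n <- length(v)
  s <- sort(v)
  if (n %% 2L == 1L) return(s[(n + 1L) %/% 2L])
  lo <- s[n %/% 2L]
  hi <- s[n %/% 2L + 1L]
  switch(rule, smallest = lo, conventional = (lo + hi) / 2, largest = hi)
}

#' Raw log2 enrichment ratios
#'
#' Computes `rtilde_i = log2(p_i / q_i)` per (position, symbol). Zeros in
#' either `p` or `q` are rejected: stabilize the estimates first (see
#' [pseudocount_probs()] or [eb_shrink_log_ratios()]).
#'
#' @param p An `edl_probs` foreground.
#' @param q A [background()]: `"uniform"`, a named vector, or an `edl_probs`.
#' @return An `edl_scores` object with `mode = "raw"`, `centering = "none"`.
#' @examples
#' p <- probability_matrix(list(`1` = c(A = 0.33, C = 0.33, G = 0.33, T = 0.01)))
#' log_ratios(p, "uniform")
#' @export
log_ratios <- function(p, q = "uniform") {
  stopifnot(inherits(p, "edl_probs"))
  qs <- resolve_background(q, p)
  vals <- lapply(seq_along(p$positions), function(j) {
    pv <- p$values[[j]]
    qv <- qs[[j]]
    bad_q <- which(qv <= 0)
    if (length(bad_q))
      stop_domain(sprintf(
        "background probability is 0 at position %s, symbol %s; stabilize (pseudocounts or EB shrinkage) before scoring",
        p$positions[j], names(qv)[bad_q[1L]]))
    bad_p <- which(pv <= 0)
    if (length(bad_p))
      stop_domain(sprintf(
        "foreground probability is 0 at position %s, symbol %s; stabilize (pseudocounts or EB shrinkage) before scoring",
        p$positions[j], names(pv)[bad_p[1L]]))
    log2(pv / qv)
  })
  names(vals) <- p$positions
  score_matrix(vals, p$positions, mode = "raw", centering = "none")
}

#' Median-center a score matrix
#'
#' Subtracts, per position, the centering constant of the chosen rule. This
#' applies to any score matrix, including externally derived quantities such
#' as a position-specific scoring matrix, so existing PSSMs can be
#' de-cluttered the same way.
#'
#' @param scores An `edl_scores` object.
#' @param rule `"smallest"`, `"conventional"` or `"largest"` (see
#'   [edlogo-scoring]).
#' @return The centered `edl_scores`, with `centering` set to `rule`.
#' @examples
#' s <- score_matrix(list(`1` = c(A = 0, B = 0, C = 1, D = 1)))
#' median_center(s, "conventional")
#' @export
median_center <- function(scores, rule = c("smallest", "conventional", "largest")) {
  stopifnot(inherits(scores, "edl_scores"))
  rule <- match.arg(rule)
  scores$values <- lapply(scores$values, function(v) v - center_constant(v, rule))
  names(scores$values) <- scores$positions
  scores$centering <- rule
  scores
}

#' Enrichment-depletion logo scores
#'
#' The full scoring pipeline: raw log2 ratios then median centering.
#'
#' @inheritParams log_ratios
#' @inheritParams median_center
#' @return An `edl_scores` object with `mode = "edlogo"`.
#' @examples
#' p <- probability_matrix(list(`1` = c(A = 0.33, C = 0.33, G = 0.33, T = 0.01)))
#' edlogo_scores(p, "uniform", rule = "conventional")
#' @export
edlogo_scores <- function(p, q = "uniform",
                          rule = c("smallest", "conventional", "largest")) {
  rule <- match.arg(rule)
  s <- median_center(log_ratios(p, q), rule)
  s$mode <- "edlogo"
  s
}

#' Total stack height at a position
#'
#' The sum of absolute heights, i.e. the total amount of ink the position
#' receives; median centering minimizes it.
#'
#' @param scores An `edl_scores` object.
#' @param position A position label; `NULL` returns the named vector over
#'   all positions.
#' @return Non-negative number (or named vector).
#' @export
stack_height <- function(scores, position = NULL) {
  stopifnot(inherits(scores, "edl_scores"))
  if (is.null(position))
    return(vapply(stats::setNames(scores$positions, scores$positions),
                  function(p) sum(abs(position_values(scores, p))), numeric(1)))
  sum(abs(position_values(scores, position)))
}

#' Standard information-content logo scores
#'
#' Classic Schneider-Stephens heights: each symbol's height is its relative
#' frequency times the position's information content
#' `IC = log2(n_ref) + sum(p_i * log2(p_i))` (bits, with `0 log 0 = 0`).
#'
#' @inheritParams log_ratios
#' @param n_ref Reference alphabet size for the uniform baseline; defaults to
#'   each position's own alphabet size. Must be at least 2.
#' @return An `edl_scores` object with `mode = "standard"`; all heights are
#'   non-negative and sum to the information content.
#' @export
standard_logo_scores <- function(p, n_ref = NULL) {
  stopifnot(inherits(p, "edl_probs"))
  if (!is.null(n_ref) && n_ref < 2)
    stop_validation("n_ref must be at least 2")
  vals <- lapply(p$values, function(pv) {
    nr <- if (is.null(n_ref)) length(pv) else n_ref
    plogp <- ifelse(pv > 0, pv * log2(pv), 0)
    ic <- log2(nr) + sum(plogp)
    pv * ic
  })
  names(vals) <- p$positions
  score_matrix(vals, p$positions, mode = "standard", centering = "none")
}

#' Weighted Kullback-Leibler logo scores
#'
#' Signed heights `p_i * log2(p_i / q_i)` (with `0` mapped to `0`): each
#' symbol's contribution to the KL divergence between foreground and
#' background, negative for depleted symbols. Provided for comparison with
#' the enrichment-depletion logo; its stacks show every deviating symbol and
#' are typically busier.
#'
#' @inheritParams log_ratios
#' @return An `edl_scores` object with `mode = "wkl"`.
#' @export
wkl_scores <- function(p, q = "uniform") {
  stopifnot(inherits(p, "edl_probs"))
  qs <- resolve_background(q, p)
  vals <- lapply(seq_along(p$positions), function(j) {
    pv <- p$values[[j]]
    qv <- qs[[j]]
    bad <- which(qv <= 0)
    if (length(bad))
      stop_domain(sprintf("background probability is 0 at position %s, symbol %s",
                          p$positions[j], names(qv)[bad[1L]]))
    ifelse(pv > 0, pv * log2(pv / qv), 0)
  })
  names(vals) <- p$positions
  score_matrix(vals, p$positions, mode = "wkl", centering = "none")
}

#' Log-odds ratio between two symbols
#'
#' The difference in plotted heights of two symbols at one position equals
#' the log-odds ratio `log2((p_a / p_b) / (q_a / q_b))`, whatever centering
#' rule was used — the centering constant cancels. This makes height
#' differences in the plot directly interpretable.
#'
#' @param scores An `edl_scores` object (edlogo or raw mode).
#' @param position Position label.
#' @param symbol_a,symbol_b Symbols at that position.
#' @return The height difference `r_a - r_b`.
#' @export
log_odds <- function(scores, position, symbol_a, symbol_b) {
  stopifnot(inherits(scores, "edl_scores"))
  v <- position_values(scores, position)
  for (s in c(symbol_a, symbol_b))
    if (!s %in% names(v))
      stop_lookup(sprintf("symbol '%s' not in alphabet at position %s", s, position))
  unname(v[[symbol_a]] - v[[symbol_b]])
}
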