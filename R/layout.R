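#' Resolve a score matrix into glyph boxes
#'
#' Converts signed heights into a deterministic set of glyph boxes. At each
#' position, symbols with positive height are stacked upward from the axis
#' and symbols with negative height downward, each box exactly `|r_i|` tall;
#' reading the whole stack bottom-to-top gives symbols in order of
#' increasing height, so the largest glyphs sit furthest from the axis.
#' Symbols with height 0 (within `1e-12`) are not drawn. Ties are broken by
#' alphabet order, the earlier symbol nearer the axis.
#'
#' Position slots are centered on integer x = 0..L-1; each box spans the
#' slot shrunk by `gap` (a fraction of the unit slot width) on each side.
#'
#' @param scores An `edl_scores` object with finite values.
#' @param gap Horizontal gap fraction per side (default 0.05).
#' @return A `logo_layout`: a data frame with one row per drawn box and
#'   columns `position` (label), `slot` (0-based x slot), `symbol`, `x0`,
#'   `x1`, `y0`, `y1`, `side` (`"above"`/`"below"`), `rank` (1 = bottom of
#'   the stack), and the attributes `mode` and `centering` of the scores.
#' @examples
#' s <- score_matrix(list(`1` = c(A = 0.4, C = -1.2, G = 0.4, T = 0.1)))
#' logo_layout(s)
#' @export
logo_layout <- function(scores, gap = 0.05) {
  stopifnot(inherits(scores, "edl_scores"))
  if (!is.numeric(gap) || gap < 0 || gap >= 0.5)
    stop_validation("gap must be in [0, 0.5)")
  rows <- list()
  for (j in seq_along(scores$positions)) {
    v <- scores$values[[j]]
    if (any(!is.finite(v)))
      stop_validation(sprintf("non-finite score at position %s",
                              scores$positions[j]))
    keep <- abs(v) > 1e-12
    if (!any(keep)) next
    r <- v[keep]
    idx <- seq_along(v)[keep]  # alphabet index for tie-breaks
    neg <- r < 0
    # Bottom-to-top = ascending r. Ties: nearer the axis means *later* in
    # the below-axis run but *earlier* in the above-axis run.
    ord_neg <- order(r[neg], -idx[neg])
    ord_pos <- order(r[!neg], idx[!neg])
    sym_sorted <- c(names(r)[neg][ord_neg], names(r)[!neg][ord_pos])
    r_sorted <- c(r[neg][ord_neg], r[!neg][ord_pos])
    ylo <- -sum(abs(r_sorted[r_sorted < 0]))
    y0 <- ylo + cumsum(c(0, abs(r_sorted[-length(r_sorted)])))
    y1 <- y0 + abs(r_sorted)
    rows[[length(rows) + 1L]] <- data.frame(
      position = scores$positions[j],
      slot = j - 1L,
      symbol = sym_sorted,
      x0 = (j - 1L) - 0.5 + gap,
      x1 = (j - 1L) + 0.5 - gap,
      y0 = y0, y1 = y1,
      side = ifelse(r_sorted < 0, "below", "above"),
      rank = seq_along(r_sorted),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    position = character(0), slot = integer(0), symbol = character(0),
    x0 = numeric(0), x1 = numeric(0), y0 = numeric(0), y1 = numeric(0),
    side = character(0), rank = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mode") <- scores$mode
  attr(out, "centering") <- scores$centering
  attr(out, "positions") <- scores$positions
  class(out) <- c("logo_layout", "data.frame")
  out
}
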