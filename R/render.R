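# Deterministic SVG rendering of a logo layout.
#
# The serializer writes every element itself with fixed number formatting
# and no timestamps or random ids, so two renders of the same layout and
# style are byte-identical. Glyphs are <text> elements scaled non-uniformly
# into their boxes via explicit transforms computed from fixed nominal
# metrics (glyph width 0.6 em per character, cap height 0.72 em), which
# keeps the geometry independent of the viewer's font metrics.

default_style <- function() {
  list(
    slot_px = 80,            # pixels per position slot
    height_px = 360,         # plot area height in pixels
    margin_left = 56, margin_right = 12,
    margin_top = 14, margin_bottom = 34,
    font_family = "sans-serif",
    palette = c("#109648", "#255C99", "#F7B32B", "#D62839",
                "#7B4B94", "#1B998B", "#E4572E", "#6C6EA0"),
    below_opacity = 1,       # optional dimming of depletion glyphs
    axis_color = "#222222",
    background = "#FFFFFF",
    max_stretch = 8          # cap on vertical stretch relative to uniform fit
  )
}

style_options <- function(style = list()) {
  base <- default_style()
  unknown <- setdiff(names(style), names(base))
  if (length(unknown))
    stop_validation(sprintf("unknown style option(s): %s",
                            paste(unknown, collapse = ", ")))
  utils::modifyList(base, style)
}

fmt <- function(x) sprintf("%.3f", x)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

y_axis_label <- function(mode) {
  switch(mode,
         standard = "Information content (bits)",
         "Enrichment score (log2)")
}

#' Render a logo layout to SVG
#'
#' Writes a standalone SVG document: an x axis at score 0 with one tick per
#' position (labeled with the position labels), a labeled y axis in the
#' scoring mode's units, and one glyph per layout box. Single-character and
#' string symbols are both supported: text is uniformly scaled to fit the
#' box width, then stretched vertically to the box height, with the stretch
#' capped at `max_stretch` times the uniform scale (beyond the cap the glyph
#' is vertically centered in its box) so long strings in shallow boxes stay
#' legible. Output is deterministic: identical inputs give byte-identical
#' files.
#'
#' @param layout A [logo_layout()].
#' @param file Output path; omit to just get the SVG text.
#' @param style Named list of style overrides (unknown keys are an error):
#'   `slot_px`, `height_px`, margins, `font_family`, `palette`,
#'   `below_opacity`, `axis_color`, `background`, `max_stretch`.
#' @return The SVG document as a character vector of lines, invisibly when
#'   `file` is given.
#' @export
render_svg <- function(layout, file = NULL, style = list()) {
  stopifnot(inherits(layout, "logo_layout"))
  st <- style_options(style)
  positions <- attr(layout, "positions")
  L <- max(length(positions), 1L)
  mode <- attr(layout, "mode") %||% "raw"

  ymax <- max(layout$y1, 0)
  ymin <- min(layout$y0, 0)
  if (ymax == ymin) { ymax <- 1; ymin <- -1 }
  pad <- 0.04 * (ymax - ymin)
  ymax <- ymax + pad
  ymin <- ymin - pad

  W <- st$margin_left + L * st$slot_px + st$margin_right
  H <- st$margin_top + st$height_px + st$margin_bottom
  sx <- function(x) st$margin_left + (x + 0.5) * st$slot_px
  sy <- function(y) st$margin_top + (ymax - y) / (ymax - ymin) * st$height_px

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt(W), fmt(H), fmt(W), fmt(H)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="%s"/>',
            fmt(W), fmt(H), st$background)
  )

  # y axis, ticks, label
  ticks <- pretty(c(ymin, ymax), n = 6)
  ticks <- ticks[ticks >= ymin & ticks <= ymax]
  ax <- st$margin_left - 6
  out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
                        fmt(ax), fmt(sy(ymin)), fmt(ax), fmt(sy(ymax)), st$axis_color))
  for (t in ticks) {
    out <- c(out,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
              fmt(ax - 4), fmt(sy(t)), fmt(ax), fmt(sy(t)), st$axis_color),
      sprintf('<text x="%s" y="%s" font-family="%s" font-size="11" text-anchor="end" dominant-baseline="middle" fill="%s">%s</text>',
              fmt(ax - 7), fmt(sy(t)), st$font_family, st$axis_color, fmt2(t)))
  }
  out <- c(out, sprintf(
    '<text x="%s" y="%s" font-family="%s" font-size="12" text-anchor="middle" fill="%s" transform="rotate(-90 %s %s)">%s</text>',
    fmt(14), fmt(sy((ymin + ymax) / 2)), st$font_family, st$axis_color,
    fmt(14), fmt(sy((ymin + ymax) / 2)), xml_escape(y_axis_label(mode))))

  # x axis at score 0 and position tick labels
  out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
                        fmt(st$margin_left), fmt(sy(0)),
                        fmt(st$margin_left + L * st$slot_px), fmt(sy(0)),
                        st$axis_color))
  for (k in seq_along(positions)) {
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="%s" font-size="12" text-anchor="middle" fill="%s">%s</text>',
      fmt(sx(k - 1)), fmt(st$margin_top + st$height_px + 16), st$font_family,
      st$axis_color, xml_escape(positions[k])))
  }

  # glyph boxes
  pal <- st$palette
  sym_levels <- unique(layout$symbol)
  col_of <- function(s) pal[(match(s, sym_levels) - 1L) %% length(pal) + 1L]
  if (nrow(layout)) for (i in seq_len(nrow(layout))) {
    b <- layout[i, ]
    bw <- (b$x1 - b$x0) * st$slot_px
    bh <- abs(sy(b$y1) - sy(b$y0))
    cx <- sx((b$x0 + b$x1) / 2)
    nc <- max(nchar(b$symbol), 1L)
    gw <- 0.60 * nc            # nominal text width at font-size 1
    gh <- 0.72                 # nominal cap height at font-size 1
    u <- bw / gw               # uniform scale fitting the box width
    v <- bh / gh               # stretch filling the box height
    centered <- FALSE
    if (v > st$max_stretch * u) { v <- st$max_stretch * u; centered <- TRUE }
    glyph_h <- v * gh
    y_bottom <- if (centered) (sy(b$y1) + bh / 2 + glyph_h / 2) else sy(b$y0)
    opacity <- if (b$side == "below" && st$below_opacity < 1)
      sprintf(' opacity="%s"', fmt(st$below_opacity)) else ""
    out <- c(out, sprintf(
      '<text transform="translate(%s %s) scale(%s %s)" font-family="%s" font-size="1" font-weight="bold" text-anchor="middle" fill="%s"%s>%s</text>',
      fmt(cx), fmt(y_bottom), fmt(u), fmt(v), st$font_family,
      col_of(b$symbol), opacity, xml_escape(b$symbol)))
  }

  out <- c(out, "</svg>")
  if (!is.null(file)) {
    writeLines(out, file, sep = "\n")
    return(invisible(out))
  }
  out
}

fmt2 <- function(x) {
  s <- sprintf("%.2f", x)
  sub("^(-?\\d+)\\.00$", "\\1", s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
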