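#' One-call logo pipeline
#'
#' Convenience wrapper running stabilization, scoring, layout and
#' (optionally) SVG rendering in one step.
#'
#' @param x Foreground: an `edl_counts` or `edl_probs`.
#' @param bg A [background()] (default uniform), `edl_probs` or `edl_counts`.
#' @param score `"edlogo"`, `"standard"` or `"wkl"`.
#' @param rule Centering rule for edlogo scores (default `"smallest"`, the
#'   enrichment-flavored software default; use `"conventional"` for the
#'   mirror-symmetric plot).
#' @param stabilize `"none"`, `"pseudocount"` or `"eb"`.
#' @param config A [stabilizer_config()]; built from `stabilize` when
#'   omitted.
#' @param file Optional SVG output path.
#' @param style Style overrides for [render_svg()].
#' @return A list with `scores`, `layout` and `svg` (character lines).
#' @examples
#' ex <- edlogo_examples()
#' res <- edlogo_plot(ex$dna_probs, rule = "conventional")
#' res$layout
#' @export
edlogo_plot <- function(x, bg = "uniform",
                        score = c("edlogo", "standard", "wkl"),
                        rule = c("smallest", "conventional", "largest"),
                        stabilize = c("none", "pseudocount", "eb"),
                        config = NULL, file = NULL, style = list()) {
  score <- match.arg(score)
  rule <- match.arg(rule)
  stabilize <- match.arg(stabilize)
  if (is.null(config)) config <- stabilizer_config(stabilize)

  scores <- if (score == "edlogo") {
    stabilized_edlogo(x, bg, config, rule)
  } else {
    p <- stabilized_probs(x, config)
    qb <- stabilized_query_background(bg, x, config)
    if (score == "standard") standard_logo_scores(p) else wkl_scores(p, qb)
  }
  lay <- logo_layout(scores)
  svg <- render_svg(lay, file = file, style = style)
  list(scores = scores, layout = lay, svg = svg)
}

# Probabilities for the comparison logos under the chosen stabilizer.
stabilized_probs <- function(x, config) {
  if (inherits(x, "edl_probs")) {
    if (config$method == "none") return(x)
    x <- probs_to_counts(x)
  }
  switch(config$method,
         none = normalize_counts(x),
         pseudocount = pseudocount_probs(x, config$pseudocount),
         eb = pseudocount_probs(x, config$pseudocount))
}

stabilized_query_background <- function(bg, fg, config) {
  if (config$method == "none") return(as_prob_background(bg))
  fgc <- if (inherits(fg, "edl_probs")) probs_to_counts(fg) else fg
  pseudocount_background(bg, fgc, config)
}
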