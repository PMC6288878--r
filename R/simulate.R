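#' Specify a synthetic positional count data set
#'
#' Describes how to construct a ground-truth foreground distribution and
#' sample counts from it, for testing estimator behavior with a known
#' answer. The foreground at each position starts from the background `q`
#' and applies the requested log2 effects: `p  propto  q * 2^effect`, so the
#' true raw score of a symbol with effect `e` (before centering) is
#' `e - log2(sum(q * 2^effect))`. Alternatively a Dirichlet draw around `q`
#' can be requested via `concentration`.
#'
#' @param n_positions Number of positions.
#' @param alphabet Symbols shared by every position (character vector), or a
#'   list of per-position alphabets.
#' @param depth Sequencing depth `m`: counts per position (single number or
#'   per-position vector). Must be positive.
#' @param background `"uniform"`, a named probability vector, or an
#'   `edl_probs`.
#' @param effects Optional data frame with columns `position`, `symbol`,
#'   `log2fc` giving designated enriched (positive) or depleted (negative)
#'   symbols.
#' @param concentration Optional Dirichlet concentration; when given, `p` at
#'   each position is drawn as `Dirichlet(concentration * n * q)` before
#'   effects are applied.
#' @param seed Integer seed; generation is reproducible from the spec alone.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_positions, alphabet, depth,
                           background = "uniform", effects = NULL,
                           concentration = NULL, seed = 1L) {
  if (!is.list(alphabet)) alphabet <- rep(list(as.character(alphabet)), n_positions)
  if (length(alphabet) != n_positions)
    stop_validation("need one alphabet (or a shared one) per position")
  lapply(alphabet, check_alphabet, where = "synthetic alphabet")
  depth <- rep_len(depth, n_positions)
  if (any(depth <= 0))
    stop_validation("depth must be positive at every position")
  structure(list(n_positions = n_positions, alphabet = alphabet,
                 depth = depth, background = background, effects = effects,
                 concentration = concentration, seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic counts with known truth
#'
#' Draws per-position counts `Multinomial(m, p)` from the foreground
#' distribution constructed by [synthetic_spec()] and returns the counts
#' together with the background and the true raw scores
#' `log2(p / q)`, enabling recovery tests of the stabilizers.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `fg` (`edl_counts`), `bg`
#'   (`edl_background`), `p` (`edl_probs`, the true foreground) and `truth`
#'   (`edl_scores`, mode `"raw"`: the true uncentered log2 ratios).
#' @examples
#' sp <- synthetic_spec(2, c("A", "C", "G", "T"), depth = 100, seed = 7)
#' sim <- simulate_counts(sp)
#' sim$fg
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labels <- as.character(seq_len(spec$n_positions))
  qb <- background(spec$background)

  with_preserved_rng(spec$seed, {
    pvals <- vector("list", spec$n_positions)
    qvals <- vector("list", spec$n_positions)
    for (j in seq_len(spec$n_positions)) {
      syms <- spec$alphabet[[j]]
      n <- length(syms)
      qv <- switch(qb$kind,
        preset = stats::setNames(rep(1 / n, n), syms),
        shared = {
          if (!all(syms %in% names(qb$vector)))
            stop_validation("background lacks symbols of the synthetic alphabet")
          w <- qb$vector[syms]
          w / sum(w)
        },
        matrix = position_values(qb$matrix, labels[j])[syms])
      base <- qv
      if (!is.null(spec$concentration)) {
        g <- stats::rgamma(n, shape = spec$concentration * n * qv)
        base <- g / sum(g)
      }
      eff <- rep(0, n)
      if (!is.null(spec$effects)) {
        sel <- spec$effects$position == labels[j]
        hit <- match(spec$effects$symbol[sel], syms)
        if (anyNA(hit))
          stop_validation("effects name a symbol absent from the alphabet")
        eff[hit] <- spec$effects$log2fc[sel]
      }
      pv <- base * 2^eff
      if (any(pv < 0) || sum(pv) <= 0)
        stop_validation("effects push p outside the simplex")
      pv <- pv / sum(pv)
      pvals[[j]] <- stats::setNames(pv, syms)
      qvals[[j]] <- stats::setNames(qv, syms)
    }
    counts <- lapply(seq_len(spec$n_positions), function(j) {
      k <- stats::rmultinom(1, size = spec$depth[j], prob = pvals[[j]])[, 1]
      stats::setNames(as.numeric(k), names(pvals[[j]]))
    })
    names(counts) <- names(pvals) <- names(qvals) <- labels
    truth <- lapply(seq_len(spec$n_positions), function(j)
      log2(pvals[[j]] / qvals[[j]]))
    names(truth) <- labels
    list(
      fg = count_matrix(counts, labels),
      bg = background(probability_matrix(qvals, labels,
                                         effective_count = spec$depth)),
      p = probability_matrix(pvals, labels),
      truth = score_matrix(truth, labels, mode = "raw", centering = "none")
    )
  })
}
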