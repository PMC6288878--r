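#' @title Stabilized estimation of log-ratio scores
#'
#' @description
#' Log2 ratios `log2(p_i/q_i)` explode when probabilities are estimated from
#' low counts: a symbol never observed among `m` sequences has maximum
#' likelihood estimate 0 and an infinite log ratio. Two stabilizers are
#' provided.
#'
#' **Pseudocounts** add a small constant `c` (default 0.5) to every count
#' before normalizing: `p_hat_i = (m_i + c) / (m + n c)` for an `n`-symbol
#' alphabet. Simple, but it stabilizes `p` and `q` separately, so symbols
#' with identical (e.g. zero) foreground counts still receive different
#' log-ratio estimates whenever their background rates differ — the plot can
#' show symbols as enriched or depleted even though they never occur in the
#' data.
#'
#' **Empirical Bayes shrinkage** stabilizes the log ratios themselves.
#' Per-cell point estimates (half-count offset) and delta-method standard
#' errors feed a normal-means model whose prior is a scale mixture of
#' normals centered at each position's median log ratio, with mixture
#' weights fitted jointly across all cells by maximum marginal likelihood
#' (EM). Posterior means are returned, so estimates vary no more than the
#' data support: noisy low-count cells are pulled to the position baseline
#' while well-determined signals survive essentially unshrunk.
#'
#' @name edlogo-stabilization
NULL

#' Stabilizer configuration
#'
#' @param method `"none"`, `"pseudocount"` or `"eb"`.
#' @param pseudocount Pseudocount `c > 0` added to every cell
#'   (default 0.5).
#' @param effective_count Pseudo sample size used to convert probability
#'   inputs to counts (default 1000: probabilities trusted to about three
#'   decimal places).
#' @param seed Integer recorded for reproducibility of any sampling step;
#'   the bundled EB fit is deterministic and does not consume it.
#' @return A `stabilizer_config` list.
#' @export
stabilizer_config <- function(method = c("none", "pseudocount", "eb"),
                              pseudocount = 0.5, effective_count = 1000,
                              seed = 1L) {
  method <- match.arg(method)
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop_validation("pseudocount must be positive")
  if (!is.numeric(effective_count) || effective_count < 1)
    stop_validation("effective_count must be at least 1")
  structure(list(method = method, pseudocount = pseudocount,
                 effective_count = effective_count, seed = as.integer(seed)),
            class = "stabilizer_config")
}

#' Pseudocount-stabilized probabilities
#'
#' `p_hat_i = (m_i + c) / (m + n c)`; strictly positive for any counts. The
#' resulting `effective_count` is `m + n c` per position.
#'
#' @param counts An `edl_counts` object.
#' @param c Pseudocount, positive (default 0.5, i.e. half a count; for a
#'   20-letter amino-acid alphabet this is the familiar `(m_i + 0.5)/(m + 10)`).
#' @return An `edl_probs` object.
#' @export
pseudocount_probs <- function(counts, c = 0.5) {
  stopifnot(inherits(counts, "edl_counts"))
  if (!is.numeric(c) || length(c) != 1L || c <= 0)
    stop_validation("pseudocount must be a single positive number")
  vals <- lapply(counts$values, function(v) (v + c) / (sum(v) + length(v) * c))
  names(vals) <- counts$positions
  ec <- vapply(counts$values, function(v) sum(v) + length(v) * c, numeric(1))
  probability_matrix(vals, counts$positions, effective_count = ec)
}

# Coerce a background (counts / probabilities / preset) to integer counts
# aligned to the foreground's per-position alphabets.
background_counts <- function(bg, fg, effective_count) {
  if (inherits(bg, "edl_counts")) {
    return(lapply(seq_along(fg$positions), function(j) {
      bv <- position_values(bg, fg$positions[j])
      syms <- names(fg$values[[j]])
      if (!setequal(names(bv), syms))
        stop_validation(sprintf(
          "background alphabet differs from foreground at position %s",
          fg$positions[j]))
      bv[syms]
    }))
  }
  if (inherits(bg, "edl_probs")) {
    ec <- bg$effective_count
    qs <- resolve_background(background(bg), fg)
    return(lapply(seq_along(qs), function(j) round(qs[[j]] * ec[min(j, length(ec))])))
  }
  qs <- resolve_background(bg, fg)
  lapply(qs, function(qv) round(qv * effective_count))
}

#' Empirical Bayes shrinkage of log2 ratios
#'
#' Returns finite, shrunken estimates of `log2(p_i/q_i)` from foreground and
#' background counts (see [edlogo-stabilization] for the model). Estimates
#' converge to the maximum-likelihood log ratio as counts grow, and
#' zero-count symbols are pulled to a common per-position baseline rather
#' than inheriting spurious structure from the background.
#'
#' @param fg An `edl_counts` foreground.
#' @param bg An `edl_counts`, `edl_probs` or [background()]; probabilities
#'   are converted to counts at `config$effective_count` (or the
#'   probability matrix's own recorded precision).
#' @param config A [stabilizer_config()].
#' @return An `edl_scores` object with `mode = "raw"`, `centering = "none"`.
#' @export
eb_shrink_log_ratios <- function(fg, bg, config = stabilizer_config("eb")) {
  stopifnot(inherits(fg, "edl_counts"))
  bcounts <- background_counts(bg, fg, config$effective_count)

  npos <- length(fg$positions)
  x <- se <- pos_idx <- vector("list", npos)
  for (j in seq_len(npos)) {
    mv <- fg$values[[j]]
    bv <- bcounts[[j]]
    n <- length(mv)
    M <- sum(mv)
    B <- sum(bv)
    # Half-count offset point estimate; identical form on both sides so
    # fg == bg gives exactly zero.
    xj <- log2((mv + 0.5) / (M + 0.5 * n)) - log2((bv + 0.5) / (B + 0.5 * n))
    # Delta-method SE of a log2 ratio of proportions; zero-count cells get
    # the SE of a half-count cell via the same offset.
    vj <- pmax(1 / (mv + 0.5) - 1 / (M + 0.5 * n), 0) +
          pmax(1 / (bv + 0.5) - 1 / (B + 0.5 * n), 0)
    x[[j]] <- xj
    se[[j]] <- sqrt(pmax(vj, 1e-12)) / log(2)
    pos_idx[[j]] <- rep(j, n)
  }
  xs <- unlist(x, use.names = FALSE)
  ss <- unlist(se, use.names = FALSE)
  pj <- unlist(pos_idx, use.names = FALSE)
  mu <- vapply(x, stats::median, numeric(1))[pj]

  post <- normal_mixture_posterior(xs, ss, mu)

  k <- 0L
  vals <- vector("list", npos)
  for (j in seq_len(npos)) {
    n <- length(fg$values[[j]])
    vals[[j]] <- stats::setNames(post[k + seq_len(n)], names(fg$values[[j]]))
    k <- k + n
  }
  names(vals) <- fg$positions
  score_matrix(vals, fg$positions, mode = "raw", centering = "none")
}

# Normal-means EB: x_i ~ N(theta_i, s_i^2), theta_i ~ sum_k pi_k N(mu_i,
# sigma_k^2) with a fixed sigma grid including 0 (pure shrinkage to the
# position baseline) and pi fitted jointly across all cells by EM on the
# marginal likelihood. Deterministic: fixed grid, uniform initialization,
# tolerance 1e-8, max 1000 iterations.
normal_mixture_posterior <- function(x, s, mu) {
  d <- x - mu
  if (all(abs(d) < 1e-12)) return(mu)
  smin <- max(min(s) / 10, 1e-8)
  smax <- max(2 * max(abs(d)), smin * 2)
  sigma <- smin
  while (sigma[length(sigma)] < smax) sigma <- c(sigma, sigma[length(sigma)] * sqrt(2))
  sigma <- c(0, sigma)
  K <- length(sigma)
  n <- length(x)

  sd_ik <- sqrt(outer(s^2, sigma^2, `+`))
  loglik_ik <- stats::dnorm(matrix(d, n, K), 0, sd_ik, log = TRUE)

  log_pi <- rep(-log(K), K)
  last <- -Inf
  for (iter in seq_len(1000L)) {
    a <- sweep(loglik_ik, 2L, log_pi, `+`)
    amax <- apply(a, 1L, max)
    w <- exp(a - amax)
    rowsum_w <- rowSums(w)
    ll <- sum(amax + log(rowsum_w))
    w <- w / rowsum_w
    log_pi <- log(pmax(colMeans(w), 1e-300))
    if (is.finite(last) && abs(ll - last) < 1e-8 * (abs(last) + 1)) break
    last <- ll
  }
  factor_ik <- outer(rep(1, n), sigma^2) / outer(s^2, sigma^2, `+`)
  mu + d * rowSums(w * factor_ik)
}

#' Stabilized enrichment-depletion scores
#'
#' End-to-end scoring from counts under a chosen stabilizer: `"none"`
#' normalizes and scores directly (and errors on zero counts),
#' `"pseudocount"` applies [pseudocount_probs()] to both sides, `"eb"`
#' median-centers the output of [eb_shrink_log_ratios()].
#'
#' @param fg An `edl_counts` foreground (an `edl_probs` is accepted and
#'   converted to counts at its recorded `effective_count` when the method
#'   needs counts).
#' @param bg A [background()], `edl_probs` or `edl_counts`.
#' @param config A [stabilizer_config()].
#' @param rule Centering rule, see [median_center()].
#' @return An `edl_scores` object with `mode = "edlogo"`.
#' @export
stabilized_edlogo <- function(fg, bg = "uniform",
                              config = stabilizer_config("pseudocount"),
                              rule = c("smallest", "conventional", "largest")) {
  rule <- match.arg(rule)
  stopifnot(inherits(config, "stabilizer_config"))
  if (inherits(fg, "edl_probs") && config$method != "none")
    fg <- probs_to_counts(fg)
  if (config$method == "none") {
    p <- if (inherits(fg, "edl_probs")) fg else normalize_counts(fg)
    return(edlogo_scores(p, as_prob_background(bg), rule))
  }
  if (config$method == "pseudocount") {
    p <- pseudocount_probs(fg, config$pseudocount)
    qb <- pseudocount_background(bg, fg, config)
    return(edlogo_scores(p, qb, rule))
  }
  s <- median_center(eb_shrink_log_ratios(fg, bg, config), rule)
  s$mode <- "edlogo"
  s
}

probs_to_counts <- function(p) {
  vals <- lapply(seq_along(p$values), function(j)
    round(p$values[[j]] * p$effective_count[j]))
  names(vals) <- p$positions
  count_matrix(vals, p$positions)
}

as_prob_background <- function(bg) {
  if (inherits(bg, "edl_counts")) background(normalize_counts(bg)) else background(bg)
}

# Pseudocount stabilization of the background: count backgrounds get the
# same treatment as the foreground; probability backgrounds are used as-is
# when strictly positive, and only converted to counts at effective_count
# and pseudocounted when they contain zeros.
pseudocount_background <- function(bg, fg, config) {
  if (!inherits(bg, "edl_counts")) {
    qs <- resolve_background(as_prob_background(bg), fg)
    if (all(unlist(qs) > 0)) return(as_prob_background(bg))
  }
  bc <- background_counts(as_bg_or_counts(bg), fg, config$effective_count)
  names(bc) <- fg$positions
  background(pseudocount_probs(count_matrix(bc, fg$positions), config$pseudocount))
}

as_bg_or_counts <- function(bg) {
  if (inherits(bg, "edl_counts") || inherits(bg, "edl_probs")) bg else background(bg)
}
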