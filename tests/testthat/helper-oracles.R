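# Shared helpers: random inputs and brute-force oracles.

rand_simplex <- function(n, symbols = NULL) {
  v <- stats::rgamma(n, shape = 1) + 1e-4
  v <- v / sum(v)
  names(v) <- if (is.null(symbols)) paste0("S", seq_len(n)) else symbols
  v
}

one_pos_probs <- function(p) probability_matrix(list(`1` = p))

# Brute-force stack height over a dense grid of centering offsets plus the
# data points themselves (the minimum of a piecewise-linear convex function
# is attained at a data point).
min_stack_by_grid <- function(v, extra = 401L) {
  offs <- sort(unique(c(v, seq(min(v) - 1, max(v) + 1, length.out = extra))))
  f <- vapply(offs, function(c) sum(abs(v - c)), numeric(1))
  list(min = min(f), offsets = offs, f = f)
}

extdata <- function(...) system.file("extdata", ..., package = "edlogo")
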