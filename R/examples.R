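#' Bundled worked example inputs
#'
#' Small in-memory inputs used throughout the documentation and tests:
#'
#' \describe{
#'   \item{`dna_probs`}{one DNA position with
#'     `p = (A, C, G, T) = (0.33, 0.33, 0.33, 0.01)` — against a uniform
#'     background, the textbook case where "T is depleted" is the most
#'     parsimonious description.}
#'   \item{`tie_scores`}{a raw score vector `(0, 0, +1, +1)` over four
#'     symbols, the canonical even-alphabet tie: every centering constant
#'     between the two central values gives the same minimal stack height 2.}
#'   \item{`glyco_center_counts`}{amino-acid counts at the central position
#'     of an N-linked glycosylation motif alignment of 5422 sequences:
#'     asparagine (N) 5422, all nineteen other residues 0. The standard
#'     stress test for stabilizers.}
#'   \item{`aa_background`}{a shared 20-residue background: Swiss-Prot-like
#'     amino-acid frequencies (so e.g. L is common, W rare).}
#'   \item{`mutsig_probs`}{a five-position mutational-signature profile with
#'     per-position alphabets: flanking positions -2, -1, +1, +2 over
#'     `A, C, G, T`, and the central position over the six strand-collapsed
#'     substitution strings, with `C>T` at 0.96 and `T>C` at 0.03 (the
#'     remaining 0.01 split equally over the other four types is a fixture
#'     convention, not data).}
#' }
#'
#' @return A named list of package objects (see Details).
#' @examples
#' ex <- edlogo_examples()
#' stack_height(median_center(ex$tie_scores, "conventional"), "1")
#' @export
edlogo_examples <- function() {
  dna_probs <- probability_matrix(
    list(`1` = c(A = 0.33, C = 0.33, G = 0.33, T = 0.01)))

  tie_scores <- score_matrix(list(`1` = c(A = 0, B = 0, C = 1, D = 1)))

  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  counts <- stats::setNames(rep(0, 20), aa)
  counts["N"] <- 5422
  glyco_center_counts <- count_matrix(list(`0` = counts))

  aa_freq <- c(A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
               Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
               L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
               S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0687)
  aa_background <- background(aa_freq / sum(aa_freq))

  subst <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  center <- stats::setNames(rep(0.01 / 4, 6), subst)
  center["C>T"] <- 0.96
  center["T>C"] <- 0.03
  flank <- function(a, c, g, t) c(A = a, C = c, G = g, T = t)
  mutsig_probs <- probability_matrix(
    list(`-2` = flank(0.28, 0.22, 0.22, 0.28),
         `-1` = flank(0.20, 0.35, 0.20, 0.25),
         `0`  = center,
         `1`  = flank(0.32, 0.28, 0.08, 0.32),
         `2`  = flank(0.27, 0.24, 0.22, 0.27)))

  list(dna_probs = dna_probs,
       tie_scores = tie_scores,
       glyco_center_counts = glyco_center_counts,
       aa_background = aa_background,
       mutsig_probs = mutsig_probs)
}
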