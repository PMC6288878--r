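---
title: "Enrichment-depletion logos: model, stabilization and rendering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enrichment-depletion logos: model, stabilization and rendering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edlogo)
```

## The scoring model

A logo plot summarizes, position by position, how a foreground probability
vector $\mathbf{p} = (p_1,\dots,p_n)$ over the $n$ permitted symbols
compares with a background $\mathbf{q}$. The enrichment-depletion logo
plots, for each symbol, the median-centered log ratio

$$ r_i = \tilde r_i - \mathrm{median}(\tilde r_1,\dots,\tilde r_n),
\qquad \tilde r_i = \log_2 \frac{p_i}{q_i}, $$

above the axis when positive and below when negative, each glyph $|r_i|$
tall and stacked bottom-to-top in order of increasing $r_i$.

Why the median? If we model $p_i \propto \lambda_i q_i$, only the ratios of
the $\lambda_i$ are identifiable: every vector $l_i = \log_2(p_i/q_i) + k$
is an equally valid estimate of $\log_2 \lambda_i$. Total stack height
$\sum_i |l_i|$ is a piecewise-linear convex function of $k$ whose minimum is
attained when the subtracted constant is a median of the $\tilde r_i$ — so
the median-centered vector is the *most parsimonious* representation, the
one using the least ink. A position where one symbol is rare against an
otherwise flat profile is drawn as a single depleted glyph rather than
$n-1$ enriched ones.

```{r intuition}
p <- probability_matrix(list(`1` = c(A = 0.33, C = 0.33, G = 0.33, T = 0.01)))
edlogo_scores(p, "uniform", rule = "conventional")
```

Two consequences worth knowing:

* **Height differences are log-odds ratios.** For any two symbols,
  $r_a - r_b = \log_2\!\big((p_a/p_b)/(q_a/q_b)\big)$ independent of the
  centering constant (`log_odds()`). Heights themselves are only defined
  relative to the per-position median, so "enriched" and "depleted" mean
  *relative to the median symbol*, not relative to $q$ in an absolute sense.
* **Mirror property.** Under conventional centering, swapping foreground
  and background reflects the plot about the x axis, so enrichment and
  depletion are treated symmetrically.

## Ties when $n$ is even

With an even alphabet (DNA being the prime case) every constant in the
closed interval between the two central order statistics minimizes the
stack height; for $\tilde r = (0, 0, 1, 1)$, subtracting anything in
$[0, 1]$ gives total height 2. The package exposes the three natural
choices as `rule =`:

* `"smallest"` — the lower central order statistic. Favors an enrichment
  reading and is the default.
* `"conventional"` — the mean of the two central order statistics. The only
  rule that preserves the mirror property.
* `"largest"` — the upper central order statistic; favors depletion.

Ties among equal $\tilde r_i$ are resolved on the sorted multiset with no
jitter, and in the layout by alphabet order with the earlier symbol nearer
the axis — a convention; the choice has no effect on heights.

## Comparison modes

For side-by-side reading the package also computes the standard
information-content logo (heights $p_i \cdot \mathrm{IC}$ with
$\mathrm{IC} = \log_2 n_{\mathrm{ref}} + \sum_i p_i \log_2 p_i$ bits,
uniform reference only — background-corrected standard logos are out of
scope) and the weighted Kullback–Leibler logo. No formula for the latter is
fixed by convention in one place; we use the per-symbol KL contribution
$p_i \log_2(p_i/q_i)$, signed, with $0 \log 0 = 0$, and regard the mode as
comparison-only.

## Stabilizing the log ratios

Estimates $\hat p_i = m_i/m$ from counts put zeros — hence infinite
$|\tilde r_i|$ — wherever a symbol goes unobserved. Two stabilizers are
provided, configured by `stabilizer_config()`:

**Pseudocounts** (`method = "pseudocount"`, default $c = 0.5$):
$\hat p_i = (m_i + c)/(m + nc)$. For 20 amino acids this is the familiar
$(m_i + 0.5)/(m + 10)$. The weakness is structural: $p$ and $q$ are
stabilized separately, so two symbols that *both never occur* in the
foreground still get different log ratios whenever their background rates
differ, and the plot shows spurious enrichments and depletions.

**Empirical Bayes** (`method = "eb"`) stabilizes the log ratios
themselves:

1. per-cell point estimates with a half-count offset,
   $\hat{\tilde r}_i = \log_2\frac{m_i + 1/2}{m + n/2} -
   \log_2\frac{b_i + 1/2}{b + n/2}$, where $b_i$ are background counts
   (probability backgrounds are converted at their `effective_count`;
   default 1000, i.e. trusted to roughly three decimals);
2. delta-method standard errors for a log ratio of proportions, the same
   half-count offset giving zero-count cells the uncertainty of half a
   count;
3. a normal-means model $\hat{\tilde r}_i \sim N(\theta_i, s_i^2)$,
   $\theta_i \sim \sum_k \pi_k\, N(\mu_{j(i)}, \sigma_k^2)$, with prior
   mean the per-position median, a fixed $\sigma$ grid from $\min(s)/10$ to
   twice the largest deviation (factor $\sqrt2$, plus a point mass at 0),
   and the weights $\pi$ fitted by maximum marginal likelihood with EM
   jointly across *all* cells of the matrix (tolerance $10^{-8}$, at most
   1000 iterations, uniform initialization — fully deterministic);
4. posterior means, median-centered as usual.

Shrinking jointly across positions gives the prior more data; shrinking
per position would be the other defensible choice and would differ for
very short motifs. Under this scheme estimates converge to the maximum
likelihood log ratio as counts grow, and zero-count symbols collapse to
nearly the position baseline: on the bundled glycosylation-center fixture
(one residue observed 5422 times, nineteen never) the spread among the
nineteen zero-count residues is about 2% of what pseudocounts leave, so
the logo shows the single genuine enrichment and nothing else. A small
residual dependence on the background does survive — the zero cells have
finite standard errors, so they are not shrunk *exactly* onto one value —
which we consider statistically honest rather than a defect.

In pseudocount mode a background supplied as strictly positive
probabilities is used as-is (it needs no stabilizing); count backgrounds,
and probability backgrounds containing zeros, get the same pseudocount
treatment as the foreground.

## Layout and rendering

`logo_layout()` turns scores into glyph boxes: position slots centered on
integer x, shrunk by a 5% gap per side; heights exactly $|r_i|$; symbols
with $|r_i| \le 10^{-12}$ are not drawn; above-axis boxes tile
$[0, \sum_{r_i>0} r_i]$ and below-axis boxes $[-\sum_{r_i<0}|r_i|, 0]$
without gaps.

`render_svg()` emits the SVG itself — fixed number formatting, stable
element order, no timestamps — so identical inputs give byte-identical
files, and a run manifest written by the CLI can be replayed to reproduce
outputs exactly. Glyphs are `<text>` elements scaled non-uniformly into
their boxes using fixed nominal metrics (0.6 em width per character,
0.72 em cap height), which keeps the geometry independent of viewer font
metrics; we chose this over embedding font outlines as paths to keep the
package free of binary font data. String symbols (substitution types like
`C>T`, histone marks) are first scaled uniformly to the box width, then
stretched vertically, with the stretch capped at 8 times the uniform scale
(beyond the cap the glyph is vertically centered) so long strings in
shallow boxes stay legible — a readability convention, not part of the
scoring model.

## The synthetic generator, and what tests can show

`synthetic_spec()` / `simulate_counts()` draw per-position counts
$\mathrm{Multinomial}(m, p)$ with $p \propto q\,2^{\mathrm{effect}}$,
returning the true $\log_2(p/q)$ alongside. This emulates the sampling
noise of counting symbols in an alignment of $m$ sequences — the binomial
view under which the stabilizers are justified. It does not emulate
overdispersion between sequencing runs, phylogenetic correlation between
aligned sequences, or alignment error; recovery results on synthetic data
therefore speak to estimator behavior under clean multinomial sampling,
not to artifacts upstream of the count matrix.

Test problem sizes were chosen to exercise the asymptotics cheaply:
consistency is checked on expected counts at $m = 10^2, 10^4, 10^6$
(sampling noise at $10^6$ would otherwise dominate the 0.01 error bound),
recovery across 20 seeds at depths $10^2, 10^3, 10^5$, and the
parsimony/mirror/log-odds identities on hundreds of random simplex pairs
at $10^{-12}$ — these are closed-form double-precision identities, so the
tolerance reflects accumulated rounding only.

## Known limitations

* The EB scheme is a normal-approximation shrinkage; for cells with counts
  of 1–2 the normal likelihood is a crude summary of the binomial one, and
  estimates there are conservative (over-shrunk) rather than exact.
* Standard logos support a uniform reference only.
* Rendering targets clarity and determinism, not typography: glyph scaling
  uses nominal metrics, so exact visual proportions vary slightly with the
  viewing font.
* One logo per run; multi-panel composition is left to external tools.
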