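---
title: "Choosing stable RT-qPCR reference genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing stable RT-qPCR reference genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

RT-qPCR quantifies a target transcript *relative* to reference genes that
are assumed stable across the conditions compared. That assumption must be
verified per experiment: no gene is universally stable, and normalizing to
a drifting reference propagates its drift into every fold change. Given a
panel of candidate genes measured over the same samples (a genes × samples
Ct matrix), `refstab` scores each candidate with three algorithms that make
deliberately different assumptions, then aggregates their rankings.

Input Ct values are validated to (0, 45] cycles — a 40-cycle protocol plus
headroom — with explicit table orientation (never guessed) and a
reject-by-default policy for missing cells. Optional imputation replaces a
missing value with the mean of its gene's other biological replicates in
the same (cultivar, sample class) cell; it is behind an explicit flag
because silent imputation shrinks variance estimates, the very quantity
these methods rank by. Replicates are treated as individual samples
throughout; averaging replicates before analysis is possible upstream but
not done by default, since the stability algorithms are meant to see
biological replicate scatter.

## geNorm

geNorm works on relative quantities `Q_gs = E^(min_s' Ct_gs' − Ct_gs)`,
with the per-gene minimum Ct as calibrator (so max Q = 1) and efficiency
`E = 2` by default (no efficiency estimates are required; per-gene values
in [1.5, 2.2] are accepted). Its core assumption: two *ideal* references
have a constant expression ratio across samples, so the sample SD of their
log2 ratio (`V_jk`, computed with the n−1 denominator throughout) measures
their joint instability. A gene's `M` is its mean `V` against all other
candidates; the gene with the largest recomputed `M` is eliminated
stepwise until two remain. Consequences worth knowing:

- The final pair cannot be ordered by the method itself, so both genes
  share dense rank 1 — which is also what comprehensive ranking tables in
  this field show.
- `M` is blind to variation shared by the whole panel (per-sample loading),
  and co-regulated gene pairs can hide each other's instability.
- `V_n/n+1` compares normalization factors (geometric means of the top-n
  genes' Q) for consecutive n; the smallest n with `V_n/n+1` below the
  cutoff (default 0.15, the conventional threshold) is reported as the
  optimal reference count, or `NA` when no n passes. Genes enter `NF_n` in
  stability-rank order, ties resolved by full-panel `M` then name.
- The `M < 1.5` acceptability convention is reported as a flag and never
  used to drop genes silently.
- Ties in the elimination step (exact, to within 1e-12) remove the
  lexicographically last gene name — determinism with no statistical
  content.

## NormFinder

NormFinder fits `y = log2 Q` with additive gene and sample effects.
Ungrouped, residuals from two-way centering give a naive per-gene variance
`v_i`; because centering mixes the panel's variances, the estimator applies
the `k/(k−2)` correction `σ̂²_i = max(0, k/(k−2) · (v_i − Σv_l /
(k(k−1))))`, which is unbiased under the additive model (we verified the
algebra: the expectation of `v_i` is `σ²_i (1−2/k) + σ̄²/k`). `S_i = σ̂_i`.
Negative estimates are floored at zero before the square root; a fully
degenerate zero-variance panel yields all-zero S with a warning rather
than an error. At least 3 genes are required (the correction factor is
undefined below that), and at least 4 samples ungrouped.

With a grouping factor, per-group variances `σ̂²_ig` are combined with the
gene's group contrast `d_ig` (group mean minus overall group mean, centered
across groups), shrunk towards zero by `γ² / (γ² + σ̂²_ig/n_g)` where `γ²`
is the method-of-moments variance of the contrasts net of their mean
sampling variance (floored at 0). Then `S_i = mean_g(|d̃_ig| +
√(σ̂²_ig/n_g))`. This is validated by parameter recovery on simulated
panels (Spearman correlation of S with true σ, and detection of injected
group shifts), not by matching any particular binary's output — the
original implementations are not redistributable, and recovery against
ground truth is the stronger check. Log base 2 keeps S commensurate with
geNorm's log2-ratio units; any base gives identical ranks.

Which grouping factor to supply is an experimental-design decision the data
cannot make: `analyze_group(normfinder_groups = ...)` accepts
`"sample_class"`, `"cultivar"`, `"none"`, an explicit factor, or `"auto"`
(the default: group by sample class whenever the subset spans at least two
classes with two samples each, otherwise ungrouped). The default mirrors
how tissue-panel studies are usually run; outputs record which mode was
used.

## BestKeeper

BestKeeper deliberately stays on the raw Ct scale: per-gene SD and
CV% = 100·SD/mean, the SD > 1 cycle exclusion rule, the index (per-sample
geometric mean Ct of retained genes) and per-gene Pearson correlation with
the index (two-sided p from the t distribution with n−2 df). Two SD
flavours are provided because published tables are often ambiguous about
which was used: `sample_sd` (n−1 denominator, the default) and
`mean_abs_dev` (the original tool's mean absolute deviation). Ranks sort by
ascending SD with ties broken by CV then name; a zero-variance gene gets
`r = NA` with a warning — a correlation is never fabricated. If fewer than
two genes survive the SD rule the index is not computable and the function
stops, advising manual `retained =` selection.

Because it uses raw Ct, BestKeeper *is* sensitive to per-sample loading
differences that geNorm and NormFinder cancel by construction; the test
suite asserts this asymmetry explicitly, as it is the main practical
difference between the methods.

## Comprehensive ranking

The aggregate score is the plain sum `G + N + B` of the three dense ranks —
the convention used by comprehensive ranking tables in this literature (not
the geometric mean of ranks used by RefFinder). The final rank is dense by
ascending sum; tied sums are displayed by ascending geNorm M then name,
a rule of ours documented here because published tables never exhibit the
tie. geNorm's shared final pair contributes rank 1 from each member, so the
minimum possible sum is 3.

## 2^−ΔΔCt validation

`ddct()` normalizes a target to the arithmetic mean Ct of the reference
set (equivalently the geometric mean of quantities — the field-standard
multi-reference combination), subtracts the calibrator group's mean ΔCt
and reports `2^−ΔΔCt` with a dispersion range `2^−(ΔΔCt ∓ SD)` from the
replicate SD of ΔCt. Efficiency is fixed at 2 (no Pfaffl correction). The
calibrator defaults to the green-fruit class when present — the natural
baseline of a fruit-development series — and is always recorded in the
output rather than asserted. `compare_normalizations()` quantifies the
cost of a bad reference as the maximum absolute log2 fold-ratio between
reference sets across groups.

## The synthetic generator

`simulate_ct()` draws `Ct_is = b_i + δ_i,g(s) − u_s + ε_is`: per-gene
baselines `b_i`, group effects `δ` attached to cultivar or sample-class
levels, a shared per-sample loading effect `u_s ~ N(0, τ²)` entering with a
minus sign (more template, earlier Ct), and Gaussian per-gene noise on the
Ct scale (multiplicative on quantities — the standard qPCR error model).
The default spec mirrors a four-cultivar berry study: 12 genes × 72
samples (4 cultivars × 6 classes × 3 replicates), baselines spanning
roughly 22–31 cycles, τ = 0.3 cycles, two designed-stable genes (σ = 0.10
and 0.12, no group structure), a designed-unstable gene (σ = 1.2 plus a
1.5-cycle mature-fruit shift) and a mid-panel with σ between 0.3 and 0.9
and modest effects. These values were fixed once, as what a practitioner
would call a realistic panel, and are the conditions under which the
package's recovery claims are tested.

What the generator does *not* emulate: technical replicates, pipetting
outliers, plate effects, amplification-efficiency differences between
genes, inhibition, or heavy-tailed noise. Passing tests therefore show the
algorithms recover the truth of this generative model, not that they are
robust to every pathology of real plates.

## Problem sizes and numerical choices

The test suite and acceptance script run at the study's natural scale —
12 × 72 panels, with 100-seed replication for recovery rates, 20 seeds for
parameter-recovery and loading-contrast properties, and 500 replicates for
the unbiasedness check at small per-run cost. Oracle agreement for geNorm
M is asserted at 1e-12 (pure floating-point reordering); closed forms at
1e-10 or exact. Ct validity, efficiency bounds and threshold positivity
are hard errors; degenerate inputs (constant genes, zero-variance panels)
take the documented warning paths instead of failing.

## Known limitations

- geNorm's co-regulation blindness is inherited, not fixed; run NormFinder
  with a meaningful grouping to catch group-confounded genes.
- NormFinder's grouped mode needs replication per group (≥ 2, ideally ≥ 8
  samples) for its shrinkage to be meaningful.
- The BestKeeper index depends on which genes survive the SD rule, so its
  correlations are conditional on that retention set.
- The comprehensive rank sum treats the three methods as equally credible;
  it has no probabilistic interpretation.
- No efficiency estimation from dilution series, no melt-curve analysis,
  and no parsing of instrument-native exports: inputs are plain CSV/TSV Ct
  tables.
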