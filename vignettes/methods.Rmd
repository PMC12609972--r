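---
title: "Methods: two-color array preprocessing, intensity-dependent Z-scores, and downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-color array preprocessing, intensity-dependent Z-scores, and downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayz)
library(dplyr)
```

`arrayz` implements the analysis chain of a classic spotted two-color
microarray experiment — control sample in channel 1, treated sample in
channel 2, probes printed in duplicate, a small number of biological
replicate hybridizations — together with the downstream interpretation
layers such experiments typically feed: literature concordance,
over-representation analysis, interaction-network hubs, and exploratory
signature-level survival. This vignette explains the models and the
choices behind them.

## Preprocessing model

Each spot contributes foreground and background intensities per channel.
The corrected signal is `s_c = fg_c − bg_c`; spots where either corrected
signal is non-positive are flagged rather than silently dropped, so the
filter report can account for every input row. The default quality filter
then removes flagged spots and spots with
`min(fg1/max(bg1,1), fg2/max(bg2,1)) < 1.5`. The 1.5 signal-to-noise
default is a conventional, configurable choice — spotted-array protocols
describe "inadequate signal" qualitatively, and any fixed number is a
policy, not a fact about the data.

Working coordinates are the MA plane: `M = log2(s2) − log2(s1)` (treated
minus control; negated for dye-swapped arrays so orientation is uniform)
and `A = (log2 s1 + log2 s2)/2`. Intensity-dependent dye bias appears as a
curved trend of M against A. We remove it with classic Cleveland LOWESS —
locally weighted linear fits with tricube weights, a span of 0.3 (the
fraction of points in each local fit), and 3 robustness iterations — via
`stats::lowess()`, subtracting the fitted curve: `M′ = M − f(A)`. Below 50
points a local fit is not meaningful and the function falls back to
median-centering with a warning. Arrays are normalized separately; no
print-tip or composite variants are offered, deliberately.

Replicate averaging is two-stage and unweighted: duplicate spots are
averaged within each array first, then per-array means are averaged
across biological replicates. The package defaults to two replicate
arrays; the count is configurable because designs vary (four biological
replicates per group is common at the bench, while final analyses often
average the arrays that pass QC).

QC metrics follow the usual thresholds for this platform: Pearson
correlation of gene-level log-ratios between replicate arrays (> 0.85
expected for dye-swap/replicate consistency, > 0.90 for array-to-array
reproducibility) and the fraction of spots passing filters (> 0.95).
Pearson is used because these thresholds are conventionally quoted as
plain `r` values.

## The intensity-dependent Z-score

Ratio variance on spotted arrays grows toward low intensity. A global
mean/SD would therefore over-call dim genes. Instead, genes are ranked by
A and each gene is standardized against a sliding window of 500 genes of
similar average intensity:

- the window is symmetric in rank around the focal gene and clamped at the
  extremes, so it always holds exactly `min(500, n)` genes;
- the focal gene is included in its own window — with 500 members
  self-inclusion shifts the estimate negligibly, and inclusion keeps the
  definition simple (an exclude-self variant would change z by O(1/w));
- μ is the window mean and σ the window sample SD (n−1 denominator);
- `Z = (R_i − μ)/σ`, with `Z = NA` (call `NONE`) in degenerate
  zero-variance windows.

Thresholds are inclusive: `UP` at `Z ≥ 2`, `DOWN` at `Z ≤ −2`, and
`STABLE` at `|Z| ≤ 1.5`; anything between the stable band and the DE
cutoffs is `NONE`. Under a locally Gaussian null, `|Z| ≥ 2` corresponds to
a two-sided tail of ≈ 0.0455, i.e. approximately p < 0.05 per gene —
`null_calibration()` verifies this empirically by running the full
simulate–preprocess–call pipeline on null configurations. No gene-level
FDR is applied to the microarray calls: the statistic is defined by its Z
thresholds, and the package keeps that contract (enrichment analyses
downstream do use FDR).

How a *stable-expression* call relates to a separate control-group
contrast is genuinely underdetermined in single-contrast designs: one
treated-versus-control statistic cannot simultaneously be a basal-stability
statistic. `classify_overlap()` therefore treats stable-overlap
categories as supplementary intersections against a caller-supplied
stable-gene set (e.g. from a control-vs-control hybridization) rather than
forcing them into the main partition: the six study-by-literature
categories partition the DEG list exactly; `lit_seg_not_de` and the
`stable_overlap_*` categories are reported alongside.

## Over-representation analysis

The test is the one-sided hypergeometric upper tail
(`p = P[X ≥ k]`, `X ~ Hypergeometric(N, K, n)`), computed with
`stats::phyper`; tests are cross-checked in the test suite against exact
combinatorial tail sums on fully enumerable universes. The background
defaults to the full probe universe of the array — for a 5000-probe
platform, those 5000 genes — because enrichment against a whole-genome
background would overstate significance for a fixed panel.
Benjamini–Hochberg FDR is applied within each collection separately
(e.g. KEGG separately from each GO branch), matching how per-analysis FDR
values are conventionally reported. Tiers are `significant` at
`FDR ≤ 0.05` (inclusive; the boundary is configurable) and `suggestive`
at `0.05 < FDR ≤ 0.10`, with an additional fold-enrichment filter
`FE ≥ 5` that demotes records to `none` without deleting them.

The term network connects retained terms whose query-restricted member
sets have Jaccard similarity ≥ 0.2; edge weight is the shared-gene count,
node attributes carry `k` and `−log10(FDR)`. Both the similarity measure
and the cutoff are configurable — "degree of gene overlap" admits several
formalizations and Jaccard on query hits is the most interpretable.

## PPI hubs

Scored, undirected edge lists are filtered at a minimum confidence score
of 0.700, read inclusively ("minimum required" means ≥). Hubs are nodes
of the *filtered* graph with degree ≥ 10 — filtering first is the
implied order, since hub-ness should reflect only high-confidence
interactions. Upstream k-means clustering of networks into functional
modules, as offered by interaction databases on their internal
embeddings, is intentionally not re-implemented: those embeddings are not
public, so the package provides connected components and degree
statistics instead.

## Signature survival and correlation

A subject's signature score is the mean of the z-standardized expression
of the signature genes (zero-variance genes dropped with a warning). This
simple aggregation is a design choice; web platforms that offer signature
survival do not document a canonical rule, and the standardized mean is
symmetric, scale-free, and robust to signature size.

Subjects are median-split: strictly above the median is `high`, ties go
`low` (configurable). The two groups are compared with the log-rank test
(`survival::survdiff`), Kaplan–Meier curves come from
`survival::survfit`, and the hazard ratio is computed from the log-rank
observed/expected totals, `HR = (O_high/E_high)/(O_low/E_low)`, with a
log-scale CI using `SE(log HR) = sqrt(1/E_high + 1/E_low)`. The O/E ratio
is fully determined by the risk-set tables the test already computes and
is adequate for a two-group median split; a proportional-hazards model
would add machinery without changing the estimand here. The test suite
cross-checks O and E against a manual risk-set tabulation.

Spearman correlation uses mid-ranks (ties averaged). For n ≤ 9 the
two-sided p-value is exact, from the full n! permutation distribution;
above that the usual t approximation applies. The cutover at 9 keeps the
exact path affordable (9! ≈ 3.6 × 10^5 permutations).

## The synthetic-data generator

Because raw scans for the motivating experiment are not deposited, the
generator is a first-class module, and its defaults are the conditions the
package's checks run under:

- 5000 gene-specific probes printed in duplicate; 2 biological replicate
  arrays; per-gene baseline log2 intensities `Normal(10, 2)`;
- 6% of genes truly DE at `|log2FC| = 2` (≈ 300 genes on a 5000-probe
  array, the scale typical of these experiments), sign random;
- observed spot ratio `M = true_log2fc + c(A) + ε(A)`, with a cubic
  dye-bias curve `c(A)` (coefficients `(0.3, −0.06, 0.008, −0.0008)` in
  centered A — a classic "banana" with amplitude ≈ 1 at the intensity
  extremes, chosen gentle enough that span-0.3 LOWESS can recover it:
  steeper curvature at the sparse low-intensity boundary is not removable
  by any local-linear smoother and would conflate generator artifacts
  with normalization error);
- ratio noise SD interpolating log-linearly from 0.4 at low A to 0.15 at
  high A, emulating the variance inflation that motivates the local
  Z-score;
- additive per-channel background (mean 50) on top of the foreground, so
  background correction is exactly invertible in expectation;
- channel orientation fixed (channel 1 control, channel 2 treated), with
  optional dye-swap arrays;
- one random stream per array derived from `(seed, array index)`, so
  adding arrays never changes earlier ones; identical configurations are
  bit-identical.

Companion generators plant known structure downstream: a gene-set term
with an exact query overlap, a PPI hub of exact post-filter degree,
cohorts whose hazard is planted on the median-dichotomized signature
score (so `exp(planted_log_hr)` is exactly the estimand of the
median-split analysis), and an infiltration column coupled to a gene
through a Gaussian copula with Pearson parameter `2·sin(π·ρ/6)` so the
*Spearman* correlation equals the planted ρ (exactly monotone at ρ = ±1).

What the generator does *not* emulate — and what passing tests therefore
do not establish about real arrays: spatial artifacts (print-tip, wash
gradients), saturation, correlated duplicate-spot noise, heavy-tailed
outliers beyond the robustness iterations' reach, batch effects between
replicate arrays, and any biology in the DE set (effects are a clean
two-point mixture). Sensitivity estimates on this generator are best-case.

## Problem sizes and numerical choices

The bundled checks run at reduced scale chosen to exercise every code
path while keeping the full suite fast on a laptop: null calibration uses
20 replicates of 2000-gene arrays; dye-bias recovery uses a noise-free
2000-gene array and excludes the extreme 2% of the A range, where
boundary bias is intrinsic to one-sided local fits; hazard-ratio recovery
averages 200 cohorts of n = 2000; the log-rank type-I study uses 500
cohorts of n = 120; Spearman recovery uses n = 500. Ties in ranking are
broken by gene symbol to make window membership deterministic; windows
with zero SD yield `NONE` calls rather than infinite scores; BH adjustment
validates p ∈ (0, 1] before delegating to `stats::p.adjust`.

## Known limitations

Single global LOWESS only; no gene-level FDR for array calls (by
contract); the hazard-ratio estimator is the log-rank O/E ratio, which is
slightly attenuated relative to a partial-likelihood estimate under heavy
censoring; exact Spearman inference stops at n = 9; and the literature
and case-study tables bundled for demonstration contain only the
explicitly named genes, not a full curated database.
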