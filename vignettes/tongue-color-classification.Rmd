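---
title: "Color-space features for tongue-image ZHENG classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-space features for tongue-image ZHENG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguecolor)
```

# The problem

TCM practitioners differentiate ZHENG — e.g. Hot versus Cold syndrome in
gastritis patients — largely from the color of the tongue body and its
coating. `tonguecolor` turns this judgement into a reproducible pipeline:
per-pixel color features over a masked tongue photograph, statistical
aggregation over a region, supervised binary classification, and
cross-validated scoring by class-size-weighted F-measure. Tongue
*segmentation* is deliberately out of scope: the mask is an input.

This vignette records the model, the tunable parameters and the design
decisions made where the protocol leaves latitude, so that every numeric
choice in the code has a stated rationale. It states no empirical claim
that the test suite does not itself compute.

# The 25 per-pixel features

Each 8-bit pixel (R, G, B) is first normalized to r = R/255 etc., then
mapped through eight color spaces, giving 25 components in fixed order:
RGB (f₁–f₃), HSV (f₄–f₆), YIQ (f₇–f₉), Y'CbCr (f₁₀–f₁₂), XYZ (f₁₃–f₁₅),
L\*a\*b\* (f₁₆–f₁₈), Luv (f₁₉–f₂₁), CMYK (f₂₂–f₂₅). Details worth noting:

* **HSV.** V is the channel maximum M̃; S = (M̃−m̃)/M̃ with S = 0 at black;
  H follows the branch of the channel attaining M̃ (ties broken in R, G, B
  order). The red branch yields H ∈ [−1/6, 1/6); negative values are
  wrapped by +1 so H ∈ [0, 1) — the standard hue convention, and the only
  reading that keeps f₄ in range.
* **YIQ** uses normalized RGB; **Y'CbCr** uses the raw 8-bit channels, as
  its transform is conventionally written. The Y'CbCr matrix used here has
  no +128 chroma offset, so Cb and Cr are centered at 0 and normalized
  from [−127.5, 127.5].
* **XYZ** applies the sRGB-style gamma correction γ(t) (linear below
  t = 0.04045 with slope 1/12.92, else ((t+0.055)/1.055)^2.4) before the
  linear transform. With these printed constants the two branches of γ
  differ by ≈ 2.33 × 10⁻⁹ at the threshold — the well-known kink of the
  rounded sRGB constants (exact continuity would require a threshold of
  ≈ 0.0392857). The tests therefore assert branch continuity at 1e−8, the
  tightest bound the constants themselves allow; φ(t), the L\*a\*b\*
  compression, is exactly continuous at (6/29)³ and is tested at 1e−12.
* **L\*a\*b\* and Luv** use the D65 white point {0.950456, 1.0, 1.088754}.
  The Luv chroma terms are computed exactly as specified with the
  constants k₁ = 0.2009 and k₂ = 0.4610 — *not* the textbook CIELUV
  u′v′ form. At black, L″ = 0 and the chromaticity denominator vanishes;
  u and v are defined as 0 there, removing the 0 · undefined ambiguity.
* **CMYK**: K = 1 − M̃; the ink ratios are 0/0 at black and are defined as
  C = M = Y = 0 (standard convention).

## Normalization bounds

The protocol requires every feature in [0, 1] but does not say how signed
components are mapped. The rule used here is affine:
x_norm = (x − min)/(max − min), clamped, with (min, max) the component's
extrema over the full 8-bit RGB cube. For the linear components these are
analytic (I: ±0.596, Q: ±0.523, Cb/Cr: ±127.5, X: [0, 0.9505], Z:
[0, 1.0890], L\*: [0, 100], …). The a\*/b\* and u/v extrema have no closed
form under the gamma-corrected transform; they were computed once by an
exhaustive scan of all 256³ pixels and frozen as named constants (see
`color_bounds()`). All eight extrema turn out to lie on cube *edges* (two
channels pinned at 0 or 255), which is what lets the test suite re-verify
the frozen constants with a 3072-point edge scan instead of a 16.7M-pixel
sweep. This choice is self-consistent and testable; it is not claimed to
match any particular reference implementation's scaling.

# Regions and aggregation

Two regions are supported: the **entire** mask foreground, and the
**middle** rectangle — the TCM stomach-correspondence area — defined as a
fractional window of the mask's bounding box, by default rows 0.35–0.65
and columns 0.30–0.70. The proportions are a geometric reading of the
usual drawn diagram and are fully configurable (`region_spec()`); indices
are half-open with `floor(fraction × extent)`, so the mapping is
deterministic at every image size. Whether the rectangle should be
relative to the bounding box or to image coordinates is genuinely open;
the bounding box makes the region translation-invariant, which the tests
check.

Aggregation over the region's pixels gives five composite vectors: mean,
median (even counts: mean of the two central order statistics), population
standard deviation σ = sqrt(Σ(f−μ)²/N), and the 50-component
concatenations mean+σ and median+σ (average first). The population
(1/N) normalization is the only reading consistent with the protocol's
"standard deviation" wording; with features bounded in [0, 1] it also
gives the testable bound σ ≤ 0.5.

# Classifiers

All three trainers take an n × p matrix and labels in {−1, +1}, are
deterministic given their seed, and break prediction ties toward +1.

* **AdaBoost** (`train_adaboost()`): discrete AdaBoost over depth-limited
  weighted decision trees (default depth 1 = stumps; rounds T = 50).
  Weights start at D₁(i) = 1/n; a round with weighted error ε ≥ 1/2 stops
  training unstored; ε = 0 is clamped to 1e−10 (finite α) and stops after
  storing. The per-round normalizers Z_t are kept in the model history so
  the training-error bound ∏Z_t is directly testable. The stump search
  considers interior cut points only — constant predictions are the
  majority-leaf fallback — which keeps tied splits usable by deeper trees
  (e.g. depth 2 solves XOR).
* **SVM** (`train_svm()`): polynomial kernel k(x, z) = (x·z + coef)^degree
  (defaults degree 1, coef 1, C 1, tol 1e−3), solved in the dual by
  sequential minimal optimization. The partner for each KKT violator is
  chosen by maximal |E_i − E_j|, falling back through the remaining
  candidates until one makes progress; convergence is declared after
  `max_passes` clean sweeps, and hitting the hard sweep cap returns the
  best iterate with a warning (this happens by design on no-signal data,
  where the dual has no good solution to converge to).
* **MLP** (`train_mlp()`): one sigmoid hidden layer (default
  ceil((p+2)/2) units), two softmax outputs (unit 1 ↔ class +1),
  cross-entropy loss, *online* back-propagation in fixed data order
  (lr 0.01, 500 epochs). Online rather than batch updates: at these
  defaults batch gradient descent is too slow to meet the package's own
  separable-data contract, while per-sample updates — the classic
  formulation — do, and remain deterministic given the seed.

Because the kernel and the gradients are scale-sensitive, SVM and MLP
standardize features to the training fold's mean/sd (stored in the model,
applied at prediction); AdaBoost, being threshold-based, uses raw
features. Both behaviors can be disabled per call. Models serialize to a
versioned JSON document (`model_to_json()`) that reloads to identical
predictions.

# Evaluation

`cross_validate()` uses stratified k-fold assignment (default k = 3):
each class is shuffled under the seed and dealt round-robin, so fold
proportions track the data — important at the 132/68-style imbalance the
cohort emulates. Each fold is tested once against the model trained on the
rest. Per-class F-measures use 0/0 → 0 throughout, keeping the weighted
average total. Fold results are **pooled**: confusion counts are summed
per class before applying the F formulas. Since every sample is tested
exactly once, pooled CA is exactly the fold-size-weighted mean of fold
accuracies, and the identity CA = 100·(TP+TN)/n holds on the pooled counts
(averaging per-fold F instead would lose that identity; per-fold metrics
are still reported for inspection).

# Feature selection

`information_gain_rank()` scores each feature by H(Y) − H(Y | bins), with
bins from Fayyad–Irani MDL recursive binary splitting — the de-facto
standard discretization companion of information-gain ranking. A feature
whose discretization collapses to one bin scores 0; because the cuts
depend only on the induced ordering, the score is invariant to strictly
monotone transforms. `best_first_select()` performs forward best-first
search: a priority list of scored subsets, expansion of the best
unexpanded subset by single-feature additions, stopping after
`stale_limit` (default 5) consecutive non-improving expansions —
`stale_limit = 0` degenerates to pure greedy forward selection. The
default subset evaluator is a CFS-style merit
k·r̄_cf / sqrt(k + k(k−1)·r̄_ff) computed from absolute Pearson
correlations (feature–label with y as ±1, and feature–feature); the
protocol names no evaluator, so this standard best-first companion is a
declared choice, and a wrapper evaluator (e.g. cross-validated weighted F
of a classifier) can be passed instead. On small problems the search
provably matches exhaustive enumeration in the tests.

# The synthetic cohort

`generate_cohort()` produces the *stated world* the acceptance tests run
in: elliptical tongue masks (semi-axes 0.45·H, 0.40·W) on a fixed
(16,16,16) background (so mask = "not background" is exact),
class-conditional body color — positive/Hot (170, 60, 60) red versus
negative/Cold (205, 140, 140) pale red — class-conditional coating color —
yellowish (200, 180, 100) versus whitish (225, 222, 205) — rendered as
random elliptical blobs covering ≈ 40% of the middle region, per-image
color jitter (sd 8) and i.i.d. Gaussian pixel noise (sd 8), with a
132/68 class split. The discriminating channels are separated by well over
3 noise standard deviations, the regime in which the pipeline is expected
to recover the labels (weighted F ≥ 0.9 for all three classifiers); with
the class distributions made identical, performance must fall back to the
majority-class baseline, which is the no-information-leak check. Coating
is rendered as colored blobs, not texture, because only color statistics
feed the features.

What a green test does **not** establish: performance on real tongue
photographs. The generator has no specular highlights, no camera or
illumination variation, no segmentation error, no coating texture, and its
class-conditional distributions are cleanly unimodal — real clinical
separability is far lower, and nothing here estimates it.

# Numerical choices and edge cases

* Channels must be whole numbers in [0, 255]; all arithmetic is double
  precision; normalization happens only at output.
* Degenerate inputs error early: empty masks/regions, single-class
  training data, non-finite MLP loss (with a smaller-lr hint).
* Determinism: generators, fold assignment and all trainers are seeded;
  per-sample seeds derive from the cohort master seed and stay below 2³¹.
* Rasters are ASCII netpbm (PPM P3 / PGM P2): this environment ships no
  PNG codec for R, and the text formats keep every fixture diffable. The
  manifest (CSV) and report (CSV/JSON) formats are unchanged by this
  substitution.

# Known limitations

* The Luv chroma constants are used exactly as specified, so the u/v
  channels are *not* standard CIELUV coordinates; they are consistent
  within the package and normalized by their own cube extrema.
* Best-first selection optimizes the CFS merit, which is only a proxy for
  classifier performance; the selected-versus-whole comparison
  (`run_selection_comparison()`) reports both columns so the proxy's
  failures are visible.
* The middle-region proportions are a documented guess at a drawn figure;
  every experiment records them via its `experiment_config`.
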