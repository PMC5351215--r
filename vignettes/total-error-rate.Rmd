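---
title: "Evaluating cell segmentation with the total error rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cell segmentation with the total error rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terseg)
```

## The model

Supervised evaluation of cell image segmentation starts from matched pairs
of ground-truth (GT) and algorithm-detected (AD) regions. `terseg` reduces
each pair to the pixel-count quadruple `(n_G, n_g, n_A, n_a)` — GT size,
missed pixels, AD size, spurious pixels — constrained by
`n_G − n_g = n_A − n_a = n_I` (the intersection). Five set-theoretic cases
are possible: disjoint (1), identical (2), AD inside GT (3), GT inside AD
(4), partial overlap (5); partial overlap dominates real data.

Per cell, the false-negative rate `r_fn = n_g / n_G` and false-positive
rate `r_fp = n_a / n_A` combine into a misclassification error rate (MER).
The package implements three variants: the self-weighted
`r_w = (r_fn² + r_fp²)/(r_fn + r_fp)` (default; larger errors pay more, and
the degenerate situations where one rate is 0 while the other approaches 1
are scored near 1 rather than near ½), the arithmetic average `r_a`, and
the proportion of misclassified pixels `r_3 = (n_g + n_a)/(n_G + n_A)`.
`r_w ≥ r_a` always, with equality exactly when the rates coincide; we
define `r_w = 0` at `r_fn = r_fp = 0`, its continuous limit.

The algorithm-level **total error rate** is the size-weighted aggregate
`TER = Σ MERᵢ Sᵢ / Σ Sⱼ` with `Sᵢ = n_G` of cell *i* — the weights make
the penalty for mis-segmenting a cell proportional to that cell's share of
the total cell area, and the TER interpretable as the total probability of
misclassification across the image.

Two conventions extend the published definitions to inputs the formulas do
not cover, and both are flagged in output:

* **Absent detection** (`n_A = 0`, no AD object at all for a GT cell):
  treated as a disjoint pair with rates (1, 1). This is a conservative
  extension; disjointness is the only case with an undefined FP rate.
* **Spurious detections** (AD objects overlapping no GT cell) cannot enter
  a measure defined per GT cell; they are excluded from the TER and
  reported separately by `unmatched_ad_objects()`.

## Bootstrap uncertainty

The SE of a single cell's MER comes from a constrained nonparametric
bootstrap (`bootstrap_se_mer()`). Conceptually the AD cell's pixels carry
exchangeable dummy scores — 2 on the FP region, 0 on the intersection —
and a replicate resamples the `n_A` scores with replacement; a draw is
rejected unless the implied intersection fits inside the GT cell
(`n_A − n'_a ≤ n_G`), after which the FN count is forced by the constraint.
Because a replicate depends only on the resampled count of score-2 pixels,
the draw is implemented as a truncated `Binomial(n_A, n_a/n_A)` — exactly
the distribution of the literal resample, at O(1) per replicate. A literal
resampling mode (`method = "literal"`) is retained and tested against the
shortcut. When the AD cell lies strictly inside the GT cell (Case 3) there
are no FP pixels to resample; the GT side is resampled with the mirrored
acceptance rule. Disjoint and identical pairs have SE fixed at 0: their
MERs are the constants 1 and 0.

Numerical choices: the replicate SD uses denominator M − 1 (the standard
sample estimator); the default M = 2000 replications follows established
bootstrap variability practice for ROC-type statistics; the rejection loop
is capped (default 10⁶ draws) and errs rather than silently biasing — the
cap is only reachable when `n_A` vastly exceeds `n_G`, where the acceptance
region has negligible binomial mass. When `n_A ≤ n_G` no draw can be
rejected, which the tests assert directly. An exact enumeration oracle
(`exact_se_mer_oracle()`) computes the population SD of the truncated
binomial replicate distribution; the Monte-Carlo bootstrap is tested
against it within three standard errors of the sample-SD estimator, with
those standard errors derived from the oracle's exact second and fourth
central moments — the tolerance never depends on the code under test.

Per-cell SEs combine into `Var(TER) = Σ wᵢ² SE²ᵢ` under the assumption
that cells are segmented independently, and the CI is the normal
approximation `TER ± z₁₋α/₂·SE` justified by the central-limit structure of
the weighted sum. Bounds are deliberately not clamped to [0, 1]; an
out-of-range bound sets a flag instead, so the user sees that the normal
approximation is strained (relevant only for TERs within ~2 SE of 0 or 1).

Reported relative errors are `1.96·SE / estimate` in percent, and reports
print six decimals, matching the conventions of the reference tables for
this family of statistics.

Because the bootstrap is stochastic, the SE of the TER is itself random.
`se_ter_distribution()` repeats the entire per-cell bootstrap L times
(default 500) and summarizes the L SE values by mean, SD, and a confidence
interval from type-2 sample quantiles (inverse EDF with averaging at
discontinuities — chosen because the distribution of SEs is discrete-ish
and narrow, where interpolating definitions are no better and this one has
an exact inverse-EDF meaning).

## Comparing algorithms

Algorithms evaluated on the same GT cells have correlated TERs.
`ter_correlation()` estimates ρ by synchronized resampling: M
with-replacement resamples of the cell indices are applied *identically*
to both evaluations, each resample yields a paired TER replicate, and the
Pearson correlation over the M pairs estimates ρ; the estimate is averaged
over 10 independent runs by default to damp its own Monte-Carlo noise.
Resampling acts at the level of whole cells (the quadruple records): no
pixel-level resampling happens inside a replicate, because the pairing
that generates the correlation lives at the cell level. Whether an
additional inner pixel-level resampling layer could be intended is
ambiguous in the source material for this method family; cell-level
resampling is the defensible minimal reading and is what the enumeration
oracle in the tests verifies.

The Z statistic `(T̂_A − T̂_B)/√(SE²_A + SE²_B − 2ρ SE_A SE_B)` gives a
two-tailed p from the standard normal; p-values below 1e-300 are reported
as 0 with an underflow flag. A non-positive variance of the difference
(ρ ≈ 1 with equal SEs) raises an explicit degenerate-comparison error, and
identical per-cell MERs short-circuit to "no detectable difference" rather
than attempting a 0/0 statistic. Error-bar classification
(`classify_algorithms()`) places an algorithm in class k when its whole CI
lies between consecutive accuracy criteria; intervals crossing a criterion
are reported as straddling, with the one-algorithm CI test
(`one_algorithm_test()`) as the follow-up.

## The analytic special case

Under the overlap constraint, shifting the boundary pixel by pixel couples
the FN and FP rates into the sweep `((n_g+i)/n_G, (n_a+i)/n_A)`; both
rates are affine in the shift, so their Pearson correlation is exactly 1
(`pair_sweep_correlation()`, verified to 1e-12 over randomized sweeps).
This perfect correlation yields a closed-form SE for the *average* MER,
`(SE_fn + SE_fp)/2` with binomial SEs per rate
(`analytic_se_average_mer()`). The closed form generally *underestimates*
the bootstrap SE; the tests verify this as a tendency (≥ 90% of fixture
cells) on partial-overlap fixtures drawn from an over-detection regime
(FP rate stochastically larger than FN rate, Beta(3, 9) vs Beta(2, 48)),
which mirrors how thresholding segmenters typically err; with FN-dominated
errors the inequality can reverse, which is why it is a tendency and not a
theorem. No analytic SE exists for the weighted MER.

## Mask matching

`match_cells()` builds the bipartite overlap graph between GT and AD
objects — an edge for ≥ 1 shared pixel, the minimal unambiguous threshold —
and pools each connected component (transitive closure via union-find) into
one record, so that fragmented detections of one cell and merged detections
of several cells are both handled, simultaneously. Connected-component
labeling of binary masks supports 4- and 8-connectivity (default 8, the
common choice for cell masks) via an in-package vectorized minimum-label
propagation. Pixels are unit squares on a 0-based row-major grid; no
sub-pixel handling.

## What the synthetic generator does and does not emulate

`simulate_counts()` draws GT sizes log-uniformly over 647–27,562 pixels —
the observed size range of the cultured-cell benchmark data this
methodology targets, so the bootstrap is exercised at realistic counts —
and plants per-cell FN/FP rates, Beta(2, 18) by default (mean 0.1,
matching the error levels of mid-range thresholding segmenters). Planted
rates are realized to within one pixel of rounding per region, which the
tests check exactly. `generate_gt_mask()` and `perturb_mask()` provide the
mask-level analogue: elliptical blobs with low-frequency boundary noise,
perturbed by per-object dilation (plants Case 4), erosion (Case 3),
translation (Case 5), or dropping (Case 1).

What passing these tests shows is that the statistical machinery is
correct *given* pixel counts. What they do not show: real microscopy
effects — intensity-dependent boundary ambiguity, touching cells,
debris — live upstream of the counts and are not simulated; blob shapes
are not cell morphologies (irrelevant downstream, since every statistic
depends on counts alone); and the generator plants rates independently
across cells, whereas real algorithms err in spatially correlated ways.

## Problem sizes and reproducibility

The test suite runs the bootstrap at M = 2000 where it is compared to the
exact oracle, and scales the variability study to a 20-cell evaluation at
L = 100, M = 500 — sizes chosen so the whole suite completes in well under
a minute while keeping Monte-Carlo tolerances meaningful; the acceptance
checks state their tolerances as multiples of exactly computed Monte-Carlo
standard errors, so smaller problem sizes widen, never bias, the check.

Every stochastic routine takes an integer `seed`; per-cell and
per-iteration substreams are derived additively from it, so results are
independent of cell processing order and bit-identical on re-execution,
and the caller's RNG state is always restored. The command-line interface
writes its resolved configuration (including the seed) next to its
outputs; re-running from that file reproduces them exactly.

## Known limitations

* The CI is a normal approximation; no percentile or BCa bootstrap CI for
  the TER is offered.
* Cells are assumed independent in the variance formula; spatially
  correlated errors would make the SE optimistic.
* The TER is silent about spurious detections (reported separately) and
  3-D masks are out of scope.
* No multiple-testing correction is applied across many pairwise
  comparisons; users comparing more than a handful of algorithms should
  adjust p-values themselves.
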