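---
title: "Peri-implant histomorphometry with periomorph: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-implant histomorphometry with periomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periomorph)
```

## The measurement problem

A titanium disc (7 × 1 mm cross-section) sits press-fit in a 5 mm trephine
defect; after 4 or 13 weeks of healing the resin-embedded section is
surface-stained and digitized. Three quantities summarize osseointegration:
bone formation (BF, mm²), bone density (BD, % of a region), and
bone–implant contact (BIC, % of the implant surface covered by bone), each
evaluated both for the whole defect and within a structured peri-implant
zone. A fourth, CD31-positive immunofluorescence area (µm² per field),
proxies angiogenesis. `periomorph` implements these measurements as pure
mask arithmetic on calibrated pixel grids, so every number is an exact
function of segmentations that can themselves be validated against
synthetic ground truth.

## Pixel calibration

All physical quantities derive from one constant: the per-pixel area
(default 17.43 µm²/pixel). The pixel edge is defined as its square root
(≈ 4.175 µm) rather than kept as a second independent constant, so
distances and areas can never disagree. Every generator and every geometric
operation takes the calibration as a parameter; coarser grids (the `scale`
argument of `section_spec()`) multiply the pixel edge while preserving the
physical geometry, which is how the large simulation studies keep their
run times reasonable without changing any biology-side parameter.

## Zone geometry

The peri-implant band is the set of pixels outside the implant whose exact
Euclidean distance (centre-to-centre, via the distance transform) to the
nearest implant pixel is below 300 µm, intersected with the defect. Three
choices deserve justification:

* **Exact distances, not iterated dilation.** 100 µm is ≈ 23.95 pixels at
  the native calibration; counting dilation rounds would quantize the layer
  boundaries differently along diagonals and axes.
* **Half-open layer bins** [0, 100), [100, 200), [200, 300) µm make the
  layer assignment a deterministic function of the distance value; no pixel
  can belong to two layers and boundary ties cannot occur.
* **Sides and sections from the implant's principal axis.** The implant
  cross-section is an elongated trapezoid; its principal axis (PCA of the
  implant pixel coordinates) defines "upper/lower" by the sign of the
  perpendicular offset (ties assigned to upper) and the three axial
  sections by the normalized projection onto the axis, scaled to the
  implant's own extent and clamped to [0, 1] with bins [0, ⅓), [⅓, ⅔),
  [⅔, 1]. Measuring thirds along the implant (not the defect wall) keeps
  the peripheral sections anchored to where the implant meets the cavity
  walls, which is where wall-derived bone first reaches the surface.

The partition always defines 18 region identifiers; clipping can empty a
region (e.g. an implant flush against a wall) but never removes it, so
downstream tables keep a fixed schema.

The BIC surface band enlarges the implant by one pixel with
8-connectivity — 4-connectivity would leave diagonal gaps along the
trapezoid's slanted edges — and removes the implant again. Both the BIC
numerator and denominator use the defect-clipped band: the implant ends
embedded in native bone beyond the cavity walls are not "healing surface",
and using one set for both keeps BIC ≤ 100 by construction. The unclipped
whole-perimeter variant remains available (`clip_to_defect = FALSE`) for
sensitivity analyses.

## Segmentation

Bone is thresholded in HSV (hue window 0.88–1.00, saturation ≥ 0.40, value
0.35–0.95 by default): hue is invariant to overall illumination scaling,
which RGB thresholds are not; an RGB red-dominance rule is provided as a
fallback. The routinely "manually adjusted" thresholds of histomorphometry
are realized as per-image override lists, so a manual adjustment is a
recorded, reproducible object rather than an untracked click. Connected
components below 5 pixels are removed by default (stain specks); oracle
tests set `min_object_px = 0` because the exact-inversion contract is about
the raw thresholds. The implant is the largest connected dark component
(value < 0.20) with holes filled; when no dark component exists the
function errors deliberately, prompting a manual mask.

## The synthetic-section generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's accuracy claims hold.

* **Geometry.** Defect: a vertical 5 mm slot with a semicircular bottom
  (trephine), opening at the top bone surface. Implant: a symmetric
  trapezoid (8 % taper), long axis horizontal, centred at 45 % of the
  defect depth; its 7 mm length crosses the 5 mm cavity so its ends sit in
  native bone, exactly the situation the defect clip exists for.
* **Growth.** Stochastic cellular dilation: candidates are 8-neighbours of
  existing bone (seeded exclusively at the defect walls, excluding the
  periosteum-stripped opening), each mineralizing with probability 0.2 per
  step, multiplied by a conduction bias (default 4, capped at 0.95) inside
  the 100 µm band along the implant. This is the simplest mechanism that
  reproduces the reported healing pattern — bone originating from the
  cavity walls and propagating along the implant surface — while keeping
  monotone growth and implant avoidance true by construction.
* **Rendering.** Compartment colours (Alizarin red/magenta bone, blue soft
  tissue, near-black metal, near-white background, pale native bone) are
  chosen strictly inside/outside the default segmentation windows, so at
  `noise_level = 0` segmentation inverts rendering exactly. The noise model
  is hue/saturation/value jitter, Gaussian blur and additive sensor noise,
  all scaled by one `noise_level` knob; it exercises threshold robustness
  without attempting to model optics.
* **What it does not emulate.** Trabecular microstructure, stain
  heterogeneity within bone, sectioning artefacts, or native bone rendered
  in stain colours outside the defect. Passing the synthetic suite
  therefore demonstrates the correctness of the measurement arithmetic and
  the robustness margin of the thresholds — not segmentation performance on
  real histology, which manual overrides exist to absorb.

## The synthetic study and its statistical operating characteristics

`gen_study()` crosses 10 surface conditions × 12 animals × 2 timepoints
(minus configurable lost discs; a lost disc flags its animal–timepoint
block incomplete, and Friedman drops incomplete blocks listwise rather than
imputing). Each disc receives a target immediate-layer bone fraction from a
logit-normal model: timepoint baseline (0.10 at 4 weeks, 0.30 at 13 weeks,
matching low early zone densities and substantially filled late defects) +
planted condition effects + animal effect (SD 0.25) + disc effect
(SD 0.35), together ≈ 0.10 SD on the fraction scale near the late baseline
— the same 10 % dispersion the study design's own power arithmetic assumed.
Each of the disc's 3–4 cross-sections is an independent growth realization
run until its immediate layer reaches the disc target, then quantified
through the shared zone partition. The skewed, bounded fractions this
produces are deliberately non-normal, which is what routes the pipeline
through its nonparametric branch.

Two Monte-Carlo properties are asserted over this generator: the type-I
error of the Friedman omnibus under a 6-block × 10-condition null
(2000 replicates; the chi-square approximation is known to be mildly
conservative at six blocks, with a long-run rejection rate of about 3.5 %
at the nominal 5 % level), and that a +0.3 planted immediate-layer shift at 13 weeks is
detected against the uncoated-Ti control by the Dunn/Bonferroni post hoc
(all 45 pairs corrected — the behaviour of the standard software's
"Friedman with Bonferroni") in at least 80 % of 200 replicated studies at
n = 12 blocks. The power study runs at `scale = 12` (≈ 50 µm pixels,
112 × 152 px sections, 3–4 sections × 120 discs per replicate), a problem
size chosen so the full 200-replicate experiment is a routine desk run;
the planted-effect loop works at mask level (generator → zones →
morphometry → statistics) since the render → segment stage is validated
separately and is exactly invertible at zero noise.

## Statistics

The Friedman chi-square is computed from within-block midranks with the
standard tie correction (it agrees with `stats::friedman.test` to machine
precision, which the tests assert); post hoc comparisons are Dunn-type z
tests on mean ranks with SE √(k(k+1)/6n), Bonferroni-multiplied by the
number of pairs (all pairs by default, control-only comparisons and paired
Wilcoxon as alternatives). Mann–Whitney uses the exact distribution when
both samples have n ≤ 8 and ties permit, otherwise the tie-corrected
normal approximation. The family-wise design arithmetic (α = 5 %/14 =
0.36 %) is exposed as `bonferroni_alpha()` but not silently applied to the
in-study tests, which report at the conventional 5 % level; conflating the
design-stage and analysis-stage levels would change conclusions, so both
are explicit.

## Release kinetics

Interval sampling follows the medium-exchange schedule (days 1, 2, 3, then
every 3 days to 21). The release law is a delayed burst plus first-order
pool: M(t) = T·[β·1(t>δ) + (1−β)(1−e^{−k(t−δ)⁺})]. Fitting exploits that,
for fixed (k, δ), the law is linear in T·β and T·(1−β): those are profiled
out by nonnegative least squares on the cumulative curve, leaving a 1-D
search over k per candidate δ on a 0.25-day grid, with a local refinement.
Two degeneracies are handled explicitly: an all-zero series returns
T = 0 with the other parameters flagged undefined, and the onset delay is
only identifiable up to the sampling interval that brackets it (a delay
inside a gap trades off exactly against the burst fraction), so ties are
broken towards the smallest delay — which also makes the noiseless
delay-zero fit exact. With interval noise of 5 % of the total, the rate
constant is recovered with a median relative error of roughly 18 % over
repeated series; the information content of nine interval samples under
that noise bounds how much better any least-squares estimator could do.

Per-area normalization uses the exposed disc surface supplied by the
caller: 0.35 cm² for one face (the grouped in vitro mounts expose a single
face), 0.70 cm² for both faces (individual loading for implantation).

## Numerical and degenerate-input conventions

Missing values propagate as `NA`, never as zeros — a lost disc must be
absence, not a zero measurement. Empty regions make BD undefined (`NA`),
an empty surface band makes BIC undefined, an empty implant mask is a
geometry error, and a single-pixel implant cannot define an axis and is
rejected. Seeded determinism is part of every generator's contract
(bit-identical output under a fixed seed), and generators restore the
caller's RNG state.

## Known limitations

Side assignment by perpendicular sign ignores implant curvature (irrelevant
for trapezoids, approximate for bent implants). The axial thirds are
measured along the implant, a documented convention; measuring along the
defect wall would shift section boundaries by a few pixels. Fluorescence
synthesis places circular blobs with a lower-border bias and makes no
attempt at realistic vessel morphology; it exists to give `measure_cd31()`
an exact area oracle. The release fit assumes a single first-order pool;
multi-phase profiles will show structured residuals rather than a failure
flag.
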