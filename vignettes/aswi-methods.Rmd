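---
title: "Methods: the aswi stereo pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the aswi stereo pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aswi)
```

## Problem and assumptions

Given a rectified stereo pair, every left-image pixel `p = (x, y)`
corresponds to right-image pixel `(x − d(p), y)` for some disparity
`d(p) ≥ 0`, and depth follows from `Z = fx · b / d`. `aswi` estimates
`d` densely with a local (window-based) matcher. The package assumes:

- rectified input (epipolar lines horizontal, disparity purely
  horizontal and non-negative);
- RGB images as H×W×3 arrays in [0, 1], row = y, column = x,
  user-facing coordinates 0-based;
- a known candidate range `[d_min_global, d_max_global]` in integer
  levels.

## Pipeline

**Cost.** For each candidate `d`,
`C(p, d) = α · min(TM, M) + (1 − α) · min(TG, G)` with `M` the summed
absolute RGB difference and `G` the absolute difference of horizontal
Sobel gradients (replicate-padded, scaled by 1/8 so gradients live in
[−1, 1]). Truncation makes single-pixel outliers (glare, occlusion)
cost no more than `α·TM + (1−α)·TG`, which is also the value assigned
to candidates without a counterpart and to entries excluded by a range
mask — so an excluded entry looks exactly like a maximally implausible
one, and a mask covering the full range reproduces the unmasked run
bit for bit (a property the tests assert).

**Aggregation.** Each disparity slice is smoothed by the guided filter
with the reference RGB image as guide: within each window the output is
an affine function of the guide, coefficients from the window's 3×3
guide covariance regularised by `eps` on the diagonal, then per-pixel
averaging of coefficients over all covering windows. All means are
separable box filters with border windows shrunk to their in-bounds
part, so the filter is O(n) in pixels and exact at borders. A single
radius `br` is used for both the coefficient windows and the averaging
pass. With an RGB guide whose three channels are identical, the colour
filter equals the scalar filter at regularisation `eps/3` (the rank-one
covariance concentrates the signal; the tests pin this identity), so
the scalar filter is the right mental model.

**Selection.** Winner-takes-all over valid entries (ties go to the
smaller disparity), then a parabola through the costs at the winner and
its two neighbours:
`d* = d + (C(d−1) − C(d+1)) / (2(C(d−1) − 2 C(d) + C(d+1)))`,
applied only where the three points are convex and the winner interior;
the shift never exceeds 0.5 level.

**Postprocessing.** The right-view map is filtered with a weighted
median whose weights are the product of a spatial Gaussian
(`sigma_G`, pixels) and a colour Gaussian on the guide difference
(`sigma_M`, normalised intensity); the weighted median is the smallest
value whose cumulative weight reaches half the total. A left–right
check keeps `p` iff the right map at `(x − round(d_l(p)), y)` is in
bounds and agrees within `lr_tolerance`. Pixels saturated in all three
channels (`≥ glare_threshold`) are invalidated as glare. Invalid pixels
take the smaller of the nearest valid disparities to their left and
right on the scanline — occluded regions belong to the farther
surface — with a column fallback for fully invalid rows. A final
weighted median smooths the filled map.

**Video.** After `warmup_frames` full-range frames, the previous
(fully filled) map is rounded to integer levels — the underlying
matching candidates; sub-pixel shifts are at most half a level — and
windowed min/max extremes, widened by `d_offset` and clamped to the
global bounds, give a per-pixel candidate interval. There is one window
per filtering stage: the separable filter passes reach
`(er+br, er+2·br)`, `(er+br, er+br)`, `(er, er+br)`, and `(er, er)`
pixels in (y, x), so earlier stages use correspondingly wider windows
and every stage finds the entries it needs. The cost volume is computed
on the merged envelope of the four masks; output validity follows the
final stage's mask. Rounding (rather than flooring/ceiling the
sub-pixel values) keeps the masks invariant to sub-millilevel jitter,
which is what lets a static scene reach a bitwise fixed point — with
floor/ceil, an estimate hovering at an integer flips a bound every
frame and the iteration never settles. If a frame's left–right
inconsistency rate exceeds `cut_fraction`, the next frame is treated as
a scene cut and runs at full range.

## Parameters

| name | default | unit | role |
|---|---|---|---|
| `alpha` | 0.1 | — | weight of the colour term vs the gradient term |
| `TM` | 0.0824 | intensity sum | colour-cost truncation (≈ 7/255 per channel × 3) |
| `TG` | 0.0078 | gradient | gradient-cost truncation (≈ 2/255) |
| `er`, `br` | 7, 7 | px | mask window / guided-filter radii |
| `eps` | 1e-4 | intensity² | guided-filter regularisation |
| `d_offset` | 2 | levels | mask widening; bounds tolerated inter-frame motion |
| `sigma_G` | 9 | px | weighted-median spatial scale |
| `sigma_M` | 0.1 | intensity | weighted-median colour scale |
| `median_radius` | 9 | px | weighted-median window radius |
| `lr_tolerance` | 1.0 | levels | left–right agreement tolerance |
| `glare_threshold` | 250/255 | intensity | saturation level counted as glare |
| `warmup_frames` | 5 | frames | full-range frames before masking |
| `cut_fraction` | 0.5 | — | inconsistency rate treated as a scene cut |

Defaults suit frames of roughly VGA size and up. Radii should scale
with resolution: the shipped 24×32 `worked_fixture()` uses
`er = br = median_radius = 3` (≈ width/10) because a 15-px window would
span half that image.

## The synthetic generator

`generate_scene()` emulates the *structure* the matcher relies on, not
endoscope photometrics: disparity surfaces (fronto-parallel plane,
slanted plane, smooth sinusoidal height field, nested step pyramid),
band-limited noise or sinusoid textures, exact visibility-aware warping
(when several left pixels land on one right pixel the largest disparity
wins and the losers are marked occluded), saturated glare discs painted
consistently in both views, and an optional per-frame disparity drift.
Disoccluded right-image pixels show a hidden background texture drawn
once per scene: disocclusion bands never contain a copy of the
occluder (which would create phantom right-view matches), and a static
scene produces identical images every frame. Ground truth and the
occlusion mask are exact by construction; everything is reproducible
from the spec's seed, and the generator saves and restores the caller's
RNG state.

## Problem sizes and cost

The pipeline is O(H·W·D) in time and memory (two cost volumes, left
and right view). A 40×56 pair over 13 levels matches in well under a
second; range masks reduce the per-frame work on video roughly to the
mask width over the full range. Everything is plain R with vectorised
inner loops except the weighted median, which loops over pixels and is
the dominant cost at larger sizes.

## Limitations

- Local matching: untextured or repetitive regions are resolved only as
  far as the guided-filter window carries evidence.
- The scanline fill's min-of-two-sides rule is right at leading edges
  of raised surfaces but leaves a band of background disparity at
  trailing edges (where the fill's valid neighbour on one side belongs
  to the raised surface); the final median shrinks but does not remove
  it.
- The left–right check needs the right-view map, doubling the matching
  work.
- Range masks assume inter-frame motion of at most `d_offset` levels
  outside the windowed extremes; faster motion relies on the scene-cut
  fallback.
- No radiometric calibration: strong exposure differences between the
  views are only absorbed so far by truncation and the gradient term.
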