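---
title: "Measuring femoral sagittal bowing: model, parameters and limitations"
author: "fembow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring femoral sagittal bowing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fembow)
```

## The measurement problem

The femoral shaft is bowed anteriorly. On a lateral radiograph this bow is
quantified as a radius of curvature: the radius of the circle that best fits
the central line of the shaft, in millimetres, with larger radii meaning
straighter bones. Because intramedullary nails are inserted along the canal
and knee-replacement stems occupy the distal third, the clinically useful
description is not one number but four: the radius of the whole shaft and of
its proximal, middle and distal thirds, measured both on the cortical
outline (cortical bow) and on the medullary canal (medullary bow). Reported
radii of current nails (roughly 1.9–3.0 m) exceed most measured anatomies,
and the distal third of Asian femora is particularly bowed, so reproducible
measurement of the per-segment radii matters.

`fembow` implements the computerized pipeline for this measurement. The
operator contributes what humans are good at — tracing the four borders
(upper/lower × outline/canal) and marking three anatomical points — and the
package derives everything else deterministically.

## Landmark construction

Three points are operator inputs: the junctions of the shaft and the
condylar flare on the upper and lower cortical borders (points 1 and 2,
the distal boundary of the measured shaft) and the bottom of the lesser
trochanter on the lower cortical border (point 3, the proximal boundary).

* The **distal end line** is the line through points 1 and 2. Its crossings
  with the canal borders are the distal canal endpoints (a, b); when a wavy
  border crosses more than once, the most distal crossing is used.
* The **proximal end line** passes through point 3 and is chosen so that its
  acute angle to the local tangent of the lower cortical border at point 3
  equals its acute angle to the local tangent of the upper cortical border
  at the crossing point. This "equal-angle" condition formalizes a
  cross-sectional cut through an obliquely projected shaft. The crossing
  with the upper border is point 4; the crossings with the canal borders are
  the proximal canal endpoints (c, d).

The equal-angle direction is found by bisecting the signed angle-difference
over a ±60° range centred on the perpendicular to the lower border's
tangent, to a residual of at most 0.05°. Two situations need explicit
rules, since the defining text of the construction does not fix them:

* **Locally parallel borders.** Every direction then satisfies the
  equality; the perpendicular to the lower tangent is returned. This is the
  limit of the general solution as the borders become parallel and keeps
  the construction deterministic.
* **Multiple roots.** The root nearest that perpendicular is taken.

A border's "local tangent" is likewise not defined by the construction
alone. We use the principal axis (total least squares, so the estimate is
rotation-equivariant) of all border vertices within a window of ±half the
`tangent_window`, whose default spans 21 points of a 300-point uniform
resampling of the border (~7% of its length). Shorter windows follow
tracing noise; much longer ones blur the trochanteric flare into the shaft.

## The central line: equal-speed territory growth

Both trimmed borders are treated as seeds that expand at the same speed;
the set of points they reach simultaneously is the central line. On the
raster grid this is realized *without* iterative dilation: a cell belongs
to the border whose exact Euclidean distance is smaller, and the meeting
locus is the boundary between the two label sets plus any exact-tie cells.
This is mathematically the same meeting condition as simulated growth, but
deterministic and order-independent. Two numerical choices matter:

* **Exact Euclidean distance**, not 4/8-connected chamfer propagation.
  "Same speed" means isotropic growth; chamfer metrics are faster but
  direction-dependent, and their anisotropy (up to ~8% radial error) would
  bias fitted radii.
* **Supersampling.** The grid places `supersample` cells per image pixel
  (default 2). The midline is assembled from midpoints of opposing label
  pairs across cell faces, so its quantization is half a cell; at the
  default the equidistance residual (the largest difference between a
  midline point's distances to the two borders) stays below 1 px, and
  below 0.5 px at `supersample = 4`.

The domain of growth is the region bounded by the two borders and the two
end lines (cells strictly interior to that closed polygon, excluding the
one-cell-wide border rasterizations). Borders that touch or cross raise a
topology error rather than producing a meaningless midline.

The meeting locus is thinned to one point per grid cell, ordered by greedy
nearest-neighbour chaining from the point nearest the proximal end line
(jump tolerance 3 grid cells; a locus that falls apart into more than one
chain is reported as an extraction error), smoothed with a 5-point moving
average to remove raster stair-stepping, and returned in pixel coordinates.

## Radii of curvature

The midline is resampled to 300 uniform points (uniformity is obtained by
iterating interpolation to the equal-chord fixed point, which makes
resampling idempotent) and split into three contiguous segments of equal
arc length. Each curve is fitted with an algebraic least-squares circle
(Kåså) followed by one geometric Gauss–Newton pass on the orthogonal
distances, which removes most of the algebraic fit's small-arc bias; the
reported `rms_residual` is the root-mean-square orthogonal distance. An
all-points fit is used instead of the classical three-point circle because
the latter amplifies tracing noise at the sampled points. Fits are
rejected only for exactly collinear input; radii above 10^5 px are returned
with a `near_straight` flag instead, since on shallow arcs the distinction
between "very straight" and "straight" is below raster resolution.

Millimetre conversion happens in exactly one place:
`mm = px × pixel_spacing / magnification`. The pixel spacing comes from the
DICOM `PixelSpacing` attribute (0.15 mm/px in the reference series). The
magnification default is 1 — i.e. no correction — matching the practice of
the reference study, which reported projection magnification of 1.10–1.20×
but published uncorrected radii; users with a calibration marker can set
the factor explicitly.

## Synthetic phantoms

Because every stage is geometric, phantoms with closed-form truth exercise
the full pipeline:

* `generate_annular_pair()` — two concentric arcs at R ± w/2; the true
  central line is the arc of radius R.
* `generate_three_arc_femur()` — a centerline of three tangent-continuous
  circular arcs of equal arc length with borders offset exactly ±w/2 along
  the normal; the simplest shape consistent with the hockey-stick lateral
  contour of Asian femora. Defaults: segment radii 752/1379/599 mm
  (proximal/middle/distal magnitudes representative of measured Taiwanese
  femora), segment length 110 mm (a ~330 mm measured shaft span, typical
  for an adult femur between the lesser trochanter and the condylar
  flare), border separations 27 mm (cortical outline) and 13 mm (canal),
  pixel spacing 0.15 mm/px. Borders carry an 8 mm overhang beyond the
  landmark ends, as an operator would trace past the anatomical marks —
  without it the equal-angle line could not cross the upper border.
* `generate_repeat_set()` — emulates the repeat-measurement protocol: each
  repeat independently re-jitters all border vertices (and with them the
  three marked points, which sit on border vertices) and re-runs landmark
  construction, midline extraction and fitting.

Tracing noise is modelled as independent isotropic Gaussian jitter on
border vertices. This emulates hand-tracing wobble but **not** systematic
observer differences: a human who re-draws a border tends to deviate
coherently over centimetres (different perceived edge, different window
level), whereas iid jitter averages out over a long border. Consequently
the simulated coefficient of variation of the *whole-shaft* radius
(~0.002 under 1 px jitter) is smaller than any human repeatability, while
segment CVs (~0.01–0.07) land inside empirically observed ranges. Passing
reliability tests therefore demonstrate that the *algorithmic* chain adds
little variance of its own, not that human inter-observer variability is
reproduced. No image intensities are simulated at all — the method consumes
polylines, and photorealistic radiograph synthesis would add nothing to the
geometric validation.

## The packaged reference table

`load_reference_radii()` ships the per-subject radii (rounded averages of
three repeated measurements) of a ten-radiograph validation series (five
women, five men, ages 20–57). One documented quirk: in the printed source,
the per-subject table's "Proximal"/"Distal" column headings are interchanged
relative to the study's own pooled summary table — the pooled means only
reconcile under the swap (e.g. the printed per-subject "proximal outline"
column pools to 452 mm, which the summary table reports as the *distal*
outline radius, consistent with the distal third being the most bowed part
of the outline). The loader's default `"canonical"` labeling applies the
swap so that part names agree with the pooled summaries; `"printed"`
returns the columns exactly as printed. Because the per-subject entries are
themselves rounded to integer mm, recomputed summary cells can differ from
printed ones by up to one unit in the last printed digit; tests compare at
that precision.

Summary statistics use the sample standard deviation (n−1 denominator);
this convention is verified against the printed subgroup SDs, which only
reproduce with n−1. Group comparisons default to Welch's t-test (the safer
choice under unequal variances; the method is recorded in the output), and
outline-vs-canal comparisons are unpaired by default with a `paired`
switch, since the pairing used in the source analyses is not documented.

## Problem sizes used in the checks

The packaged checks run noiseless recovery on three-arc phantoms with
segment radii spanning 300–2000 mm (recovered within 2%; worst case ~0.6%)
and a reliability simulation of 100 seeded re-tracings of the default
phantom (3 repeats each, 1 px jitter, cortical outline), whose per-phantom
mean CVs are required to fall inside the empirically observed band
0.007–0.295 in at least 90% of phantoms. The canal pipeline is identical
code and is exercised by its own recovery tests; simulating one structure
keeps the suite brisk without changing what is demonstrated.

## Known limitations

* The measurement is 2-D: it quantifies the projection of a 3-D bow onto
  the sagittal plane and inherits the radiograph's positioning errors;
  CT-based 3-D curvature is out of scope.
* Borders are operator-traced; there is no automatic edge detection, and
  annotation quality bounds measurement quality.
* Radii are uncorrected for projection magnification unless the user
  supplies a factor.
* The midline is a raster construct; features narrower than one grid cell
  (at the default, half a pixel) are invisible to it.
* Signed curvature and inflection points are not computed; each segment is
  summarized by one unsigned radius.
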