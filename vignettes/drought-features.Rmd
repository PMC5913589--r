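---
title: "Quantifying drought response from RGB imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drought response from RGB imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtfeat)
```

## The measurement problem

Grasses react to water deficit with two macroscopically visible symptoms.
Leaves roll inward (hydronastically, reversibly), which narrows the
projected silhouette; and leaves senesce from the tips, turning yellow —
genotypes that delay this are said to have the *stay-green* trait. Both
symptoms are classically recorded as ordinal visual scores, which are
subjective and hard to compare across observers, sites and dates.
`droughtfeat` computes continuous proxies for both symptoms from ordinary
RGB photographs, either side views of single potted plants or nadir/oblique
views of field plots.

## Pipeline and model

### Segmentation

The plant mask is obtained in HSI colour space with fixed thresholds: hue
inside `[h_min, h_max]` (inclusive; the gate wraps across 0° when
`h_min > h_max`, which green never needs but which keeps the gate general),
saturation at least `s_min`, intensity in `[i_min, i_max]`. The HSI
transform itself is a convention rather than a standard: acquisition
libraries disagree on the exact formulation, so the package fixes the
Gonzalez–Woods arccos form

$$ I = \tfrac{R+G+B}{3},\qquad S = 1 - \tfrac{3\min(R,G,B)}{R+G+B},\qquad
   H = \begin{cases}\theta & B \le G\\ 360-\theta & B > G\end{cases} $$

with $\theta$ the arccos expression on the channel differences, and
documents it as such. Achromatic pixels get $H = 0$; all-black pixels
(channel sum 0) get $S = 0$ and are thus never plant. After thresholding,
8-connected components smaller than `min_region_area` pixels are removed —
8-connectivity because a 4-connected filter would detach diagonal leaf
tips.

### Greenness

On chromaticity-normalised planes $N_r = R/(R{+}G{+}B)$ (and likewise
$N_g$, $N_b$; all three set to 0 at black pixels by convention), the
excess-green and excess-red indices are

$$ ExG = 2N_g - N_r - N_b, \qquad ExR = 1.4\,N_r - N_b . $$

A plant pixel is a *greenness* pixel when $ExG > t_{ExG}$ **and**
$ExR < t_{ExR}$. The double gate matters: yellow tissue keeps a high ExG
(pure yellow has $ExG = 0.5$) and is excluded only by its high ExR
($0.7$). Index planes are computed in double precision; nothing is
quantised before thresholding.

### Morphometry

All four measurements are exact pixel counts on the binary mask, with
0-based coordinates, $x$ = column, $y$ = row, row 0 at the top:

* **area** — number of true pixels;
* **perimeter** — true pixels with at least one false 4-neighbour, the
  raster border counting as false. This boundary-pixel definition is
  deterministic and parameter-free; whether an instrument's edge detector
  counts 4- or 8-neighbour boundaries changes PAR by a few percent on
  diagonal edges, so the convention is fixed here once;
* **bounding rectangle** — axis-aligned, inclusive endpoints;
* **convex hull** — the hull of the true-pixel *centres*, reported as the
  number of pixels whose centre lies inside or on the hull polygon
  (boundary ties broken toward inclusion, for determinism). Collinear
  masks degenerate to the lattice points of the spanning segment.

### Features

$$ GPAR = \frac{\text{greenness area}}{\text{area}},\quad
   TBR = \frac{\text{area}}{\text{bbox area}},\quad
   PAR = \frac{\text{perimeter}}{\text{area}},\quad
   TCR = \frac{\text{area}}{\text{hull area}} $$

all dimensionless (no mm calibration is attempted; none is needed for
ratios of pixel counts from one image). Because the hull is contained in
the bounding rectangle, $TCR \ge TBR$ always. Under controlled conditions
a plant is imaged from several angles; per-view features are averaged
arithmetically, and views whose segmentation comes back empty are dropped
from the mean rather than zero-filled — a zero ratio is not a meaningful
feature value — with the contributing-view count reported.

### Field imagery

Paddy backgrounds (water, wet soil) defeat a hue-only gate, so the
plot-level vegetation mask uses the $ExG$ gate directly (configurable).
Plot GPAR is computed over the whole image; whether a cropped region would
match the original field protocol more closely is not decidable from
available documentation, so the full-image choice is made explicit here.
PAR is computed on the top third of the image rows
(`0 .. floor(height/3) − 1`, rows of the image rather than of the plant
height) where rolled leaf tips dominate and plants do not yet overlap.

### Dynamics and statistics

The first derivative of a daily feature series is $d_i = X_i - X_{i-1}$,
indexed by the later day, defined only between consecutive days with both
values present. Gaps are never interpolated: the intended series are dense
(daily or half-hourly), and interpolation would invent dynamics.

Visible leaf-rolling onset appears as a derivative extremum: a PAR peak
and a TBR/TCR valley. No published combination rule exists for the three
descriptors, so the package uses a majority vote over their extremum days
with ties broken in favour of PAR, PAR being the most robust and sensitive
rolling descriptor (it is least perturbed by single-leaf accidents, which
can move the bounding rectangle or hull wholesale). GPAR is excluded from
the vote — it tracks senescence, not rolling. A descriptor with a flat or
undefined derivative abstains; if all abstain, the result is an explicit
no-onset report. A residual tie among non-PAR candidates resolves to the
earliest day, for determinism.

Group discrimination uses classical one-way ANOVA
($F = MS_{between}/MS_{within}$ on $(k-1, N-k)$ degrees of freedom), with
zero within-group variance reported as an infinite $F$ flagged degenerate
rather than an error. Pearson correlation relates controlled-condition
feature changes (after minus before stress) to field ones. Post-hoc
pairwise testing (Tukey HSD) is deliberately not implemented: the
discrimination claim rests on the omnibus $F$.

## The synthetic generator

No public image archive accompanies this problem, so validation rests on
a seeded generator (`synthetic_plant_spec()`, `render_plant()`,
`render_series()`, `render_field_plot()`) that draws a fan of curved,
tapering leaves from a basal point and returns exact ground-truth masks.
Its encoding of the two symptoms is deliberately minimal:

* **rolling** is silhouette narrowing — `leaf_width` shrinks. The shape
  descriptors only ever see projected geometry, so a 3-D leaf model would
  add nothing they could detect;
* **senescence** is tip-down yellowing — the `1 − green_fraction` share of
  plant pixels farthest along their leaf turns yellow;
* **noise** is green specks placed outside a one-pixel dilation of the
  plant, sized to be removed by the region-area filter.

The palette — green (30,160,60), yellow (200,210,40), blue background
(40,60,160) for the single-plant rig, brown (120,90,60) for field plots —
was chosen so that every class is unambiguous under the default
thresholds: the yellow's arccos-HSI hue is 63°, safely inside the default
60–180° plant gate (a slightly redder yellow would fall below 60° and
leak out of the plant mask), while its $ExR = 0.53$ keeps it out of the
greenness mask; the brown background has $ExG = 0$ and hue 30°, invisible
to both gates. All randomness (leaf angles, lengths, speck placement)
flows through one locally scoped seeded RNG; the global random state is
untouched and identical spec + seed renders bit-identically.

Default study conditions used by the tests and the acceptance script:
13-day series with onset days 4–9 and a width trajectory that is flat
before onset, drops sharply at onset and declines gently after (the sharp
drop is the "visible rolling" event the derivative detector looks for);
discrimination trials of 20 resistant vs 20 sensitive plants, drawn from
one common distribution before stress (leaf width 12–14 px, green
fraction 0.93–0.97) and diverging after stress (resistant: width halved,
green fraction −0.05..−0.11; sensitive: width ×0.94–1.0, green fraction
−0.30..−0.40); a 10-level leaf-width sweep from 13 px down to 4 px at a
fixed seed; images of 160×160 px with 7 leaves of nominal length 60 px.
These sizes keep a full validation run around a minute on one core while
leaving every effect far above rasterisation noise.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: lighting and shadow, soil texture and specular
water, panicles and stems, overlapping neighbour plants within field-plot
cells, camera distortion, and colour drift. Threshold defaults
(`h_min = 60, h_max = 180, s_min = 0.15, i_min = 20, i_max = 255,
min_region_area = 50, t_{ExG} = t_{ExR} = 0.10`) are therefore explicitly
rig-specific: on real imagery they are starting points to be overridden
from a YAML/JSON config, not calibrated constants.

## Numerical choices and degenerate inputs

* Black pixels (channel sum 0): chromaticity 0, $S = 0$, $H = 0$, hence
  background everywhere downstream.
* Achromatic pixels: $H = 0$ by convention.
* Empty plant mask: a typed `no_plant_error` condition, so batch drivers
  can record a missing row instead of fake zeros.
* Hull inclusion: pixel-centre test with on-boundary counted inside; all
  arithmetic on integer coordinates is exact in doubles at raster scales.
* ANOVA with zero within-group variance but non-zero between: $F = \infty$,
  $p = 0$, `degenerate = TRUE`; fully constant input is rejected.
* Pearson correlation: pairwise deletion of missing pairs; fewer than 3
  complete pairs or zero variance is an error, not an `NA`.

## Known limitations

Projected-silhouette features cannot separate rolling from wilting or
leaf-angle change, and GPAR conflates senescence with any non-green
discolouration. The features are ratios within one image and so are
robust to scale, but not to severe perspective or occlusion; field PAR in
particular assumes the top third of the frame holds unoccluded leaf tips.
The segmentation is threshold-based by design — learned segmentation is
out of scope — so heavy shadows or colour casts on real imagery require
re-tuning the config rather than expecting the defaults to hold.
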