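---
title: "Measuring the fetal cardiac axis and cardiothoracic ratio from segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the fetal cardiac axis and cardiothoracic ratio from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourchamber)
```

## The measurement problem

The four-chamber view is the central plane of fetal echocardiographic
screening. Two biometrics summarize cardiac position and size in that plane:

* the **cardiac axis (CAx)**: the angle between the long axis of the
  interventricular septum and the anteroposterior (AP) axis of the thorax
  (the line from the spine through the anterior chest wall). Deviations are
  associated with outflow-tract anomalies, diaphragmatic hernia and other
  conditions.
* the **cardiothoracic ratio (CTR)**: the ratio of heart area to thoracic
  area, a marker of cardiomegaly and fetal cardiovascular compromise.

Both are defined on anatomy, not on pixels, so once a pixel-level label map
of the view exists — from a segmentation network or a human annotator — the
biometrics should be computed from the masks by a deterministic geometric
procedure. This package implements that procedure for the 15-label annotation
scheme (four chambers, interventricular and interatrial septum, two
ventricular walls, two lungs, descending aorta, spine, ribs, and the heart
and thorax area annotations), together with the segmentation metrics and
rater-agreement statistics used to validate automated measurements.

## Conventions

Grids are `H x W` integer matrices indexed 1-based as `(row, col)`, with
pixel centers at integer coordinates — the native R matrix convention, also
used by EBImage. Row 1 is the image top; the phantom places "anterior" there.
Pixel spacing `(row_mm, col_mm)` defaults to 1 mm isotropic; it is carried by
NIfTI headers (`pixdim`) and by the PNG pHYs chunk, so label maps round-trip
losslessly on both grid and spacing. Because the heart-area and thorax-area
annotations overlap the structural labels spatially but a grid is
single-valued, a label map can carry the two area labels in an aligned second
layer (`*_area.*` file); `extract_mask()` consults it transparently, and the
thorax-area mask includes heart-area pixels (the heart lies inside the
thorax).

## Cardiac axis

Pipeline, applied to the label map:

1. **Septal mask**: interventricular septum label, largest 8-connected
   component. Ties on component size are broken by the earliest foreground
   pixel in row-major order, for determinism.
2. **Skeleton**: Zhang–Suen topological thinning to a one-pixel medial line.
   Thinning preserves connectivity and never moves points outside the mask.
3. **Pruning**: the skeleton pixels are treated as an 8-connected graph with
   Euclidean edge weights, and only the longest shortest path (the graph
   diameter) is kept. Real septa produce short side branches where papillary
   structure or noise widens the mask; pruning prevents those branches from
   biasing the line fit.
4. **Line fit**: total (orthogonal) least squares — the line through the
   centroid along the principal eigenvector of the coordinate covariance,
   computed by SVD. Ordinary regression is undefined for vertical lines, and
   near-vertical septa are common; the orthogonal fit treats all orientations
   identically. An isotropic point cloud (equal singular values) has no
   principal direction and is rejected as degenerate.
5. **AP axis**: the line through the centers of mass of the thorax and spine
   masks, oriented spine → thorax (posterior → anterior). "Center-of-mass
   lines" admits more than one reading (e.g. per-row centroid traces); the
   two-centroid line is the simplest estimator that is exact for any
   symmetric thorax and is what we implement.
6. **Angle**: `arccos(|u_septal . u_AP|)`, the acute angle in [0, 90]°. A
   signed variant (positive when the apex points to the image left of the AP
   axis) is reported alongside, from the 2-D cross product of the two
   directions, but the unsigned acute angle is the primary output, matching
   clinical reporting ranges.

With anisotropic spacing, coordinates are mapped to physical units before
both fits (angles are not invariant under anisotropic scaling); a warning is
recorded, as is a skeleton of fewer than 10 points.

## Cardiothoracic ratio

For each of the heart and thorax masks: largest component → ordered outer
contour (Moore tracing, 8-connected, no sub-pixel refinement — the ellipse
fit averages boundary quantization) → direct least-squares ellipse fit. The
fit solves the algebraic conic problem with the elliptical constraint
`4AC − B² = 1` via the numerically stable block decomposition, after
centering and scaling the points for conditioning; it recovers noiseless
ellipse parameters to machine precision and raises an error (rather than
returning a bounding box) when the best conic is not an ellipse, e.g. for
collinear input. The CTR is the ratio of the two ellipse areas, which makes
it invariant under rotation, translation and any axis-aligned scaling —
including anisotropic pixel spacing, which therefore needs no correction.

When the dedicated area annotations are absent (a prediction may omit them),
the heart falls back to the union of the four chambers, both septa and both
ventricular walls, and the thorax to the union of all non-background labels.
Both paths go through the same ellipse pipeline.

## Segmentation metrics

Per-label Dice and IoU with their class means mDice/mIoU. Two conventions
needed fixing:

* a label empty in **both** maps carries no information and is excluded from
  the class means (the class count reflects scored labels only) — relevant
  for ribs, which are variably present in real views; a label empty in
  exactly one map scores 0.
* across a test set, scores are aggregated per image first (class mean within
  the image), then averaged over images; per-label table cells are per-label
  means over the images where the label was scored. Percent formatting is a
  concern of the command-line layer only.

The identity `IoU = Dice / (2 − Dice)` links the two metrics per label and is
used as a cross-check in the test suite.

## Agreement statistics

Measurements by a human rater and the automated pipeline, paired by case:

* **Normality gate**: Shapiro–Wilk on the paired differences; `p > α`
  (α = 0.05) routes to the paired t-test, otherwise to the Wilcoxon
  signed-rank test. The differences are what the t-test assumes normal, so
  the gate is applied to them. All-identical differences are degenerate: the
  report then carries `p = 1` (zero offset) or `p = 0` (non-zero offset) with
  a warning rather than an error.
* **Bland–Altman**: bias = mean(rater − model); 95% limits of agreement
  `bias ± 1.96·SD` (no small-sample LoA correction); bias CI from the t
  distribution with n − 1 degrees of freedom.
* **ICC(2,1)**: two-way random-effects, absolute-agreement,
  single-measurement, from the two-way ANOVA mean squares, with the standard
  F-based 95% CI. The absolute-agreement form is the right question here —
  whether the model is interchangeable with a rater — and, unlike the
  consistency form ICC(3,1), it penalizes systematic offsets; a constant
  shift between columns lowers it below 1. Perfect agreement short-circuits
  the CI construction (which is otherwise 0/0) to a degenerate interval.

## The synthetic phantom

The phantom provides label maps with *known* CAx and CTR, which no clinical
image can. Geometry: an axis-aligned elliptical thorax (72% × 62% of the
field of view by default); a spine disc on the posterior midline, so the true
AP axis is exactly vertical; a heart ellipse whose major axis makes the
requested angle with the AP axis (apex anterior-left); a septal band of
configurable thickness along the heart's major axis (ventricular part =
interventricular septum, atrial part = interatrial septum, atria occupying
the posterior 40% of the long axis); thin ventricular-wall shells on the
anterior boundary ring; lungs filling the remaining thoracic space split at
the midline; a descending-aorta disc anterior-left of the spine; and short
rib arcs on the thorax boundary ring. The heart/thorax area layer stores the
exact filled ellipses, so `true_ctr = (heart_major × heart_minor) /
(thorax_major × thorax_minor)` by construction.

Structure sizes default to image-relative values (spine radius ≈ 2.3% and
septum thickness ≈ 1.8% of the image side — 12 px and 9 px at 512²), and the
heart center sits 6 px anterior of the thorax center so the heart clears the
spine across the whole tested CTR range. Boundary jitter, when requested, is
seeded smooth periodic radial noise (48 angular knots, linear periodic
interpolation) added to the thorax and heart inside-tests; a radial
perturbation keeps every region star-convex and simply connected, which
salt-and-pepper pixel noise would not. Infeasible requests (heart crossing
the thorax boundary or overlapping the spine, septum thicker than the heart)
raise errors.

What the phantom deliberately does **not** emulate: ultrasound texture,
shadowing and speckle; realistic chamber proportions (the atria/ventricle
split is fixed and clinically naive — irrelevant to CAx/CTR correctness);
pathological anatomies; and non-elliptical organ outlines beyond the jitter
model. Passing the recovery tests therefore demonstrates that the *geometry
pipeline* is correct and stable to boundary quantization and moderate
boundary noise — not that any segmentation model is accurate on clinical
images.

`degrade_prediction()` turns a phantom into an imperfect "prediction" for
metric testing: per-label disc erosion (default) or background-only dilation,
seeded random pixel dropout, and whole-label dropout. Erosion with growing
radius degrades mDice monotonically, which the tests exploit.

## Validation design and problem sizes

The test suite and `scripts/acceptance.R` validate the pipeline with
independent oracles rather than stored expectations wherever possible:
flood-fill component labelling written from scratch, brute-force pixel
counting for Dice/IoU and centroids, the principal axis of a full rectangle
for the skeleton direction, forward-sampled ellipses for the fitter,
closed-form formulas and `aov()` mean squares for Bland–Altman and the ICC,
and 1,000 random candidate lines for the orthogonal-least-squares optimality
check. The acceptance study uses the 8 × 4 phantom grid (CAx 10–80° in 10°
steps × CTR 0.15–0.45 in 0.10 steps) at 512² with zero jitter, 100 random
ellipses, 200 random mask pairs, a 100-pair agreement table, 40 routing
simulations and a 10,000-pair null ICC — sizes at which every check runs in
seconds on one CPU while leaving no tolerance to chance: the observed
recovery errors sit an order of magnitude inside the 2° / 3% acceptance
bands.

Note that the normality-gate routing check measures the behavior of the
gating *rule*: the Shapiro–Wilk test has its nominal 5% type-I error, so a
Gaussian table is occasionally (correctly, per the rule) routed to Wilcoxon.

## Known limitations

* The AP axis uses the two-centroid construction; annotation styles in which
  the spine mask is strongly asymmetric about the thoracic midline would bias
  it relative to a per-row-centroid construction.
* The septal long axis assumes the septum is an elongated structure; on
  near-isotropic septal masks (severe truncation) the line fit is rejected as
  degenerate rather than guessed.
* Ellipse fits are algebraic least squares, not geometric-distance fits; for
  the smooth, densely sampled contours produced by masks the difference is
  negligible, but for very sparse or highly eccentric contours a geometric
  refinement would be more accurate.
* Only 2-D maps are supported (single-slice NIfTI accepted); volumetric
  echocardiography is out of scope.
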