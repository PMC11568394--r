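---
title: "Automatic Cobb-angle measurement from corner keypoints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic Cobb-angle measurement from corner keypoints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobbangle)
```

## The measurement problem

The Cobb angle — the angle between the superior endplate of the most tilted
cranial vertebra and the inferior endplate of the most tilted caudal vertebra
of a scoliotic curve — is the standard quantitative index of scoliosis.
Manual measurement carries 3–5° of intra-observer and 5–7° of inter-observer
variation, much of it from the choice of end vertebrae. Keypoint-detection
models remove the human from that choice: a detector emits four corner points
per vertebra, and everything downstream is geometry. `cobbangle` implements
that downstream geometry, plus the statistics used to validate such a tool
against manual measurement, plus a synthetic-spine generator so the whole
chain can be verified against analytic ground truth without a single
radiograph.

All coordinates are image pixel coordinates: origin top-left, y increasing
caudally, so the superior ("upper") edge of a vertebra has the smaller y.
Corner order is fixed and validated — upper-left, upper-right, lower-right,
lower-left — because a silent reorder would corrupt every endplate line
downstream. Angles are unit-free; pixel spacing is carried as metadata only.

## The pipeline

`measure_spine()` chains four stages.

**1. Centerline by moving least squares.** The spine is modeled as a function
$x(y)$ (the film is assumed roughly upright; this is a documented limitation
for spines tilted beyond ~45°). At each of `grid_size` (default 200) query
ordinates $y$ spanning the centroid range, we fit a local quadratic
minimizing $\sum_i w(y_i - y)\,(x_i - q(y_i))^2$ over the vertebra centroids
and keep its value at $y$. The weight is Gaussian,
$w(d) = \exp(-(d/h)^2)$, with bandwidth $h$ defaulting to twice the median
inter-centroid spacing. Numerically, weights are rescaled so the nearest
centroid has weight one and floored at $10^{-8}$, and each local system is
solved by column-scaled weighted QR. Two consequences worth knowing: the fit
reproduces any straight line or parabola to better than $10^{-9}$ px at
*any* bandwidth (the quadratic-reproduction property of MLS), and the
singular-system fallback to a lower-order local fit, while implemented,
essentially never triggers because the floored weights keep the system full
rank.

**2. Second derivative by global polynomial.** A least-squares polynomial
(default degree 6, fitted on a centered/scaled ordinate for conditioning,
coefficients reported in original pixel coordinates) is fitted to the MLS
samples, and its exact analytic second derivative is evaluated on the grid.
A global fit was chosen over piecewise alternatives because the curve it
differentiates is already smooth and a single polynomial gives a continuous,
analytically differentiable curvature estimate. One caveat, verified
numerically: an even-degree fit of a full sine period can flip the curvature
sign within the outer ~5% of the span near the domain edges; degree 7
restores edge fidelity. The default stays at 6 because segment boundaries
are interior features, and edge vertebrae are pulled into the correct
segment by the ≥2-vertebrae merge rule below. `poly_degree` is exposed for
spines with more than two curves (degree 8 is used in the four-segment test).

**3. Segmentation at inflection points.** Segment boundaries are the sign
changes of the fitted second derivative, linearly interpolated between grid
points. Values with $|x''| < 10^{-12}$ px$^{-1}$ (an absolute dead band;
physiological curvatures are of order $10^{-3}$) are treated as zero so that
numerically straight spines yield one segment rather than noise-driven
crossings. Each vertebra joins the segment containing its centroid; segments
with fewer than two vertebrae are merged into the neighbour with larger mean
curvature magnitude, and same-direction neighbours created by merging are
coalesced. The result always partitions the vertebrae into contiguous runs
of at least two with alternating bending direction.

**4. Exhaustive endplate angle search.** Within each segment, every pair
(superior endplate of vertebra $i$, inferior endplate of vertebra $j$),
$i \le j$, is scored by the intersection angle of the two lines. With edge
slopes $m_1, m_2$ the angle is
$\theta = \arctan\left|\frac{m_1 - m_2}{1 + m_1 m_2}\right|$;
the implementation evaluates the equivalent direction-vector form
$\theta = \arccos|\hat d_1 \cdot \hat d_2|$, which is identical where the
slope form is defined and remains exact for vertical lines. Pairs below the
5° floor are ignored; among survivors the largest angle wins, ties broken by
the longest vertebral span and then the most cranial upper vertebra (the
anatomical convention; the tie-break itself is this package's choice).
Same-vertebra pairs ($i = j$) are allowed and measure single-vertebra
wedging. A segment in which nothing survives the floor contributes no
measurement; a spine with no surviving segment yields an *empty* report with
severity absent — an unmeasurable spine is not a spine with a small curve.

The largest surviving angle is the major curve, the second largest the
minor. Severity is graded from the major angle: mild < 25°,
25° ≤ moderate ≤ 45°, severe > 45°, boundaries honoured exactly.

## The synthetic generator and what it does (not) emulate

`spine_shape_params()` defines a centerline
$x(y) = \sum_i A_i \sin(k_i y + \varphi_i)$ over $y \in [0, L]$ and
`generate_spine()` places rigid rectangles on it: centroids at equal y
spacing (endpoints included, so a half-period sinusoid carries vertebrae at
both slope extrema), endplates exactly perpendicular to the local tangent,
then optional i.i.d. Gaussian corner noise under a fixed seed. Because the
rectangles are rigid and perpendicular, the true Cobb angle of a segment is
exactly the max-minus-min of the tangent angles $\arctan x'(y)$ over its
member centroids — known in closed form, and defined discretely (over
vertebrae, not the continuum) so acceptance comparisons carry no
discretization bias. `spine_shape_for_angle(angle)` inverts this for a
half-period curve via $A k = \tan(\mathrm{angle}/2)$.

Default geometry: 17 vertebrae (a T1–L5 column), 800 px span, 60 × 40 px
vertebrae, i.e. the scale of a full-length standing film at typical export
resolution. Validation problem sizes used throughout the tests and the
acceptance script: a 10–70° grid (step 5°) for noiseless recovery; 200
spines with 1-px corner noise and true angles uniform on 10–70° for the
noise regime; 100 jittered straight spines for floor behaviour; 5000
subjects × 2 raters for the ICC closed form; 802 paired subjects for
Bland-Altman and accuracy; 670 subjects for the offset tables.

What the generator deliberately does **not** model: vertebral rotation,
wedging, endplate curvature, 3D-to-2D projection, rib shadows, detector
failure modes (missed or hallucinated vertebrae), and non-Gaussian or
spatially correlated keypoint error. Passing tests therefore demonstrate
that the *geometry and statistics* are implemented correctly, not that any
detector achieves a particular accuracy on real radiographs.

On clamping: simulated measurements are truncated at 0° (angles are
non-negative) and the count of clamped draws is reported. The ICC
closed-form simulations use a true mean of 50° so that truncation is
negligible (≈2 × 10⁻⁴ tail mass) and the variance-components arithmetic
$\mathrm{ICC} = \sigma_s^2 / (\sigma_s^2 + \sigma_e^2)$ applies cleanly.

One generator error contract is vestigial by construction: because centroids
are placed at equal spacing *in y*, a non-monotone centroid column cannot
arise; the check remains as defensive validation.

## The statistics battery

`icc_absolute_agreement()` implements ICC(2,1) — two-way random effects,
absolute agreement, single measures — via the mean-squares form
$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$,
with the standard F-based confidence interval (Satterthwaite degrees of
freedom) and the F-test of zero subject variance for the p-value. The model
choice is recorded in every result object. The paper-style consistency bands
are fixed cut points: < 0.250 below-poor, 0.250–0.499 poor, 0.500–0.699
moderate, 0.700–0.899 good, ≥ 0.900 excellent. The estimator is
cross-checked in the tests against mean squares from `stats::aov` and
against the classic six-subject four-judge reliability table (published
ICC(2,1) = 0.29). The `grouping` argument selects what forms the columns:
raters (inter-observer), replicates (intra-observer, per rater), or methods
(method comparison) — the last is a surface extension this package adds
because method-wise ICCs are what a validation study reports.

`bland_altman()` uses the fixed 1.96 multiplier (not a t-quantile) and the
n−1 SD, with the LoA identities holding exactly on every output; no CI on
the LoA themselves is reported. `accuracy_rate()` applies a *strict* < 5°
threshold. `stratified_agreement()` assigns severity from the **reference**
method's angle (the reference defines the clinical truth being stratified
on), averages replicates/raters within method per subject, and reports
Bland-Altman, MAE and accuracy overall and per stratum; strata with n < 3
report nulls rather than degenerate statistics. `end_vertebra_offsets()`
tabulates major-curve end-vertebra level differences (A − B, negative = A
more cranial) over −2…+2 plus "other".

## Numerical choices, degenerate inputs, tie-breaks

- Dead band for inflection detection: absolute, $10^{-12}$ px$^{-1}$.
- MLS weight floor $10^{-8}$ (relative to the nearest-point weight).
- Equal maximal angles: longest span, then most cranial upper vertebra.
- A centroid exactly on an inflection belongs to the more cranial segment.
- Coincident edge corners raise a degenerate-edge error naming the vertebra.
- Vertical endplates: slope is NA, direction (0, 1); all angle arithmetic is
  done on direction vectors.
- Annotation JSON is serialized at 17 significant digits so a write/read
  round trip is bit-exact.
- Perfect agreement (MSE = 0) collapses the ICC interval to a point rather
  than producing NaNs.

## Known limitations

The $x(y)$ parametrization assumes a roughly vertical spine; severe axial
tilt (> ~45°) violates it. Segmentation operates on the smoothed MLS curve,
so very short high-frequency curves (single-vertebra "curves") are merged
away by design. Compensatory-curve clinical interpretation, Lenke
classification and sagittal-plane curves are out of scope. The agreement
battery assumes a complete crossed design; incomplete designs are rejected
with the missing cells named rather than silently dropped.
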