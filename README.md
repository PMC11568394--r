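# cobbangle

Fully automatic Cobb-angle measurement for coronal spine radiographs
annotated with four corner keypoints per vertebra, together with the
reliability statistics used to validate such measurements against manual
reads, and a synthetic-spine generator with analytically known curve angles.

The package is for people building or evaluating keypoint-based scoliosis
measurement tools: it takes a detector's output contract (4 points per
vertebra, cranial to caudal) and turns it into clinical quantities — per-curve
Cobb angles with end-vertebra labels, major/minor designation, and severity —
and it quantifies how well two measurement methods or raters agree.

## The algorithm

Given vertebra corner keypoints in image coordinates (origin top-left, y
increasing caudally; corner order UL, UR, LR, LL):

1. **Centerline** — moving least squares through the vertebra centroids:
   at each query ordinate y, a local quadratic is fitted with Gaussian
   weights w(d) = exp(−(d/h)²), h defaulting to 2× the median inter-centroid
   spacing.
2. **Curvature** — a global polynomial (default degree 6) is fitted to the
   smoothed curve and differentiated analytically; sign changes of x″(y) are
   the inflection points.
3. **Segmentation** — vertebrae are partitioned into bending segments
   between inflections (each segment ≥ 2 vertebrae, alternating direction).
4. **Angle search** — within each segment, every pair (superior endplate of
   vertebra i, inferior endplate of vertebra j, i ≤ j) is scored by

   θ = arctan |(m₁ − m₂) / (1 + m₁ m₂)|

   (evaluated in the equivalent direction-vector form arccos|d̂₁·d̂₂|, exact
   for vertical lines). Angles below 5° are ignored; the largest surviving
   pair defines the segment's Cobb angle and its end vertebrae.
5. **Report** — the largest per-segment angle is the major curve, the second
   largest the minor; severity: mild < 25°, 25–45° moderate, > 45° severe.

The agreement battery implements ICC(2,1) (two-way random effects, absolute
agreement, single measures) with F-based confidence intervals and the
poor/moderate/good/excellent bands, Bland-Altman 95% limits of agreement
(mean ± 1.96 SD), mean absolute error, the strict < 5° accuracy rate, and
end-vertebra level-offset tables — overall and stratified by severity of the
reference method.

## Worked example

Generate a noisy S-shaped synthetic spine, measure it, and compare with the
generator's analytic ground truth:

```r
library(cobbangle)

p <- spine_shape_params(centerline = list(c(45, 2 * pi / 800, 0.25)),
                        keypoint_noise_sd = 1, seed = 11)
gs <- generate_spine(p)
measure_spine(gs$annotation)
#> <cobb_report> subject 'synthetic': major 41.0 deg (moderate), minor 38.7 deg, 2 curve(s)
#>   0..7: 41.03 deg
#>   8..16: 38.73 deg
gs$truth$segments
#>   first last    angle
#> 1     1    8 38.18507
#> 2     9   16 38.18507
```

Both lobes of the S-curve are found; with 1-px corner noise the measured
angles sit within ~3° of the 38.19° truth (noiseless input reproduces the
truth to < 10⁻¹³ degrees). Agreement statistics on simulated paired
measurements (two methods, 0.1° bias, 1.75° noise each, 802 subjects):

```r
pm <- simulate_paired_measurements(
  runif(802, 10, 70),
  methods = data.frame(name = c("app", "PACS"), bias = c(0.1, 0), sd = c(1.75, 1.75)),
  seed = 11)
stratified_agreement(pm, method = "app", reference = "PACS")
#> <agreement_report> app vs PACS (reference), n=802
#> ICC 0.990 (95% CI 0.988-0.991), excellent consistency; n=802, k=2, p=0
#>   ICC(2,1) two-way random effects, absolute agreement, single measures
#> Bland-Altman: mean diff 0.18 deg, SD 2.43, 95% LoA -4.60 to 4.95 (n=802)
#> MAE 1.94 deg; accuracy (<5 deg) 96.4% (773/802)
#>   mild: n=199, MAE 1.93, accuracy 96.0%, LoA -4.38 to 4.98
#>   moderate: n=258, MAE 1.89, accuracy 96.5%, LoA -4.31 to 5.03
#>   severe: n=345, MAE 1.97, accuracy 96.5%, LoA -4.92 to 4.84
```

## Command line

A thin CLI wraps the same functions:

```sh
cobbangle simulate --out spines.json --angle 40 --noise-sd 1 --seed 3
cobbangle measure  --input spines.json --out report.json --csv-out report.csv
cobbangle agree    --input measurements.csv --method app --out agreement.json
```

(The script installs to `exec/cobbangle` inside the package library;
`system.file("exec", "cobbangle", package = "cobbangle")` gives the path.)

Annotation files follow the JSON schema in
`inst/extdata/annotation-schema.json`; measurement tables are CSV with
header `subject_id,method,rater,replicate,angle`.

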