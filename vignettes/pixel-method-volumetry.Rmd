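---
title: "Pixel-method tumor volumetry: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-method tumor volumetry: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abusvol)
```

## The measurement model

Automated breast ultrasound reconstructs the breast as a coronal slice
stack with 0.1-cm spacing. The pixel method estimates a tumor's volume by
the Cavalieri principle: if $A_i$ is the cross-sectional area of the tumor
on slice $i$ and $t$ the inter-slice spacing, then

$$V = \sum_i A_i \, t .$$

Each $A_i$ is obtained planimetrically: the tumor is outlined by hand on
the slice image, the $n_i$ pixels inside the outline are counted, and
$A_i = n_i \, r$, where the area ratio $r$ (cm²/px) comes from the image's
own scale annotation — either a bar of known length ($r = (\ell_{cm} /
\ell_{px})^2$) or a square of known area ($r = a_{cm^2} / n_{px}$). Both
calibration routes are provided since ABUS exports carry both forms of the
annotation, and they agree exactly on consistent inputs.

The comparator is the clinical caliper formula
$V_{trad} = L \times W \times H / 2$, with $L$ the largest coronal
diameter, $W$ the largest coronal diameter perpendicular to $L$, and $H$
the anteroposterior diameter. For a true ellipsoid with semi-axes
$(a, b, c)$, exact calipers give $V_{trad} = 4abc$ while the true volume
is $\tfrac{4}{3}\pi abc$, so $V_{true}/V_{trad} = \pi/3 \approx 1.047$:
the caliper formula systematically underestimates ellipsoids by ~4.5%,
which is why a planimetric method tends to read slightly higher.

### Assumptions

- The outline faithfully bounds the tumor on each slice (no segmentation
  is attempted; outlines are inputs).
- Slices are parallel, equally spaced and thin relative to the tumor
  (0.1 cm against 1–5 cm lesions).
- No end correction: a slice contributes $A_i t$ regardless of where the
  tumor surface cuts the slab. This matches the layer model of the
  clinical procedure; for 0.1-cm slices the end effect is well under the
  outlining variability.

## Rasterization conventions

Turning an outline polygon into a pixel count needs a deterministic fill
rule; image editors do not document theirs, so pixel counts taken from
editor screenshots are treated as given inputs rather than reproduction
targets. The package uses scanline even-odd fill with pixel-center
sampling: the pixel with zero-based index $(i, j)$ is set iff its center
$(i{+}0.5,\ j{+}0.5)$ lies inside the polygon under the even-odd rule,
with boundary-coincident centers resolved half-open (left/top inclusive).
This is the common scanline-fill semantics: abutting regions tile without
gaps or double counting, and mirror images have equal counts.
Self-intersecting (hand-drawn) outlines are accepted with a warning and
filled even-odd rather than rejected. The analytic shoelace area of the
polygon is exposed as a diagnostic only — the pixel count is the method.

The test suite checks the rasterizer against an independently coded
brute-force point-in-polygon oracle over random polygons, including
self-intersecting ones.

## Caliper extraction from masks

Where caliper measurements must be derived from a mask stack rather than
read by a clinician, $L$ is the maximum pixel-center-to-pixel-center
chord over all coronal masks (computed over each mask's convex hull), $W$
is the extent perpendicular to the $L$ direction on the slice attaining
$L$, and $H$ is the number of slices spanned by non-empty masks times the
slice thickness — consistent with the layer model used for the volume.
Note that a $k \times k$-pixel block has a center-to-center diagonal of
$(k{-}1)\sqrt{2}$ pixels: caliper lengths from masks are center-based, not
bounding-box-based.

## Agreement statistics and pinned conventions

Paired comparisons (two methods on the same lesions; two observers with
the same method) use:

- **Wilcoxon signed-rank**: absolute differences are mid-ranked; $W_+$ and
  $W_-$ are the rank sums by sign. Zero differences are dropped before
  ranking by default (the classical test); the Pratt variant (rank zeros,
  then discard their rank mass) is available, because inter-observer data
  can contain exact zeros and the two policies can change the p-value.
  The two-sided p-value is exact — the null distribution of $W_+$ over
  all $2^n$ sign assignments, computed by dynamic programming — when
  $n \le 25$ with tie-free ranks, otherwise a normal approximation with
  tie correction and a 0.5 continuity correction. Tests verify the exact
  route against literal $2^n$ enumeration and the approximation against
  the reference implementation in base R.
- **Bland-Altman**: bias = mean difference, sample SD ($n-1$), limits of
  agreement bias $\pm$ 1.96 SD, with points outside the limits flagged.
- **Ratio summary**: per-lesion ratio $a_i/b_i$, reported as mean, sample
  SD and a mean $\mp$ 2 SD dispersion interval (the convention the
  clinical literature prints for method ratios; note $2$, not $1.96$).
- Summary quartiles use linear interpolation of order statistics
  (`quantile` type 5).

Several conventions in the packaged 42-lesion study table are not
self-evident, so they were pinned by checking both candidates against the
printed statistics before the implementation was frozen:

- Inter-observer differences are oriented **Doctor1 − Doctor2** (the
  printed means −0.0016 and −0.194 reproduce only under this orientation).
- The method comparison ranks **pixel-method minus traditional-method**
  absolute inter-observer differences (reproduces $W_- = 879$,
  $W_+ = 24$ exactly, with the conservation identity
  $W_+ + W_- = 42 \cdot 43 / 2 = 903$).
- Ratio statistics use **physician-averaged** volumes per lesion
  (per-physician ratios give means of 1.136 and 1.034, not the printed
  1.073).
- The printed ratio interval 0.541–1.605 equals rounded-mean $\mp$
  2 × rounded-SD; the unrounded lower endpoint is 0.5399. The
  reproduction report applies the rounded arithmetic when issuing its
  verdict and the acceptance script reports the unrounded value.

The published age summary (mean 37.3, minimum 19) disagrees with the
table's own age column (mean 36.98, minimum 18); the reproduction report
carries these rows with a `discrepancy` verdict instead of silently
failing or asserting them. Published p-values are reported by the package
but are not match targets: the inter-observer comparisons contain exact
zero differences, so their p-values depend on the zero policy, which the
source did not state.

## The phantom generator

`generate_phantom()` builds what the measurement chain needs but clinical
data cannot give: slice stacks with exactly known volume. The base shape
is an ellipsoid with semi-axes $(a, b, c)$ cm, sliced at planes
$z_k = -c + (k - \tfrac12)t$ (midpoint sampling; no plane through a pole,
stack symmetric in $z$), each cross-section rendered as a 256-gon and
rasterized at the spec's pixel pitch. Defaults emulate the study
conditions: 0.1-cm slices and lesion diameters in the 1–5 cm range.

The `perturbed_ellipsoid` shape adds band-limited radial noise (a random
cosine series over the polar angle, harmonics 2 and up, scaled to a given
fraction of the local radius) to each slice contour — a stand-in for
irregular lesion outlines and for observer variability. Because such a
shape is *defined* by its per-slice polygons, its ground-truth volume is
the exact shoelace area of each polygon times $t$; this is exact where a
voxelized oracle would only approximate. `perturb_contour()` applies the
same kind of smoothed radial noise to a single outline, with
self-intersection retries at damped amplitude, to emulate two observers
outlining the same lesion. No quantitative observer model is claimed: the
amplitudes are tuning parameters, and a property test asserts only the
qualitative behaviour (inter-observer volume spread grows with
amplitude).

What the phantoms do **not** emulate: speckle, acoustic shadowing,
ill-defined margins, or any segmentation difficulty — passing phantom
tests validates the geometry and statistics pipeline, not outline
placement on real ultrasound.

### Validation results the tests compute

- A sphere of radius 1 cm at 0.01-cm pitch and slicing recovers
  $4\pi/3$ to well under 1%.
- Twenty seeded ellipsoids spanning 1–5 cm coronal lengths at 0.02-cm
  pitch and 0.1-cm slices recover their analytic volumes within 2%.
- The pixel/traditional volume ratio on those phantoms scatters around
  $\pi/3$ within a per-phantom discretization bound of
  $t/2c + p/2a + p/2b + 2\%$ (height off by up to one slice, each
  coronal diameter by up to a pixel).

## Numerical choices and degenerate inputs

- Sub-pixel scale-bar lengths and contour vertices are allowed
  throughout; nothing is quantized before the rasterization step itself.
- Calibration, contours, series and measurements validate their
  invariants at construction and fail with typed messages
  (`invalid calibration`, `invalid contour`, `invalid series`,
  `empty tumor`, `degenerate phantom`, `insufficient data`).
- An all-zero difference vector degenerates the signed-rank test to
  p = 1 with a warning flag rather than an error, so batch pipelines can
  proceed.
- Problem sizes in the default test run are chosen to keep the whole
  suite in tens of seconds: the finest phantom (0.01-cm pitch sphere)
  runs once, and the recovery study uses 20 phantoms at 0.02-cm pitch.

## Known limitations

- No DICOM ingestion, scale-annotation OCR, or automatic segmentation:
  contours, pixel pitches and caliper readings are inputs.
- Cavalieri summation without end correction slightly biases very coarse
  stacks (few slices per tumor); at the 0.1-cm clinical spacing this is
  negligible against outlining variability.
- The Bland-Altman analysis is the classical constant-bias form; no
  regression-based proportional-bias variant is provided.
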