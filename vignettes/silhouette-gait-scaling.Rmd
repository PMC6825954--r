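---
title: "Silhouette-length scaling of rodent gait parameters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silhouette-length scaling of rodent gait parameters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silgait)
```

## The problem

Stride length, body speed and swing speed of walking rodents scale with
body size. In longitudinal studies animals grow over the observation
period, and several transgenic disease models (Huntington-relevant mice,
Parkinson-relevant rats) carry genotype-driven body-size differences, so
a raw group difference in these gait parameters may reflect nothing more
than a size difference. `silgait` measures a body-length proxy — the
*silhouette length* — directly from the walkway video frames that a
markerless gait system records anyway, and divides size-sensitive gait
parameters by it. No anesthesia or manual measurement is needed, and the
size estimate comes from the same run as the gait data.

## Silhouette extraction

A run is an ordered stack of RGB frames plus one background frame of the
empty walkway, with a known resolution $x_{mm}, y_{mm}$ (mm per pixel
along and across the walkway; image columns run along the walkway).

**Analysis window.** Per-paw detection logs give, for each of RF/LF/RH/LH,
the ascending frame indices at which that paw is on the glass. The window
starts when both hind paws have appeared,
$f_{start} = \max\{f_{RH}(1), f_{LH}(1)\}$, and stops when the first
front paw leaves, $f_{stop} = \min\{f_{RF}(last), f_{LF}(last)\}$, so the
whole animal is on the walkway in every analysed frame.

**Foreground.** A pixel is foreground when
$|I_O - I_{BG}| > T_h$ in at least one of the R, G, B channels (strict
inequality, channel-wise OR). The default threshold $T_h = 10$ on the
8-bit scale rejects sensor noise while keeping the dimly lit body; a
difference of exactly 10 is background.

**Tail removal.** The tail would otherwise dominate the length
measurement, so the foreground is opened (erosion then dilation) with a
diamond structuring element — all pixels within Manhattan distance $r_d$
of the origin. The physical radius is matched to the tail: 9 mm for rats,
5 mm for mice. It is converted to pixels with half-up rounding on the
walkway-axis resolution (9 mm at 1 mm/px gives 9 px; 5 mm at 0.7 mm/px
gives 7 px), floored at one pixel. Internally the diamond of radius $r$
is applied as $r$ iterations of the 5-pixel cross, which is exactly
equivalent (Manhattan balls are Minkowski powers of the cross) and much
faster than a direct sweep; the test suite verifies exact agreement with
a brute-force set-arithmetic oracle. Pixels outside the image count as
background for every morphological operation.

**Cleanup and measurement.** Holes in the opened mask are filled (any
background region not 4-connected to the image border becomes
foreground), and only the largest 8-connected component is kept — the
body silhouette. 4-connectivity for holes with 8-connectivity for objects
is the standard complementary pair; using the same connectivity for both
can classify a diagonal gap as simultaneously open and closed. The
silhouette length is the Euclidean distance between the leftmost and
rightmost silhouette pixels along the walkway,

$$ l_{sil} = \sqrt{\{(x_1 - x_2 - r_d)\,x_{mm}\}^2 + \{(y_1 - y_2)\,y_{mm}\}^2 }, $$

with $r_d$ in pixels. The subtraction reflects a property of the
opening: where the tail root (whose diameter the radius was matched to)
joins the body, the opening retains a tail stub about one radius long,
so the raw column span overshoots the nose-to-tail-base length by
roughly $r_d$. Silhouette areas are pixel counts times the pixel area,
without the tail (from the opened mask) and with it (from the
hole-filled largest component of the raw foreground — cleaned rather
than raw, so stray noise blobs do not inflate the area). Per-run values
are the maxima over the per-frame values: frames where the animal is
partly stretched or curled understate the length, and the maximum picks
the most extended posture. In-window frames with an empty mask are
skipped with a warning, since max-aggregation tolerates dropouts.

Degenerate inputs are handled deterministically: if the column span is
smaller than $r_d$ the length is reported as 0; among several pixels in
an extreme column the one nearest the silhouette centroid row is used
(smaller row index on ties); equal-size largest components keep the one
whose first pixel comes earliest in row-major scan order.

## Scaling methods

Eleven gait parameters are carried: front/hind stride length (cm),
front/hind stand, swing and step-cycle times (s), body speed and
front/hind swing speed (cm/s). Left and right paw values are averaged
(body speed over all four paws) before any scaling. Five denominators
are supported:

| method | definition | applies to |
|---|---|---|
| length | $\hat p = p / l_{sil}$ | all parameters |
| froude | $\hat p = p / \sqrt{g\, l_{sil}}$ | speed parameters only |
| area   | $\hat p = p / a_{sil}$ | all parameters |
| weight | $\hat p = p / w$ | all parameters |
| age    | $\hat p = p / a$ | all parameters |

The Froude form is the dimensionless speed used in human gait analysis.
Gravity is kept as $g = 981\ \mathrm{cm/s^2}$ because all speeds are in
cm/s; the unit conversion lives in exactly one place. Age is in weeks,
silhouette length in cm, area in mm², weight in g; length-scaled speeds
carry unit 1/s. Scaling is applied per run and the scaled values are
then averaged per animal and age point — the mean of per-run scaled
values, not the scaled mean; the two differ whenever runs are
heterogeneous, and a regression test pins the order. The body-condition
index $I_{WSL} = w / l_{sil}^2$ (g/cm²) is provided for animals with
weight data; weights are taken as metadata recorded within a week of the
gait acquisition, with no interpolation.

## Evaluation statistics

Scaling quality is judged the way the underlying method was validated:

* **Correlations.** Sample Pearson $r$, $r^2$ and the two-sided p value
  (t distribution on $n-2$ df) between a size factor and each raw or
  scaled gait parameter. A successful size correction drives the
  correlation toward zero.
* **Repeated-measures ANOVA** for the age effect on a complete
  animal-by-age matrix: $F = MS_{age} / MS_{age \times subject}$.
* **Mixed ANOVA** (genotype between, age within): the between-subject
  genotype F is tested against subjects-within-groups; the within
  effects against the age-by-subject residual.
* **Lower-bound adjustment.** Within-subject p values are additionally
  reported under the most conservative sphericity correction,
  $\varepsilon = 1/(k-1)$ for $k$ within levels: the numerator df
  collapses to $\varepsilon (k-1) = 1$ and the denominator df scales by
  $\varepsilon$. At $k = 2$ the adjustment is the identity. The
  sums-of-squares decomposition is computed in-package (the adjusted
  reporting and the degenerate-input contracts below are not available
  from a stock `aov()` call), and the tests verify exact agreement of
  every F and unadjusted p with `aov()` error strata on balanced and
  unbalanced designs.
* **Post hocs.** Per age point, a two-sided two-sample t test of
  transgenic vs wild-type animal means, Bonferroni-corrected across age
  points ($\min(1, p \cdot k)$). Pooled variance is the default — the
  per-age group sizes are small and similar, where pooling is the usual
  choice — with Welch's correction available via `welch = TRUE`.
* **Heat-map tables.** Post hoc results collapse to a parameters-by-age
  matrix of $\mathrm{sign} \cdot (-\log_{10} p_{adj})$, positive where
  the transgenic group is higher, negative where lower, `NA` where a
  cell has fewer than two animals per group.

Within-subject analyses use only animals observed at every age point;
between-subject summaries may use all animals. Degenerate designs follow
fixed contracts: identical within-level means give $F = 0, p = 1$; a
vanishing error stratum with a non-zero effect gives $p = 0$, floored at
1e-300 for display only, never for comparisons.

## The synthetic-data generator

The generator exists so that every pipeline stage can be tested against
known ground truth; its defaults are the study conditions the package is
validated under.

**Renderer.** The body is a capsule: a rectangle with a blunt rump at
the tail base and a half-disk head cap at the nose, so the ground-truth
nose-to-tail-base length is exactly the distance between the two
extremities, and both extremities are wide enough (body width
$\ge 2 r_d$) for the opening to preserve them exactly. The design
deliberately uses a blunt rump rather than a pointed ellipse end: a
sharp rear is partially eroded by the opening, which would conflate
renderer geometry with pipeline error. The tail is a quadratically
curved ribbon tapering from one pixel under the structuring-element
diameter at the root (held for one radius, mimicking the thick tail root
the opening radius is matched to, with half a pixel of rasterization
slack) down to ~2 px at the tip, so the opening removes it and leaves
the expected one-radius stub. Contrast is far above $T_h$ and the
additive pixel noise is clamped below $T_h/2$, making segmentation exact
and attributing any length error to geometry, not thresholding. The
animal translates 6 px per frame; the paw log marks hind paws from frame
2 and front paws until the second-to-last frame, exercising the window
logic. Validation uses 50 renders spanning 80–260 mm with orientation
jitter of ±2° (corridor walking is close to axial): the median absolute
length error must stay within 2 px, and it does with margin (typically
~1.3 px). Resolutions follow the two species profiles (1 mm/px rat,
0.7 mm/px mouse).

**Cohort simulator.** Two genotypes, longitudinal ages (rats: 10, 26,
42, 55, 63 weeks; mice: 21, 32, 46), three runs per animal and age.
Lengths follow species growth trajectories (rats rise to ~228 mm then
dip slightly at advanced age; mice grow 82→89 mm) with a between-animal
random intercept (6 mm rats, 3 mm mice) and 2 mm age-point fluctuation.
Stride is proportional to length (0.75–0.76 cm/cm) and body speed to
$\sqrt{g\,l}$ at a fixed Froude number (0.21 rats, 0.33 mice — chosen to
reproduce the ~30 cm/s walking speeds of both species); both carry
multiplicative log-normal noise, which keeps parameters positive. The
noise sd of 0.075 was calibrated once so that the pooled wild-type
stride-vs-length correlation sits near 0.7, the regime reported for
rats; it was then frozen. Durations are independent of length; swing
speed is stride over swing time per side, so speed inherits the size
coupling indirectly, as in real data. Setting a coupling (or the Froude
number) to zero switches that parameter to a fixed species-typical mean,
giving a true null for decorrelation tests. Weight grows as
$0.040 \cdot l_{cm}^3$ g (isometric; ~426 g for a 22 cm rat, ~25 g for
an 8.5 cm mouse). Genotype acts through a length factor (rats 0.93,
mice 1.05, matching the direction of the two disease models) and,
optionally, through direct per-parameter effects.

What the generator does **not** emulate: paw-print geometry and paw
mislabeling, uneven illumination, reflections and shadows, partial
occlusion at walkway ends, tail kinematics (the rendered tail is rigid
per frame), postural curling (rendered animals are straight, so per-run
max aggregation is exercised only through translation and rasterization
jitter), and missing-data dropout. Passing tests therefore demonstrate
the correctness of the algorithms under controlled geometry and the
stated statistical structure — not robustness to the full variability of
real recordings.

## Statistical design of the validation suite

Two validation bounds concern null correlations and null p values, whose
single-sample variability is larger than the bound itself. At $n = 60$ a
null Pearson r has sampling sd ≈ 0.13, so requiring $|r| < 0.15$ of each
individual replicate would fail by chance about a quarter of the time
regardless of implementation correctness. The suite therefore checks the
non-scaled correlation (far from zero) per replicate, but the scaled
correlation as the mean over five fixed-seed replicates (sampling sd
≈ 0.06). Likewise, a null p value exceeds 0.2 only with probability 0.8,
so "scaled genotype effect not significant, p > 0.2" is required in a
majority (≥3) of five fixed-seed replicates, while the non-null
assertion (raw stride differs, p < 0.05) must hold in all of them. Seeds
1–5 were fixed before any outcome was inspected. The mixed-ANOVA type-I
check runs 200 null simulations and requires the empirical size at
$\alpha = 0.05$ to fall in [0.02, 0.09], the three-sigma band of a
binomial with 200 draws.

Problem sizes used throughout validation — 50 renders for recovery,
cohorts of 12–20 animals per genotype, 200-replicate simulations — are
the package's chosen balance between statistical resolution and keeping
the full suite runnable in well under a minute of morphology work per
render batch.

## Known limitations

* The $r_d$ subtraction corrects the along-walkway span only; for an
  animal walking at an angle the tail stub lies along the body axis and
  the correction slightly over- or under-corrects. The formula is
  implemented literally; at the ±2° typical of corridor walking the
  effect is below a pixel.
* Silhouette length is the projected, walking-posture length; it is a
  proxy for, not identical to, anatomical nose-to-tail-base length.
* The CSV/PNG interchange schema is an open stand-in for proprietary
  acquisition formats; frame extraction from video containers is
  upstream of this package.
* Duration parameters do not correlate with body size and should not be
  length-scaled (scaling them *introduces* a size correlation); the
  package scales them only when explicitly asked.
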