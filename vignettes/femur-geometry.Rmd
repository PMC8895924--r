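---
title: "Methods: proximal femur geometry, the synthetic cohort, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximal femur geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femurmetrics)
```

## The measurement model

`femurmetrics` computes a geometric profile of the proximal femur from 3D
landmarks (mm) rather than images. The profile rests on two skew lines:

- the **neck axis**, the total-least-squares line through the neck station
  centroids plus the sphere-fitted femoral head center, oriented toward the
  head;
- the **proximal shaft axis**, the total-least-squares line through the
  intramedullary canal centroids whose cumulative chord length from the
  proximal entry is at most 100 mm, oriented proximally.

In a real femur these axes do not intersect. Their common perpendicular has
a well-defined length — the **femur neck–shaft axis offset (FNSAO)** — and
the neck axis passes *anterior* to the shaft axis. For lines
$a(s) = p_a + s\,\hat d_a$ and $b(t) = p_b + t\,\hat d_b$:

$$\mathrm{FNSAO} \;=\; \frac{\lvert (p_b - p_a) \cdot (\hat d_a \times \hat d_b)\rvert}{\lVert \hat d_a \times \hat d_b \rVert}.$$

The remaining measures are defined from the same axes:

- **GT to sLSNI** — the signed distance *along* the proximal shaft axis from
  the orthogonal projection of the greater trochanter tip to the axes'
  closest-approach point (the anatomical analogue of the point where a
  cephalomedullary nail's lag screw crosses the nail). The along-axis
  convention (rather than a Euclidean point-to-point distance) matches the
  clinical meaning — insertion depth along the nail — and the way implant
  brochures quote the corresponding implant lengths.
- **Neck axis length** — lateral cortical entry to the head apex, where the
  apex is the fitted head center displaced by the fitted radius along the
  neck direction. Chosen because the clinically compared quantity is the
  lag-screw span from the lateral cortex into the head.
- **Neck-shaft angle (NSA)** — $180^\circ - \angle(\hat d_{neck},
  \hat d_{shaft})$, a full 3D angle and therefore inherently
  anteversion-corrected ("true NSA"), in three variants that differ only in
  the shaft axis: the proximal fit above; the line from the canal entry to
  the canal's point of maximal deviation (half-femur definition); and the
  line from the entry to the distal intercondylar notch (complete-femur
  definition).
- **Anteversion** — the signed angle, in the plane perpendicular to the
  proximal shaft axis, from the posterior condylar axis to the projected
  neck axis; anterior positive, retroversion negative.
- **Radius of curvature** — the circumradius (reported in meters) of the
  proximal-most canal point, the canal's point of maximal perpendicular
  deviation from the entry-to-notch chord, and the distal-most canal point.
  Taking the deviation in 3D makes the measure independent of the plane of
  maximal bow. A numerically straight canal is reported as the 100 m cap
  with a `capped` attribute rather than as infinity, so cohort statistics
  stay finite.

## Coordinate conventions and sidedness

Right femurs use a right-handed patient frame: +X medial, +Y anterior,
+Z proximal. Left femurs are the mirror image (x negated, side label `L`).
Distances and unsigned angles are mirror-invariant automatically. The one
subtlety is the anteversion *sign*: reflection flips the chirality of the
frame, so the right-hand rotation reference is taken as the proximal shaft
direction for right femurs and its opposite for left femurs. With that
convention "anterior = positive" holds on both sides and the whole
eight-measure battery is invariant under `mirror_x()` to 1e-9, which the
test suite asserts as a property.

## The synthetic generator as a stated world

`generate_specimen()` emits the landmark set implied by a parameter record:
a circular-arc canal centerline (equal arc-length stations, anterior bow,
sagittal plane), condyles placed so the posterior condylar axis is exactly
the mediolateral direction, a neck axis constructed at the encoded NSA and
anteversion and displaced by the encoded offset along the common
perpendicular, a spherical head sampled on a deterministic golden-spiral
lattice, and isotropic Gaussian placement noise (default sd 0.5 mm,
emulating sub-millimeter-slice CT landmarking error) added to every emitted
coordinate.

Two design choices deserve explanation:

- **The proximal axis is operational, not analytic.** The generator defines
  its reference shaft axis by running the *same* 100 mm total-least-squares
  fit the measurement stage uses, rather than using the arc tangent. An arc
  tangent and a fitted secant differ by roughly $s/(2R) \approx 2.4^\circ$
  at $R = 1.2$ m, which would make exact round-trips impossible. Real
  image-based protocols likewise measure their reference axes from the same
  data they measure angles on.
- **Adaptive head-center offset.** The distance from the common
  perpendicular's neck-axis foot to the head center defaults to 55 mm, but
  a draw of the neck-length distribution four standard deviations below its
  mean (64.5 mm) would then leave no room for a lateral entry point.
  Truncating the neck-length distribution instead would bias its mean by
  about +0.5 mm. The cohort generator therefore shortens the offset for
  short necks (`min(55, length − head radius − 5)` mm), keeping the drawn
  distribution symmetric and the geometry valid.

`generate_cohort()` draws each femur's truths *independently* per measure
from normal distributions truncated at mean ± 4 sd (clipped further only by
physiologic hard bounds: offset ≥ 0 mm, curvature radius ≥ 0.5 m; both
clips shift the means by well under the recovery tolerances). Defaults are
the published whole-cohort values; `stratify_by_sex = TRUE` switches to the
published sex-specific means and sds. Demographic strata default to 56/44
male/female and 49/51 left/right per 100, ages to a truncated normal
(35.2 ± 13.5, range 18–75). Seeds propagate hierarchically — the cohort
seed draws per-specimen noise seeds — so any subset is reproducible.

What the generator does **not** emulate: cortical and medullary surfaces,
canal width, condylar articular geometry, non-sagittal bow planes,
inter-observer landmarking differences, and any age- or sex-dependence of
the *angular* measures (truths are drawn independently, matching the
published finding of no correlation with age). A green recovery test
therefore establishes that the measurement battery inverts the stated
forward model at the stated noise — not that it would reproduce any
particular patient population.

## Numerical choices

- Sphere fit: algebraic linear least squares on the $|x|^2$ expansion —
  deterministic and exact for noise-free spherical samples; adequate at the
  ≤ 1 mm noise this package targets. No iterative refinement, no RANSAC.
- Line fits: SVD principal direction through the centroid; direction sign
  fixed by the input ordering (last point toward first), which makes
  proximal orientation a consequence of the proximal-to-distal landmark
  protocol rather than a heuristic.
- Parallelism tolerance for the skew distance: 1e-9 rad. Parallel neck and
  shaft axes are anatomically impossible, so the flag escalates to an error
  in the measurement layer instead of propagating a meaningless distance.
- Collinearity floor for the circumcircle: triangle area 1e-9 mm²; the
  straight-shaft case is capped at 100 m.
- Ties in the maximal-deviation search break to the smallest index;
  relevant for noisy near-straight arcs.
- All tolerances are centralized in `fm_tolerances()`.

## A known, quantified bias

At 0.5 mm noise the cohort mean of the measured radius of curvature sits
about 0.03–0.05 m *below* the generating mean of 1.2 m. The measurement
takes the maximum deviation over noisy stations; near the bow apex the
true deviation profile is flat (≈ 0.04 mm drop per 10 mm station at
R = 1.2 m), so roughly nine stations compete and the expected maximum of
their noise inflates the sagitta by ≈ 0.6 mm out of 16.7 mm — deflating
the circumradius by ≈ 3%. This is a property of the max-deviation
definition itself at this noise level, not an implementation artifact; the
corresponding recovery assertion in the acceptance suite is intentionally
left failing rather than widened, and the acceptance report publishes the
honestly measured value. All other measures are unbiased to well within
their recovery tolerances.

## Statistics stage

Descriptives report mean, sample sd, and a 95% CI using the t quantile
($\bar x \pm t_{n-1,0.975}\, s/\sqrt n$), plus median and quartiles and a
Shapiro–Wilk normality flag (α = 0.05). Group comparisons use Welch's
t-test when both groups pass the normality gate and a Mann–Whitney U test
(normal approximation, tie correction) otherwise; Welch rather than a
pooled t because the published subgroup sds are visibly unequal.
Correlations use Pearson when both variables pass the gate, Spearman
otherwise. No multiple-testing adjustment is applied, matching the source
analysis. Exact reproduction of printed confidence intervals from rounded
means and sds is not claimed (6.1 ± 1.7 with n = 100 gives [5.77, 6.43]
against a printed [5.7, 6.4]).

## Implant compatibility

The bundled catalog transcribes two cephalomedullary nails (Gamma 3,
InterTAN): NSA options, curvature radii, lag-screw length range, built-in
anteversion, and trochanter-to-interface options. `assess()` reports the
nearest NSA option (ties to the smaller option; out-of-range flag beyond a
configurable 5°, half the catalog's option spacing), curvature mismatch
when the femur's radius is below the smallest nail radius, anteversion
excess, lag-screw coverage of the neck axis length, and the deviation from
the nearest trochanter-to-interface option. Because no current implant has
a design parameter for the neck-shaft axis offset, every report carries an
unconditional `FNSAO_UNCOMPENSATED` flag — a design-gap statement, not a
numeric deviation. The end-cap extension noted in implant brochures is not
modeled.

## Limitations

The landmark inventory is a reconstruction from the measure definitions,
not a published protocol; the anteversion reference plane is defined
operationally (perpendicular to the proximal shaft axis against the
posterior condylar axis) and may differ point-for-point from any given
multiplanar-reconstruction protocol. Synthetic cohorts validate internal
consistency and statistical calibration only.
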