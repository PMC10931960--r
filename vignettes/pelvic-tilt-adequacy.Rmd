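---
title: "Measuring pelvic tilt and the impact of inadequate landmark annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pelvic tilt and the impact of inadequate landmark annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvitilt)
library(dplyr)
```

## The measurement problem

Pelvic tilt (PT) is a sagittal spinopelvic parameter used in hip and spine
surgery planning: the angle between the vertical gravity line and a line
anchored on two pelvic landmarks. Two definitions are in routine use:

* **anatomical (PT~a~)** — the line from the pubic tubercle up to the centre
  of the anterosuperior iliac spines (ASIS), i.e. the anterior pelvic plane
  seen edge-on;
* **mechanical (PT~m~)** — the line from the centre of the femoral heads up
  to the midpoint of the superior sacral endplate.

On a standing sagittal radiograph the gravity line is the image vertical, so
both angles reduce to the signed angle of a landmark line to the vertical.
`pelvitilt` adopts image pixel coordinates (origin top-left, y increasing
downward), reports angles in degrees with **posterior tilt positive**, and
takes a per-dataset `posterior_direction` flag because patients may face
either image direction. PT is an angle, so no physical pixel calibration is
required, and every measurement is invariant to translation and uniform
scaling of the image and equivariant under image rotation (a rotation by
θ shifts every angle by ±θ according to the posterior convention).

The mechanical landmarks can be obtained two ways, mirroring clinical
annotation practice:

* **calculation** — the annotator clicks three points on each femoral-head
  contour and the two ends of the sacral endplate; the head centre is the
  circumcentre of each contour triple (three points determine the circle
  exactly, so no least-squares fit is involved) and the two per-head centres
  are averaged, matching the bicoxofemoral-axis convention; the sacral
  midpoint is the arithmetic midpoint of the endplate ends;
* **estimation** — the annotator clicks the presumed head centre and sacral
  midpoint directly.

PT~a~ exists only as an estimation-method parameter, because both of its
landmarks are single clicked points. The package therefore measures three
parameter variants per annotator and image: `PT_m_cal`, `PT_m_est` and
`PT_a`.

Degenerate geometry is rejected rather than repaired: a contour triple whose
triangle area is below 10^-6^ times its squared longest side (a scale-free
criterion) raises a degenerate-geometry error, and a landmark line whose
"superior" point does not lie strictly above its "inferior" point raises an
orientation error. `compute_pt_all()` converts such failures into warnings
and skips the affected variant so that one bad annotation does not abort a
study.

## The adequacy review and the majority rule

In the study design the package supports, each of five annotators annotates
every image with both methods, and three assessors then review the pooled,
blinded annotations landmark by landmark. A rating either declares all five
annotations satisfactory or flags specific annotations with a reason:
`bad_quality` (the landmark region is poorly visualized), `anomaly` (an
anatomical variant misled the annotator), `outlier` (the annotation is away
from an identifiable target) or `other`.

Ratings are resolved with a majority rule — agreement of at least two of the
three assessors — applied **independently** to three clauses per
(image, landmark):

1. *landmark-wise*: the landmark is inadequate when ≥2 assessors flagged at
   least one of its annotations, not necessarily the same one;
2. *reason-wise*: a reason enters the majority set when ≥2 assessors cited
   it for this landmark, regardless of which annotator each attached it to
   (the review is landmark-level, so two assessors citing the same reason
   for different annotators still agree on the cause);
3. *annotation-wise*: an annotator's annotation is excluded when ≥2
   assessors flagged that same annotator, regardless of reason agreement.

Because the clauses are independent, a landmark can be inadequate with an
empty reason majority and no excluded annotation (two assessors flagging
different annotators for different reasons). The threshold is exposed as
`k` (default 2 of 3; no ties are possible at that design). Assessors review
at the granularity of six review-level landmarks — ASIS centre, pubic
tubercle, and the calculated/estimated femoral-head centre and sacral
midpoint — so flagging the calculated femoral-head centre excludes the
calculated mechanical measurement without distinguishing which head's
contour was at fault.

An excluded (image, landmark, annotator) removes exactly the parameter
variant that consumes that landmark: ASIS centre and pubic tubercle map to
`PT_a`, the calculated centre/midpoint to `PT_m_cal`, the estimated ones to
`PT_m_est`. Flags attached to an image-level problem (for example axial
rotation recorded under `other`) exclude only the flagged landmark, not the
whole image.

## Comparing the full and adequate datasets

For each parameter variant the per-image **case mean** over included
annotators is the analysis unit. Images that lose all five annotators for a
variant are dropped from both series (pairwise deletion). The comparison
reports:

* Pearson's r, with the qualitative bands poor (r < 0.3), fair (0.3–0.5),
  moderate (0.5–0.6), moderate strong (0.6–0.8) and very strong (r > 0.8).
  The defining inequalities are strict on both sides, leaving the cut-points
  themselves unassigned; the package places boundary values in the lower
  band and documents that choice here.
* Mean and maximum absolute paired difference, in degrees.
* A 95% interval on the paired differences. The default is the Bland–Altman
  **limits of agreement**, mean ± 1.96·SD of the differences, which
  describes the spread of per-case discrepancies; reported intervals of that
  shape bracket a near-zero mean while the mean absolute difference stays a
  fraction of a degree, which is not what a standard-error-based CI of the
  mean would produce at n ≈ 115. The SE-based interval
  (mean ± 1.96·SD/√n) remains available via `ci_method = "sem"`.
* A two-sided paired t-test p-value. When the two series are identical the
  t statistic is undefined; the package reports p = 1 and collapses the
  interval to the (zero) mean difference, so the no-exclusion case is an
  exact identity rather than an error.

External validation against a reference series (e.g. technician software
measurements of PT~m~) uses the intraclass correlation coefficient in its
ICC(2,1) form — two-way random effects, absolute agreement, single
measurement — computed from the two-way ANOVA mean squares. Absolute
agreement is the default because a systematic offset between manual and
software measurements should count against agreement; the consistency form
ICC(3,1) is available. Values above 0.9 are read as excellent.

## What the synthetic generator emulates

The generator exists so that every pipeline stage is testable against known
truth. It builds a 2-D stick-figure pelvis, not an image: the pipeline
consumes coordinates, so nothing is rendered.

`pelvis_template()` fixes the geometry (defaults in pixels, chosen once to
resemble a standing sagittal pelvis at EOS-like scale): femoral-head radius
25, head separation 40, femoral centre to sacral midpoint 150, endplate
half-width 25 at 40° inclination, ASIS centre 120 and pubic tubercle 80 from
the femoral centre along the anterior-pelvic-plane line. Template
magnitudes are configuration, not science. Per image, the true tilt is the
template value plus uniform jitter (default ±12°, giving a population SD of
about 7°, typical of adult PT distributions); landmark coordinates are
constructed by inverting the measurement geometry, so the noiseless
round trip recovers the drawn truth to machine precision — this identity is
the generator's defining invariant and is enforced by tests.

`noise_model()` turns the review's reason taxonomy into generative
mechanisms:

* Gaussian click jitter, default SD 2 px per coordinate for every landmark.
* Outlier contamination: with a per-landmark probability the whole landmark
  is displaced by 30–60 px. The ASIS displacement is lateral, emulating the
  dominant clinical failure of overlooking the contralateral iliac spine and
  marking one side rather than the centre. Default probabilities (ASIS 0.08,
  estimated femoral centre 0.07, others 0.015–0.02) were set from the
  qualitative pattern that directly estimated landmarks attract far more
  outliers than contour-derived ones; with five annotators, a per-annotation
  probability p yields an at-least-one-outlier image rate of 1 − (1 − p)^5^,
  which motivates this order of magnitude.
* Bad-quality images (default probability 0.12) multiply every jitter SD by
  3.
* Anomaly images (default probability 0.07) displace the apparent sacral
  endplate upward by 20 px — all annotators consistently mark the offset
  plate, as happens when a transitional vertebra is mistaken for S1.

`assessor_model()` is deliberately simple: an assessor flags an annotation
whose review-level position lies further than 15 px from truth, and
independently flips any verdict with probability 0.05 (a flipped-on flag is
reason `other`). Reasons for genuine flags come from the corruption ledger,
so injected mechanisms are labelled with their own category.

What the generator does **not** emulate: annotator experience or identity
effects, correlated errors between landmarks, BMI or pathology covariates,
image rendering and visual ambiguity, or assessor deliberation. Its
inadequacy *rates* are emergent from the mechanism parameters and are not
calibrated to reproduce any particular study's observed rates. Passing
tests on synthetic data therefore demonstrate the correctness of the
geometry, the adjudication logic and the statistics — not that the noise
model is a faithful portrait of clinical annotation behaviour.

## Numerical and design choices

* Circumcentre via the exact perpendicular-bisector solution; collinearity
  tolerance area < 10^-6^ × (longest side)², which is scale-free.
* "Centre of the femoral heads" with two heads = unweighted midpoint of the
  per-head circumcentres, the only symmetric choice and the bicoxofemoral
  convention.
* The ASIS centre is stored as a single clicked point; the schema does not
  model separate left/right ASIS clicks.
* Overlay rendering follows the convention that round markers are directly
  clicked points and triangles are positions derived by calculation from
  annotated contours; derived markers are drawn only when the contours are
  present and non-degenerate.
* Report tables print percentages and angles at two decimals; underlying
  tibbles keep full precision.
* All randomness flows through integer seeds; `simulate_study()` derives
  stage seeds (seed, seed+1, seed+2) so stages can be replayed
  independently, and every injected corruption is recorded in a ledger.

## Problem sizes used by the test-suite

The suite exercises the geometry with dozens of randomized circles and
rotations at fixed seeds; the majority rule with the exhaustive 2³ assessor
pattern enumeration; the statistics against naive reimplementations on
random paired series; and the full pipeline at 100–200 images × 5
annotators. The expected case-mean accuracy under 1 px jitter is estimated
by averaging 20 independent 100-image replicates, which keeps the
Monte-Carlo standard error of the estimate near 0.003° — small against the
0.2° accuracy bound the package promises under those conditions (the
analytic expectation for `PT_m_est` is √2/150 rad / √5 · √(2/π) ≈ 0.19°,
the least favourable of the three variants at the default 150 px landmark
distance).

## Known limitations

* The pipeline operates purely on coordinates; it cannot detect inadequate
  annotations itself, only adjudicate assessor opinions about them.
* The sign of PT~a~ relative to a neutral anterior pelvic plane is not
  defined; the package reports the generic signed angle to vertical.
* No divergence or 3-D calibration corrections are applied; measurements
  are planar image-space angles.
* The paired t-test and intervals are computed on case means with pairwise
  deletion; other deletion rules would give slightly different n per
  parameter.

## A minimal worked run

```{r pipeline, eval = FALSE}
sim <- simulate_study(n_images = 115, seed = 1)
measurements <- compute_pt_all(sim$landmarks)
report <- run_report(measurements, sim$ratings, n_images = 115)
report$landmark_wise
report$comparison
```
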