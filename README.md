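# pelvitilt

Pelvic tilt (PT) is a routinely templated sagittal spinopelvic parameter in
hip and spine surgery. It is measured by annotating anatomical landmarks on a
standing lateral radiograph, and the annotations are error-prone: poor image
quality, anatomical anomalies and outlying clicks produce measurements that
look fine in aggregate statistics while being wrong for individual patients.
`pelvitilt` is an R package for the quantitative side of that problem. It is
aimed at groups running multi-annotator landmark studies who need to

* compute PT from raw landmark coordinates under both clinical definitions,
* adjudicate a multi-assessor adequacy review by majority rule,
* quantify how excluding the inadequate annotations changes the measured
  parameters, and
* simulate complete annotation studies with known ground truth to validate
  the whole chain.

## The measurements

With the gravity line taken as the image vertical, both PT definitions are
signed angles of a landmark line to the vertical (degrees, posterior tilt
positive):

* **PT_a** (anatomical): pubic tubercle → ASIS centre,
* **PT_m** (mechanical): femoral-head centre → sacral-plate midpoint,

where the mechanical landmarks are either clicked directly (*estimation*) or
derived from bone-contour annotations (*calculation*): the femoral-head
centre as the midpoint of the two per-head circumcentres — for each head the
unique point c with ‖c − x_i‖ = r for the three contour points x₁, x₂, x₃,
solved in closed form from the perpendicular bisectors — and the sacral
midpoint as the arithmetic midpoint of the annotated endplate ends. Three parameter variants result: `PT_m_cal`,
`PT_m_est`, `PT_a`.

A three-assessor review is resolved per (image, landmark) with a ≥2-of-3
majority applied independently to three clauses: landmark-wise inadequacy,
reason-wise majorities (`bad_quality`, `anomaly`, `outlier`, `other`) and
annotation-wise exclusion. Excluded annotations are removed from the
"adequate" dataset, and the full and adequate per-image case means are
compared with Pearson's r (with qualitative strength bands), mean and
maximum absolute difference, Bland–Altman limits of agreement
(mean ± 1.96·SD of the paired differences; an SE-based CI is available), a
paired t-test, and ICC(2,1) against an external reference series.

## Worked example

Simulate a 115-image study with 5 annotators and 3 assessors at the default
noise settings, measure it, and build the report:

```r
library(pelvitilt)

sim          <- simulate_study(n_images = 115, seed = 1)
measurements <- compute_pt_all(sim$landmarks)
report       <- run_report(measurements, sim$ratings, n_images = 115)

report$landmark_wise
#> # A tibble: 7 × 3
#>   landmark                cases percentage
#>   <chr>                   <int>      <dbl>
#> 1 asis_centre                50       43.5
#> 2 pubic_tubercle             25       21.7
#> 3 femoral_head_centre_cal    28       24.4
#> 4 femoral_head_centre_est    43       37.4
#> 5 sacral_midpoint_cal        35       30.4
#> 6 sacral_midpoint_est        27       23.5
#> 7 any_landmark              105       91.3
```

Each row counts the images whose landmark a majority of assessors considered
inadequately annotated; `any_landmark` is the union. The full-versus-adequate
comparison (values rounded to 2 decimals):

```r
report$comparison
#> # A tibble: 3 × 9
#>   parameter n_cases pearson_r r_band      mean_abs_diff max_abs_diff ci_low ci_high
#>   <chr>       <dbl>     <dbl> <chr>               <dbl>        <dbl>  <dbl>   <dbl>
#> 1 PT_a          115      0.97 very_strong          0.9          5.89  -2.93    3.25
#> 2 PT_m_cal      109      0.99 very_strong          0.34         2.24  -1.34    1.34
#> 3 PT_m_est      109      0.97 very_strong          0.95         5.76  -3.68    3.43
```

Read: excluding the majority-flagged annotations changes the case-mean
parameters by a fraction of a degree on average (`mean_abs_diff`) while
individual cases move by several degrees (`max_abs_diff`, limits of
agreement `ci_low`–`ci_high`), and the two datasets remain very strongly
correlated — inadequate annotations hide inside excellent aggregate
statistics. `PT_m_cal/est` lose six images to full exclusion (n = 109).

The same stages are scriptable from a shell via
`inst/scripts/pt-pipeline.R` (`simulate`, `compute`, `report` subcommands),
and `render_overlay()` draws the pooled annotations of an image for visual
review.

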