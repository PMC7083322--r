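# octarep

Repeatability and discrimination analysis of OCTA image binarization.

## The problem

Vessel density metrics from optical coherence tomography angiography
(OCTA) en-face images are computed from a binarized vessel map, so every
reported value is conditional on the binarization threshold. Clinical
studies use either a manual procedure (thresholding at the maximum grey
value inside a free-hand delineation of the foveal avascular zone) or one
of several automated global histogram algorithms — and these choices
change the numbers, their test–retest stability, and their ability to
separate healthy from diseased eyes.

`octarep` is for researchers quantifying macular OCTA scans who need to
choose, or audit, a binarization approach. It implements seven approaches
side by side — Manual, Huang, Li, Otsu, Moments, Mean, Percentile — and
the complete statistical battery for comparing them on paired test–retest
cohorts, plus a synthetic-angiogram generator with known ground truth for
validating the whole pipeline.

## What it computes

From each 8-bit greyscale en-face image (two consecutive acquisitions per
eye, superficial and deep layer):

* a binarization threshold per approach (pixel is vessel iff strictly
  above the threshold),
* vessel density from the binarized map,
  `VD = n(white)^2 / n(all)^2` (the squared white-pixel fraction; the
  plain fraction is available and the convention is recorded in every
  output),
* vessel skeleton density from the Zhang–Suen-thinned map,
  `VSD = n(skeleton) / n(all)^2`.

Per (algorithm, layer, metric) it then computes relative test–retest
differences, the repeatability coefficient
`RC = 1.96 * sqrt(sum((m2 - m1)^2) / n)`, ICC(A,1) with 95% CI, the
Friedman test across algorithms with Wilcoxon post-hoc pairs under
Holm–Bonferroni correction, an age-adjusted regression of the relative
differences, Mann–Whitney healthy-vs-pathology contrasts, age-adjusted
logistic ROC/AUC with Hanley–McNeil intervals and paired DeLong
comparisons, and a Friedman power simulation.

## Worked example

Simulate a 10-eye cohort at the default study conditions (3×3 mm, 1024²
px, paired acquisitions, simulated manual rater), measure all seven
approaches, and run the comparison (about two minutes):

```r
library(octarep)
cfg <- run_config(sim = sim_config(n_healthy = 5, n_pathology = 5, seed = 42),
                  power_reps = 1000)
cohort       <- generate_cohort(cfg$sim)
measurements <- measure_cohort(cohort)          # 10 eyes x 28 rows
report       <- compare_measurements(measurements, cfg)

subset(report$repeatability, metric == "vd" & layer == "superficial")
```

```
  algorithm       rc   icc icc_ci_low icc_ci_high
     Manual 1.93e-02 0.310     -0.424       0.776
      Huang 1.24e-04 1.000      1.000       1.000
         Li 1.23e-05 1.000      1.000       1.000
       Otsu 3.77e-05 1.000      1.000       1.000
    Moments 2.80e-04 1.000      0.998       1.000
       Mean 6.27e-03 0.749      0.296       0.930
 Percentile 2.66e-02 0.490     -0.121       0.840
```

The manual approach's repeatability coefficient is two orders of magnitude
above the histogram-criterion algorithms (Huang, Li, Otsu, Moments): its
threshold is a regional maximum, so a delineation that clips even a few
perifoveal vessel pixels in one acquisition jumps the threshold by tens of
grey levels. Its ICC (0.31) says most of its between-acquisition variance
is measurement noise. The Percentile algorithm is erratic on this small
draw — consistent with its near-zero ICC on clinical data — while Mean
sits in between. Group means separate in the expected direction:

```r
report$group_comparison
```

```
 metric       layer mean_healthy mean_pathology u_statistic       p
     vd superficial     5.71e-02       5.26e-02          23 0.03175
     vd        deep     5.79e-02       4.87e-02          25 0.00794
    vsd superficial     5.40e-08       4.99e-08          20 0.15079
    vsd        deep     5.28e-08       4.65e-08          23 0.03175
```

`write_report(report, "report/")` emits the tables as CSV plus a JSON
summary; every file records the vessel-density convention, ICC model and
seed used.

A command-line interface wraps the same functions
(`inst/exec/octarep simulate|measure|compare`, YAML config), writing
cohorts as PNG images with FAZ polygons in JSON and a seed-complete
manifest CSV.

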