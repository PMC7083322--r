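---
title: "Methods: binarization repeatability and discrimination for OCTA angiograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binarization repeatability and discrimination for OCTA angiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octarep)
```

## The measurement problem

Optical coherence tomography angiography (OCTA) renders retinal perfusion as
8-bit greyscale en-face images. Quantitative endpoints such as vessel
density are computed from a *binarized* vessel map, so every result is
conditional on the choice of binarization threshold. `octarep` implements
seven approaches side by side and quantifies two properties that decide
their scientific usefulness:

* **repeatability** — how stable the endpoint is across two consecutive
  acquisitions of the same eye, and
* **discrimination** — how well the endpoint separates healthy eyes from
  eyes with impaired macular perfusion, after adjusting for age.

The seven approaches are the manual procedure used in much of the OCTA
literature plus six automated global histogram algorithms, named as in the
Fiji/ImageJ auto-threshold menu: Huang, Li, Otsu, Moments, Mean and
Percentile.

## Binarization approaches

All automated algorithms operate on the 256-bin grey-level histogram and
return an integer threshold $T$; a pixel is vessel (white) iff its value is
strictly greater than $T$. Ties in any criterion resolve to the lowest grey
level, and fractional intermediate values are floored, uniformly across
algorithms.

* **Manual.** The foveal avascular zone (FAZ) — a physiologically
  capillary-free region — is delineated free-hand on the superficial-layer
  image; the maximum grey value inside the delineation is the threshold
  (the brightest avascular background bounds the background class). The
  measurement is repeated; if the two thresholds differ by fewer than 5
  grey levels their mean (rounded half up) is used, otherwise a third
  measurement is taken and the median of the three is used. For the deep
  layer the superficial FAZ selection is transferred verbatim to the deep
  image. The combination rule for two close measurements is our recorded
  choice (the repeat protocol itself only defines the three-measurement
  branch).
* **Mean** — floor of the image's mean grey level.
* **Percentile** — the grey level whose cumulative histogram fraction is
  closest to a target $p$ (default $p = 0.5$, the reference-software
  default), candidates restricted to the populated grey range.
* **Otsu** — maximizes the between-class variance
  $\omega_0\omega_1(\mu_0 - \mu_1)^2$ over all 256 splits.
* **Moments** — Tsai's moment-preserving rule: the first three normalized
  grey moments determine the two representative levels of an ideal bilevel
  image and its background fraction $p_0$; the threshold is the level whose
  cumulative fraction is nearest $p_0$. Degenerate moment equations (e.g. a
  single-level histogram) fall back to the mean threshold with a
  degeneracy flag.
* **Huang** — fuzzy thresholding: each candidate $T$ induces memberships
  $\mu_T(g) = 1/(1 + |g - m|/C)$ toward the pixel's class mean $m$, with
  $C$ the populated grey range; the threshold minimizes the
  Shannon-entropy fuzziness $\sum_g c_g S(\mu_T(g))$ (the Shannon form
  rather than Yager's measure, the more common published variant).
* **Li** — minimum cross-entropy. The canonical Li–Tam fixed-point
  iteration runs from the image mean with a 0.5-grey-level tolerance and a
  cap of 100 iterations; because the fixed point can sit a few levels away
  from the true criterion minimum on irregular histograms, the iteration is
  followed by a sweep of the cross-entropy criterion over all valid levels
  and the global minimizer is returned. This guarantees the returned
  threshold attains the criterion optimum, which is the property the test
  suite pins against exhaustive search.

Single-level histograms return that level with a degeneracy flag rather
than erroring, so batch runs survive pathological inputs.

## Vessel metrics

With $n_w$ white pixels among $n$ pixels, vessel density is computed as
printed in the source protocol,

$$VD = \frac{n_w^2}{n^2},$$

i.e. the squared white-pixel fraction. Because part of the OCTA literature
uses the plain fraction $n_w/n$, both conventions are implemented
(`vd_convention = "squared_fraction"` is the default) and the convention
used is stamped into every output table. Whether the printed squaring is
intended or a typesetting artefact cannot be decided from the text alone;
keeping the printed form as default plus an audited switch preserves both
fidelity and comparability.

The binarized map is thinned to 1-pixel-wide centrelines by iterative
Zhang–Suen thinning (8-connectivity, border treated as background,
implemented in C++), and the vessel skeleton density is

$$VSD = \frac{n_{skel}}{n^2},$$

a length-like, calibre-insensitive measure; at $1024^2$ px its magnitude
is of order $10^{-8}$.

## Repeatability statistics

For each (algorithm, layer, metric) stratum the two acquisitions of each
eye form a pair $(m_1, m_2)$:

* **Relative difference** $|m_2 - m_1| / \bigl((m_1 + m_2)/2\bigr)$. The
  pair-mean denominator is our choice (symmetric in the two acquisitions);
  a first-measurement denominator is available as an option.
* **Repeatability coefficient** $RC = 1.96\sqrt{\sum_i (m_{2i} -
  m_{1i})^2 / n}$ — larger is poorer repeatability.
* **ICC** — two-way random-effects, absolute-agreement, single-measures
  (ICC(A,1)), computed from the mean squares of the eye-by-acquisition
  decomposition with the F-distribution 95% interval. This is the common
  default of mainstream statistics packages; the analysis protocol names no
  model, so the model string is recorded in every output. Negative values
  are legitimate (within-eye disagreement exceeding between-eye spread).
* **Friedman test** across algorithms on the per-eye relative differences,
  with Wilcoxon signed-rank post-hoc pairs and Holm–Bonferroni correction
  (corrected values reported as `p_c`). The post-hoc test choice is ours;
  the protocol says only "pair-wise comparisons".
* **Age adjustment** — ordinary least squares of the relative difference on
  age plus one 0/1 indicator per algorithm and *no separate intercept*
  (the seven indicators span it, taking the "seven binary variables"
  design literally); the equivalent intercept + 6-dummy coding is
  available. Rank-deficient designs error with the collinear columns named.
* **Friedman power simulation** — for a given per-algorithm mean/SD
  profile, each replicate draws one normal value per (eye, algorithm) cell
  and the rejection fraction at $\alpha$ estimates power; 10 000
  replicates by default.

Group contrasts (healthy vs pathology) use the Mann–Whitney U test (exact
for at most 8 untied observations per group, normal approximation with tie
correction otherwise); associations across more than two groups use
Kruskal–Wallis. The age association is reported as a Pearson correlation
(Spearman available) — the protocol does not name the coefficient.

## Discrimination

Per (algorithm, layer, metric), the two acquisitions are averaged per eye
and a binary logistic regression of health status on (metric, age) is fit
by maximum likelihood; the fitted probabilities feed an empirical ROC
curve, making the reported AUC age-adjusted. Ties among probabilities are
grouped (diagonal ROC segments, counting one half), so the trapezoidal AUC
equals the tie-aware normalized rank statistic exactly. The 95% CI uses the
Hanley–McNeil exponential approximation truncated to $[0,1]$; paired AUC
comparisons use the DeLong test. On detected complete or quasi-complete
separation the logistic fit is repeated with a small L2 penalty
($\lambda = 10^{-4}$, penalized on the standardized scale so VD at
$10^{-2}$ and VSD at $10^{-8}$ shrink comparably) and flagged. ROC analysis
is in-sample by design, mirroring the study protocol it reproduces; the
AUCs are therefore optimistic and should be read comparatively, not as
out-of-sample performance.

## The synthetic cohort generator

No clinical images are distributed, so the package generates cohorts that
emulate the study's data structure: by default 26 eyes (11 healthy, 15
pathology), each with two consecutive acquisitions of the superficial and
deep layers — 104 images of $3\times3$ mm at $1024^2$ px. The pixel
dimension is not dictated by any protocol; $1024^2$ was chosen once so that
VSD magnitudes land at the $10^{-8}$ scale, and it is configurable.

Each eye gets a vessel network grown outward from the rim of a randomly
shaped FAZ (mean radius 0.3 mm): sprouts extend in jittered segments,
branch with narrower children (widths 4 down to 2 px), and die on leaving
the field or approaching the FAZ. Two structural features matter for the
emulation:

* **Space-filling growth.** A coarse occupancy cap (2 segment endpoints
  per 16-px cell) prevents the heavy overlap a free random walk produces.
  Real en-face capillary beds rarely overlap, and without the cap the
  skeleton length decouples from total vessel length, corrupting VSD. The
  default budget of 4000 segments sits below the cap's saturation so the
  age and pathology effects can bind.
* **A capillary-free perifoveal margin.** Vessels terminate at 1.10 times
  the local FAZ radius. The emulated rater jitters every FAZ vertex
  radially (SD 6 px ≈ 18 µm); with this margin a delineation overshoots
  into the perifoveal capillaries at an intermediate rate (roughly half of
  delineations), which is precisely the regime that makes max-based manual
  thresholding erratic: a caught vessel pixel jumps the threshold by tens
  of grey levels in one acquisition but not the other. Both extreme
  regimes (never catching, always catching) would *understate* the manual
  method's instability.

Images render vessels at grey 140 and background at 60 (deep layer offset
−25, matching the lower deep-layer signal), multiplied by a mean-one
Rayleigh speckle field blended at 0.25 and spatially correlated with a
Gaussian grain of σ = 1.2 px, then clipped to [0, 255]. Correlated grain is
the physically appropriate speckle model — OCT speckle grains span several
pixels — and it matters computationally: with independent per-pixel noise,
every supra-threshold background pixel becomes an isolated skeleton point
and algorithms whose threshold sits inside the background distribution
(Mean, Percentile) acquire a large spurious VSD component. The two
acquisitions of a test–retest pair share the vessel mask and differ only in
the speckle realization.

Aging scales the segment budget down linearly (0.4%/year over ages 20–80,
the order of capillary-density decline reported in OCTA aging studies),
which reproduces a negative age–density correlation. Pathology is modelled
as peripheral capillary dropout: terminal segments are pruned (cascading to
parents) until 25% of segments are gone. Real maculopathies are
heterogeneous; dropout captures only their common denominator of reduced
perfusion density.

All randomness derives from one master seed through a fixed counter
scheme (six seeds per eye: tree, pathology, four renders; rater seeds
drawn separately at measurement time), so any cohort element is
reproducible in isolation.

### What the synthetic data do and do not show

The generator reproduces the *structure* that drives the methodological
comparison: paired acquisitions under independent speckle, an operator in
the loop only for the manual method, age- and disease-graded density.
Passing the pipeline's checks on these cohorts demonstrates that the
implementation measures, aggregates and tests correctly, and that the
qualitative conclusions (manual least repeatable; automated algorithms
discriminate at least as well) follow from that structure. It does not
validate the generator against clinical OCTA appearance: projection
artefacts, segmentation errors, motion lines, vessel-calibre distributions
and real pathology morphology are all absent, and clinical effect sizes
(Table-style means and SDs) should not be read off synthetic cohorts.

## Numerical choices

* Threshold ties resolve to the lowest grey level everywhere; fractional
  thresholds floor. Histogram cumulants are accumulated in double
  precision (a megapixel image overflows 32-bit products).
* Thinning pads with background implicitly (out-of-range neighbours are
  0); deletions within a sub-iteration are computed from the frozen state
  and applied simultaneously.
* Degenerate inputs (single-level histograms, invalid moment roots,
  all-equal paired values, all-tied rank tests) return flagged results or
  the defined limits ($p = 1$, statistic 0) rather than erroring.
* The rater's jittered polygon is redrawn (up to 25 times) if it
  self-intersects or collapses; jitter 0 returns the exact rasterization.
* Problem sizes in the test suite: unit tests run on 192-px cohorts of 2–6
  eyes (every geometric feature present at millisecond cost); the
  headline reproduction runs one full default cohort (26 eyes, $1024^2$
  px); calibration checks use 1000 Monte-Carlo replicates.

## Known limitations

* Exact bit-compatibility with the thresholds of any particular ImageJ
  release is not claimed; the criterion definitions are pinned by
  exhaustive-search tests instead.
* Two eyes of one subject are treated as independent, as in the emulated
  analysis; `subject_id` is recorded so clustered alternatives can be
  added.
* Only PNG raster I/O is provided (losslessly equivalent to the 8-bit
  greyscale bitmaps the protocol exports); BMP containers are not read.
* The CLI reads YAML configuration files.
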