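---
title: "Peripapillary vessel morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peripapillary vessel morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peridisc)
```

This vignette documents the models behind `peridisc`, the tunable
parameters with their defaults and rationale, the numerical choices that
matter for reproducibility, and the limits of what the synthetic-data
tests can show about real images.

## The measurement model

The package quantifies the vasculature in the annulus between one and six
optic-disc radii (ODr) from the disc center. The disc is found on its
segmentation mask by Canny edge detection followed by a circular Hough
transform over an integer grid of centers and radii. Votes are defined by
the rounded Euclidean distance (`floor(d + 0.5) == r`), which makes the
accumulator *identical* to an exhaustive search maximizing edge overlap —
a property the test suite verifies directly on small phantoms. Ties are
broken deterministically (smaller radius, then smaller row, then column),
and a detection is rejected when the best cell collects fewer votes than a
quarter of the circumference of the smallest searched radius. The radius
search range is a required configuration parameter: it depends on the
camera's field of view, and the package deliberately refuses to guess it.

Physical scale is either supplied (microns per pixel) or calibrated from
the detected disc using the typical adult human disc diameter of 1.83 mm.
The calibration is a convention, not a per-eye truth: neonatal discs vary,
and all pixel-unit quantities are carried alongside the converted ones.

### Tortuosity

Per vessel branch the package computes the arc-length normalized total
squared curvature,

$$\tau \;=\; \frac{1}{L}\int_0^L \kappa(s)^2\, \mathrm{d}s ,$$

and the per-eye VT is the mean of $\tau$ over branches. The normalized
form is used (rather than the bare integral) because it is invariant to
how a vessel is cut into branches and has a clean closed form on
calibration shapes: a circular arc of radius $R$ gives $\tau = 1/R^2$
regardless of its length. The unnormalized integral is also returned as an
attribute for transparency.

Estimating $\kappa$ from a rasterized centerline is the numerically
delicate step. A second difference of raw skeleton pixels at 1-px spacing
has staircase noise roughly an order of magnitude larger than the signal
at $R \approx 50$ px, and squaring turns that noise into positive bias.
The pipeline therefore:

1. refines each skeleton pixel to a sub-pixel position — the centroid of
   its neighborhood weighted by the squared Euclidean distance transform,
   with the window following the local caliber — which places points on
   the ridge of the distance map (the tube center) to well below pixel
   accuracy;
2. applies a 5-sample moving average;
3. fits a cubic smoothing spline to each coordinate against cumulative arc
   length, with about one effective degree of freedom per 7 px of arc (at
   least 4, at most half the sample count), and evaluates analytic first
   and second spline derivatives on a 0.5-px grid, trimming 3 px at each
   end where spline derivatives are unreliable.

The knot density is the main smoothing dial: more freedom lets staircase
noise through (positive bias), less attenuates genuine curvature (negative
bias). One knot per 7 px balances the two across arcs of radii 40–60 px at
several orientations and rasterized sinusoids, with errors of a few
percent against closed forms — the calibration battery in the test suite.
Branches shorter than the smoothing machinery can support return `NA` and
are excluded from the eye mean.

### Width

Widths are measured at centerline points. The Euclidean distance transform
of the **full** vessel mask (computed before ROI cropping, so the ROI
boundary never fakes a vessel edge) seeds the measurement, but the
reported sample is the boundary-to-boundary caliber: the mask is probed
from the sub-pixel centerline point along the local normal in quarter-pixel
steps until background is reached on each side. Reading the distance
transform directly would be biased, because its value is the distance to
the nearest background pixel *center*, which exceeds the distance to the
region edge by a lattice-phase-dependent fraction of a pixel; the probe
avoids that bias on curved vessels. An adaptive filter then drops samples
within 3 px of branch ends (junctions inflate the local distance values)
and samples more than 3 median absolute deviations from the branch median.
On rasterized bars of odd width 3–9 px the estimate is exact; on curved
bands it is within about 0.2 px.

### Density

Density is the exact pixel-count ratio
$\mathrm{VD} = 100\, A_\mathrm{vessel} / A_\mathrm{ROI}$, where the
numerator counts vessel pixels strictly inside the annulus and the
denominator is the in-bounds annulus area with the disc removed. No
estimation is involved; the tests assert bitwise equality with a
brute-force count.

## Skeleton topology

Skeletons come from Zhang–Suen thinning. Branch splitting uses the
*crossing number* (the number of 0-to-1 transitions around the 8-neighbor
ring): interior line pixels have crossing number 2, endpoints 1, junctions
3 or more. A raw neighbor count would misclassify every diagonal
staircase pixel as a junction. Because removing a single junction pixel
leaves its arms 8-connected through the diagonals, the full 3x3
neighborhood of each junction is cleared before branches are labeled;
branches lose at most a pixel or two at junction ends, which the 3-px end
trims absorb anyway. Branches shorter than `min_branch_px` (default 10 px)
are treated as pruning artifacts of the thinning and dropped.

## Statistics

- **Two-group comparisons** use the pooled-variance Student t-test
  (`df = n1 + n2 - 2`) when both samples pass a Shapiro–Wilk check, and
  the Wilcoxon–Mann–Whitney test otherwise. The pooled (not Welch) variant
  is the default because it is the convention the summary-table
  reproductions require; Welch is available by flag. The normality level
  (default 0.05) is split across the two samples so the joint gate keeps
  approximately its nominal level.
- **Summary-statistics t-tests** are computed directly from (mean, sd, n)
  triples, allowing published tables to be re-analyzed without raw data.
- **The 2x2 chi-square** is Pearson's statistic without continuity
  correction — again the convention required to reproduce published
  values.
- **Mann–Whitney** is exact (no ties, both groups at most 8) or uses the
  normal approximation with tie correction; the exact branch is verified
  against full enumeration of rank assignments.
- **The ordinal model** is a proportional-odds cumulative-logit fit,
  $P(Y \le k \mid x) = \mathrm{logit}^{-1}(\theta_k - x^\top\beta)$,
  maximized by Newton iteration with step-halving (the log-likelihood
  trace is non-decreasing by construction and is exposed on the fit).
  The Hessian is obtained by central differences of the analytic gradient;
  standard errors come from the inverse observed information, and
  intervals are Wald: $\mathrm{aOR} = e^\beta$ with
  $e^{\beta \pm 1.96\,\mathrm{SE}}$. Control eyes are excluded from the
  fit (stages 1–3 only), eyes are treated as independent, and
  $100\,\beta$ is also reported as the percent increase in the odds of a
  more severe stage per unit covariate. The fit is cross-checked against
  an independent reference implementation in the test suite.
- No multiple-testing correction is applied by default, matching the
  analysis convention the battery mirrors.

## Embedding

The t-SNE implementation is exact ($O(n^2)$), appropriate for cohorts of
order $10^2$ eyes and required for the analytic-vs-numeric gradient check
in the tests. Features (VT, VW, VD) are standardized to zero mean and unit
variance first, since their units are incommensurable. Per-point Gaussian
bandwidths are calibrated by binary search until each conditional
distribution's entropy is within $10^{-5}$ nats of $\log(\mathrm{perplexity})$;
perplexity defaults to 30 clipped to $(n-1)/3$. Optimization runs 1000
iterations of gradient descent on $\mathrm{KL}(P\Vert Q)$ with early
exaggeration (factor 12 for the first 250 iterations), momentum 0.5
rising to 0.8, learning rate 200 and the standard adaptive per-coordinate
gains; a fixed learning rate without gains diverges at these problem
sizes. Everything is seeded; identical input and seed give identical
coordinates.

The severity-ordering statistic projects the embedding onto the line
through the least-severe and most-severe stage centroids and reports the
Spearman correlation of that projection with stage, with a permutation
p-value in which the whole statistic (centroids included) is recomputed
per label shuffle.

## Synthetic data: what it does and does not show

`make_phantom` rasterizes vessel primitives (lines, circular arcs,
sinusoids) by exact sub-pixel distance to the parametric curve, plus a
filled disc, and returns a manifest with analytic tortuosity, nominal
width, and exact pixel counts. `make_cohort` draws per-eye feature tables
with the published group structure — 53 control eyes and 18/28/12 eyes at
stages 1–3, group means and SDs for VT/VW/VD, and covariate summaries
(sex ratio, age in days, gestational age, birth weight) — as *independent*
Gaussians per group, because no covariance structure is published;
correlated generation would be a user-supplied option, and the aORs a
correlated cohort would produce differ from those of the independent
default. `make_ordinal_cohort` samples stages from the cumulative-logit
model and is the parameter-recovery oracle for the ordinal fit.

Passing the phantom battery shows the geometry pipeline is correct on
clean binary masks with known truth. It does not show robustness to
segmentation errors, illumination artifacts, motion blur, or the anatomy
real RetCam images contain (vessel crossings near the disc, variable disc
shape, peripheral pathology); the tests quantify algorithmic correctness,
not clinical validity. Likewise, the cohort generator reproduces published
group *summaries*, so battery results on it demonstrate that the
statistical machinery recovers the encoded structure — not that the
package would reproduce the published per-eye values from the original
images, which are not deposited. The tortuosity display unit used in the
source tables ($10^4\,\mathrm{cm}^{-3}$) cannot be reconstructed from a
quantity of dimension length$^{-2}$, so the package reports VT in
$\mathrm{px}^{-2}$ and $\mathrm{\mu m}^{-2}$ and treats any display
scaling as a labeling choice.

## Degenerate inputs and problem sizes

Empty masks yield empty branch lists and zero density; an all-background
disc mask raises a no-disc error; eyes whose vessels lie entirely inside
the disc report undefined VT/VW and zero VD; duplicate-only feature sets
make affinity calibration fail loudly. Per-eye failures in a batch run are
logged and skipped, and a run fails only when no eye succeeds.

The test-suite simulations are sized to exercise the asymptotics they
check while staying quick: 100-seed gate calibration, 1000-replicate ANOVA
null, 500-replicate ordinal coverage at $n = 300$, parameter recovery at
$n = 2000$, phantom batteries at 480x640 and Hough-oracle equivalence at
128x128. The full suite runs in about a minute on one core.
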