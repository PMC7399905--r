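---
title: "Deviation-map analysis of macular layer thickness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deviation-map analysis of macular layer thickness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macuMap)
```

# The problem

Cross-sectional OCT studies of the macula commonly report layer thickness
per cell of the ETDRS grid: every subject's map is collapsed into nine cell
means, and groups are compared cell by cell ("grid analysis", GA). A defect
that covers only part of a cell is averaged together with the normal
remainder of that cell, so GA systematically understates localized thickness
changes — a flat defect of amplitude $L$ covering a fraction $f$ of a cell
shifts the cell mean by only $fL$. macuMap implements the complementary
map-based analysis (MA): group statistics are computed at every lattice
point, significant areas are detected point-wise, partitioned by the ETDRS
grid, and only the significant *fraction* of each cell is measured. In the
same partial-coverage situation MA reports $L$ itself, together with how much
of the cell it covers.

# Data model

All maps live on one fovea-centered square lattice (default 6 mm at 0.05 mm
spacing, 121×121 points, chosen so the 6 mm ETDRS disk is exactly
representable and the fovea is a lattice point). Orientation is canonical
right-eye (OD): nasal is +x, superior +y. Left eyes are mirrored about the
vertical midline before any pooling, because nasal and temporal sides are
anatomically swapped between eyes and studies pool randomly chosen
unilateral eyes. Registration to the fovea uses integer lattice shifts only:
at 0.05 mm spacing the rounding error is below the lateral accuracy of the
acquisition and no interpolation smoothing is introduced. Resampling from
sparse B-scan rows to the lattice is linear in both directions — linear
interpolation is monotone and cannot overshoot the measured range, which
matters for a strictly positive quantity like thickness.

Analyzed layers follow the usual inner-retina panel: total retina (TR),
retinal nerve fiber layer (RNFL), ganglion cell layer (GCL), inner plexiform
layer (IPL) and inner nuclear layer (INL).

# The ETDRS grid

Nine cells: a central 1 mm disk (FC), an inner (pericentral) ring of 1–3 mm
diameter and an outer (peripheral) ring of 3–6 mm diameter, the rings split
into nasal/superior/temporal/inferior quadrants on the 45° diagonals. Ring
intervals are half-open with the inner radius included (r = 0.5 mm belongs
to the inner ring) and quadrant sectors are half-open counterclockwise, so a
point on a diagonal belongs to the counterclockwise-next sector. No
convention for the boundary points is standard; this one was chosen because
it guarantees a disjoint and exhaustive assignment, and it is fixed. At the
default lattice the discretized cell areas are within one perimeter-pixel
band of the analytic values (inner quadrant π(1.5² − 0.5²)/4 ≈ 1.571 mm²,
outer quadrant ≈ 5.301 mm²).

# Reference model and color encoding

The normative reference is the control cohort itself: at every lattice
point, the control mean and the empirical 2.5th/97.5th percentiles.
Percentiles use linear interpolation between order statistics
(h = (n−1)p + 1, R's quantile type 7) — the most widely used convention; the
choice is documented because with n = 40 controls the extreme percentiles
depend visibly on the estimator.

The deviation field is a difference of group means, d(x) = mean of the
study group − mean of the controls, matching the between-group (not
single-subject-versus-normative) reading of deviation maps. The display
index maps d onto [−1, 1]: 0 at the control mean, ±1 where the group mean
reaches the upper/lower percentile, clamped beyond. Each side is normalized
by its own half-interval (upper − mean, mean − lower), because empirical
percentile bounds generally sit at unequal distances from the mean; a
full-interval normalization is a one-line change but would make the darkest
color unreachable on the narrower side. A degenerate interval (e.g. a
constant control cohort) saturates to ±1 for any nonzero deviation.

# Inference

Point-wise comparison of two groups uses the classical pooled-variance
(equal-variance) Student t-test, two-sided, at α = 0.05 by default. For
three-group designs (e.g. controls and two patient subgroups stratified by
neuropathy status) every pair is tested with Tukey's honestly significant
difference: a one-way pooled mean square error at each point and p-values
from the studentized-range distribution (base R's `ptukey`, k = number of
groups, Tukey–Kramer form for unequal n). With exactly two groups this
reduces analytically to the pooled t-test (q = |t|√2); the implementation
keeps a single code path and the identity is verified numerically to below
1e−9 in the tests.

No multiple-testing correction is applied across points or cells by
default: the deviation-map convention is to threshold each point at the
nominal level and read the significance outline as a descriptive overlay. An
optional Benjamini–Hochberg adjustment over testable points is available but
off by default. The spatial multiplicity of per-point tests is a known
limitation of this style of analysis — the per-point level is exact but the
map-wise false-positive area under the null is roughly α of the grid; the
coverage threshold (below) is the pragmatic guard against over-reading small
areas.

Degenerate points follow a fixed convention: zero pooled variance with equal
means gives p = 1, with unequal means p = 0; points with fewer than two
valid subjects in either group are untestable (NA, never flagged).
Cell-level (GA) tests apply the same machinery to per-subject cell means, so
subjects remain the unit of inference.

# MA measurement

Significant points are decomposed into connected components under
8-connectivity (4-connectivity is available; 8 was chosen so that thin
diagonal bands — an annulus crossing the quadrant diagonals, for instance —
remain one area). Components are split by deviation sign so thinning and
thickening are always reported separately. Per ETDRS cell and sign, the
significant fraction is measured as MD ± SE (mean and standard error of the
deviation field over the fraction's points) plus its coverage, the percent
of the cell's full geometric point count. Fractions below the coverage
threshold (default 10%) are reported but flagged as not passing — small
scattered areas are not generalized to the whole cell. The coverage
denominator is the full geometric cell size rather than the valid-mask
subset, so the threshold's meaning does not drift when scan edges are
masked; this is configurable in the low-level API via the mask itself.

Two SE definitions are implemented because reported MD ± SE values for
irregular areas do not pin one down: the default is the point-wise SE of
the deviation values over the fraction (computable from the deviation field
alone); a subject-level SE (difference of per-subject means over the same
points) is available when the cohort stacks are at hand, and is the larger
of the two for well-resolved areas since it scales with 1/√subjects rather
than 1/√points.

Arbitrary regions of interest spanning several cells can be measured as one
defect (`measureRoi`), which pools all significant points inside the region
and attaches a per-cell coverage breakdown — the manual workflow for
clusters that the per-cell threshold would fragment.

# The synthetic cohort generator

Patient OCT cohorts cannot be shipped, so the package carries a generator
that reproduces the statistical structure the analysis relies on, and the
whole pipeline is tested against it:

* a radially symmetric base profile b(r) per layer — foveal pit, pericentral
  peak, peripheral taper — with defaults of plausible magnitude (TR about
  270 µm at the pit and 320 µm at the peak; GCL peak about 50 µm). These are
  defaults, not normative claims; only relative behavior matters for the
  tests.
* a per-subject global offset, Normal with SD 4 µm by default, standing in
  for between-subject anatomical variation;
* within-map noise: white Gaussian noise smoothed with a separable Gaussian
  kernel (correlation length 0.25 mm by default) and rescaled analytically
  to a point-wise SD of 2.5 µm. Smoothing matters: real thickness maps are
  spatially smooth, and white noise would make per-point tests behave as if
  every point were an independent replicate;
* planted lesions — annuli, wedges, disks, scattered clusters — of
  configurable amplitude and soft edge, with ground-truth masks returned
  for recovery tests. A disk lesion can be auto-sized to cover a target
  percentage of a named cell to within 1%, which is how the
  coverage-threshold and dilution properties are exercised.

The defaults (40 controls vs 33 patients, −12 µm annular GCL thinning of
the inner ring against offset SD 4 µm and noise SD 2.5 µm) reproduce the
canonical study geometry: a per-point effect size large enough that the
annulus is recovered essentially completely, while cohort-level offset noise
keeps the recovered MD honest to within a micron or so of the planted
amplitude.

What the generator does *not* emulate: OCT speckle and B-scan artifacts,
segmentation errors, anisotropic (along-scan vs across-scan) noise,
eccentric fixation, or pathology-correlated variance changes. Passing the
recovery tests therefore demonstrates the correctness of the measurement
chain, not robustness to device-specific artifacts.

# Numerical choices and problem sizes

Everything is deterministic given seeds; `generateCohort` saves and restores
the caller's RNG state. The test suite and the acceptance script run the
null-calibration study (two cohorts of 40 and 33 from one generator, 200
replicates) on a 61×61 lattice — the calibration of a per-point t-test does
not depend on lattice resolution — and the lesion-recovery study (20 seeds)
on the full 121×121 lattice, where component geometry matters. The
calibration tolerance is three binomial standard errors at 200 replicates.
Recovered-amplitude tolerances are three times the analytic standard error
of a group-mean difference under the generator's noise model,
$3\sqrt{\sigma_b^2+\sigma_n^2}\sqrt{1/n_1+1/n_2}$.

Known limitations: per-point inference ignores spatial correlation (by
design, replicating the descriptive map convention); GA/MA SE definitions
for irregular areas are conventions, stated above; the exchange format
assumes dense in-row sampling is already available, since in-row A-scan
density is device-specific.
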