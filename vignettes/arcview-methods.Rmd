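---
title: "Planning the C-arm viewing angle for TEVAR: models and design choices"
author: "arcview"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning the C-arm viewing angle for TEVAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

During thoracic endovascular aortic repair (TEVAR) the stent graft is
deployed under 2D X-ray angiography. The gantry (C-arm) rotation angle
decides what the operator sees: a poorly chosen angle superimposes the left
common carotid artery (LCCA) and left subclavian artery (LSA) — making it
easy to cover a branch ostium with the graft — and foreshortens the aortic
arch, hiding the landing zone's true length. arcview plans this angle
pre-operatively from a segmented 3D volume (e.g. CTA) and the aortic
centerline, sweeping the LAO angle $\theta$ from 0 to 90 degrees and scoring
each simulated view.

## The two per-angle scores

**Projection overlapping rate (POR).** With $S_{LCCA}(\theta)$ and
$S_{LSA}(\theta)$ the binary silhouettes of the two branches at angle
$\theta$ and $NP(\cdot)$ a pixel count,

$$P_{overlap}(\theta) =
  \frac{NP[S_{LCCA}(\theta) \cap S_{LSA}(\theta)]}
       {NP[S_{LCCA}(\theta)] + NP[S_{LSA}(\theta)]},$$

which ranges from 0 (disjoint) to 0.5 (identical non-empty silhouettes).
Counting is exact integer arithmetic, so $P_{overlap}(\theta) = 0$ is a
meaningful predicate, not a tolerance test. When both silhouettes are empty
the ratio is undefined; `overlapRate()` returns 0 with a warning, on the
grounds that an empty silhouette cannot overlap anything.

**Projection foreshortening rate (PFR).** With $T_2$ the 3D arc length of
the aortic centerline and $T_1(\theta)$ its projected length at angle
$\theta$,

$$P_{fs}(\theta) = T_1(\theta) / T_2 ,$$

so $P_{fs} = 1$ means the arch is displayed at full length. Both lengths
are polyline sums over the delivered centerline segments; no resampling is
performed.

*Choice of numerator.* For a unit ray direction $\hat P$ and a segment
tangent $\mathbf t$, the detector-plane component is
$\lVert \mathbf t - (\mathbf t \cdot \hat P)\hat P \rVert$ and the along-ray
component is $|\mathbf t \cdot \hat P|$; the two satisfy a per-segment
Pythagorean identity. A literal sum of $|\mathbf t \cdot \hat P|$ is maximal
exactly when foreshortening is worst, which contradicts the intent of
maximizing the displayed arch length, so `foreshorteningRate()` uses the
detector-plane length by default and exposes the along-ray sum behind
`variant = "alongRay"` for audit.

## The selectors

**Standard (joint minimization).** The baseline selects
$\arg\min_\theta\, [P_{overlap}(\theta) + (1 - P_{fs}(\theta))]$. We call
this the *corrected* objective: the naive sum $P_{overlap} + P_{fs}$ would
reward foreshortening under the length-ratio definition above; it remains
selectable as `variant = "literal"`. The minimizer carries no guarantee
that the chosen view is overlap-free.

**Adaptive (two-step).** Overlap avoidance is the hard clinical
constraint, so it is imposed first:

1. $\Theta_{no\text{-}overlap} = \{\theta : P_{overlap}(\theta) = 0\}$
   (exact zeros).
2. Let $\theta_{fsmin}$ be the smallest grid angle attaining
   $P_{fsmax} = \max_\theta P_{fs}(\theta)$. The tolerated set is

$$\theta_{fs} = \begin{cases}
  \{\theta_{fsmin}\} & \theta_{fsmin} \le 50^\circ \\
  \{\theta : P_{fs}(\theta) > 0.98\, P_{fsmax}\} & 50^\circ < \theta_{fsmin} \le 60^\circ \\
  \{\theta : P_{fs}(\theta) > 0.95\, P_{fsmax}\} & \theta_{fsmin} > 60^\circ
\end{cases}$$

   (strict inequalities). Steep gantry angles are awkward to work at, so
   when the geometrically ideal view is steep the rule trades a little arch
   display (2% or 5%) for a shallower angle.
3. The selected angle is the minimum of
   $\Theta_{no\text{-}overlap} \cap \theta_{fs}$.

The published rule assumes the intersection is non-empty. To make the
selector total, arcview adds a fallback ladder, always recorded in the
result (`fallbackUsed`): first relax the foreshortening set to the 98% and
then the 95% tier; if the intersection is still empty, take the
overlap-free angle with maximal $P_{fs}$; only when *no* angle is
overlap-free, take the angle minimizing $P_{overlap}$ (ties by larger
$P_{fs}$, then smaller $\theta$). The ladder is deliberately conservative:
overlap elimination always dominates.

*Tie and grid conventions.* All argmin/argmax ties break toward the
smallest angle; in `standardSelect()` objective values within $10^{-12}$
are treated as tied, so exact-arithmetic ties survive float round-off.
Angles are reported on the sweep grid (default 0–90 in 1° steps, the
granularity of clinical C-arm settings); no sub-grid interpolation is
attempted.

On profiles where both selectors are well posed they often agree; they are
guaranteed to differ when the joint objective is minimized at an angle with
residual overlap, which is precisely the case the adaptive rule exists to
exclude. Conversely, in the 50–60° tier the adaptive rule deliberately
returns the *smallest* tolerable angle, which can sit several degrees below
the geometric optimum — a pattern the phantom cohort runs of
`scripts/acceptance.R` display for arch planes steeper than 50°.

## Projection model

* **Parallel beam.** The source-detector distance of a C-arm is large
  relative to the aortic arch, so orthographic projection is a standard
  approximation; it also admits closed-form oracles (a cuboid projects to
  an exact rectangle, a sphere to a disk). The geometry object isolates
  this choice should cone-beam support be added.
* **Single-axis sweep.** $\theta$ is the LAO rotation about the
  superior-inferior axis with zero cranial/caudal angulation: in the LPS
  patient frame the ray is $(\sin\theta, \cos\theta, 0)$, the detector axes
  are $(\cos\theta, -\sin\theta, 0)$ and $(0, 0, -1)$ (image-up =
  superior). $\theta = 0$ is the AP view.
* **Ray casting.** For every detector pixel center the ray is sampled at
  half the minimum voxel spacing with nearest-neighbor lookup; a pixel is
  set iff any sample carries the target label. Sampling this dense cannot
  skip a voxel, so silhouettes have no holes, and the error is bounded by
  the sampling step. Sample positions sit on an absolute lattice along the
  ray and the detector grid on an absolute lattice of the pixel size;
  consequently translating the scene along the ray by a lattice multiple
  reproduces bit-identical masks, and axis-aligned grids project voxel
  centers exactly onto pixel centers.
* **Defaults.** Pixel size = minimum voxel spacing; detector sized to the
  scene's projected bounding box plus a two-pixel margin.
* Rendered views (`renderView()`) are normalized foreground thickness
  maps used for qualitative display and absolute-difference images; no
  attenuation physics, contrast transport or detector noise is modeled.

## The phantom generator

`generatePhantom()` voxelizes an idealized arch with analytically known
geometry: an exact semicircular midline (radius 35 mm, aortic tube radius
14 mm) in a plane whose normal is the ray at `archPlaneLao`, joined
continuously to straight vertical ascending/descending limbs (40 mm each),
plus two straight branch tubes of radius 4 mm and length 40 mm leaving the
arch midline at 83.5° and 96.5° along the semicircle with opposed
out-of-plane tilts of 40° (LCCA anterior, LSA posterior). Defaults are
adult-sized and were fixed by an up-front geometric analysis of the
projected branch tubes so that the phantom reproduces the clinically
interesting regime: branch silhouettes overlap at shallow (AP-ward) angles
and separate a few degrees below the arch-perpendicular view. By
construction $P_{fs}$ peaks exactly at $\theta =$ `archPlaneLao`, giving
every downstream stage a known ground truth.

The closed forms this buys: the aorta centerline length is
$\pi R + L_{asc} + L_{desc}$; the arch plane normal is known; the
no-overlap window can be predicted from tube geometry. Centerlines are
sampled at 1 mm, below any sensible voxel spacing (length error of the
semicircle at that step is ≈ 0.001%).

What the phantom does *not* emulate: non-circular and non-planar arches,
vessel tapering, the brachiocephalic trunk, true/false dissection lumina,
intensity/contrast appearance, or segmentation noise. Tests passing on
phantoms therefore validate the metrics, the projector and the selection
logic — not the quality of any upstream segmentation, which this package
deliberately consumes as input.

One voxelization subtlety: labels are exclusive, so two *nearly coincident*
branch tubes split along their bisector plane, and the exact
arch-perpendicular ray (which runs inside that seam) can see the two halves
as disjoint. Truly coincident silhouettes at every angle are impossible in
a single label volume; the test suite instead uses a coaxial core/shell
construction when an everywhere-overlapping pair is needed.

`sampleCohort()` draws specification cohorts by independent uniform jitter
of named scalar fields (rejecting draws that violate the invariants). The
validation cohort used by the tests and the acceptance script draws
`archPlaneLao` uniformly from 35–55°, the range of arch orientations the
selector is expected to resolve, on grids of 96³–128³ voxels covering a
160 mm field of view. Cohort size is 20, which keeps the full pipeline
(20 × 91 projections of two labels each) around half a minute on one CPU
while the recovery statistic is already stable.

## Evaluation statistics

`compareAngleSets()` mirrors the usual cohort comparison protocol: both
samples are tested for normality (Shapiro–Wilk, at the same $\alpha$ as the
significance threshold, default 0.05 — the gate's test is a package choice;
a constant sample fails the gate); if both pass, an unpaired two-sided
t-test compares group means, otherwise a Mann–Whitney U test. The test is
unpaired because the quantities compared are group means; the per-case
absolute differences are computed separately and binned at 3° and 5°
(left-closed, right-open, plus overflow). Reported dispersions are sample
SDs. Both choices are visible in the result object so downstream reporting
can state them.

## Numerical choices and degenerate inputs

* Exact-zero overlap (integer counting) defines the no-overlap set; no
  epsilon.
* `overlapRate()` on two empty masks: 0 with a warning (undefined ratio).
* Zero-length centerlines are rejected; centerline validity requires at
  least two distinct consecutive points.
* Equal-objective ties in `standardSelect()`: $10^{-12}$ tolerance,
  smallest angle wins. Tier comparisons in the adaptive rule are strict, as
  specified.
* Scene files round-trip through NIfTI + CSV at ≥ 15 significant digits;
  coordinates are preserved to well below $10^{-6}$ mm, and re-running the
  pipeline on the same in-memory scene is bit-identical.
* Oblique NIfTI affines are rejected: the projector assumes an
  axis-aligned voxel grid.

## Known limitations

* Single-axis optimization only: no cranial/caudal angulation, matching
  the single-scalar sweep the selection rule is defined on.
* Parallel-beam silhouettes ignore magnification; absolute silhouette
  *areas* carry rasterization bias of a fraction of a voxel at each
  boundary (the sphere fidelity tests bound it at 3% for radii ≥ 10
  voxels).
* The adaptive tier rule is calibrated in degrees of gantry angle
  (50°/60° break points, 98%/95% tolerances) as printed; arcview treats
  these as fixed clinical constants, not tunables.
* The phantom's branch geometry is two tubes; cohort realism is limited to
  arch-plane orientation and global size jitter.
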