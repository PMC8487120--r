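# arcview

Optimal C-arm viewing-angle planning for thoracic endovascular aortic
repair (TEVAR).

During TEVAR the stent graft is deployed under 2D X-ray angiography, and
the C-arm (gantry) rotation angle decides what the operator sees. A poorly
chosen angle superimposes the left common carotid artery (LCCA) and the
left subclavian artery (LSA) — risking a graft that covers a branch
ostium — and foreshortens the aortic arch. In practice the angle is found
by trial and error under fluoroscopy, at the cost of extra radiation and
contrast. arcview computes it pre-operatively from a labeled 3D volume
(e.g. a segmented CTA) and the aortic centerline. It is written for
interventional imaging researchers and for anyone validating viewing-angle
selection rules; it deliberately consumes precomputed segmentations and
centerlines (no DICOM ingestion or segmentation is included).

## Method

For each LAO sweep angle θ ∈ [0°, 90°] (θ = 0 is the AP view; rotation is
about the superior–inferior axis), arcview simulates the parallel-beam
silhouette of each vessel label and scores the view with two quantities:

* **Projection overlapping rate** (range 0–0.5), by exact pixel counting:

  P_overlap(θ) = NP[S_LCCA(θ) ∩ S_LSA(θ)] / ( NP[S_LCCA(θ)] + NP[S_LSA(θ)] )

* **Projection foreshortening rate** (1 = arch shown at full length):

  P_fs(θ) = T₁(θ) / T₂

  where T₂ is the 3D arc length of the aortic centerline and T₁(θ) its
  projected (detector-plane) length.

Two selectors operate on the per-angle profile:

* `standardSelect()` — joint minimization of
  P_overlap(θ) + (1 − P_fs(θ)); no overlap-free guarantee.
* `adaptiveSelect()` — the two-step rule: restrict to angles with exactly
  zero overlap, intersect with an adaptive foreshortening-tolerance set
  (the singleton optimum θ_fsmin if it is ≤ 50°; the angles above 98% of
  the maximum P_fs if 50° < θ_fsmin ≤ 60°; above 95% if θ_fsmin > 60°),
  and take the smallest angle of the intersection. A conservative,
  always-logged fallback ladder keeps the selector total when the
  intersection is empty.

A parametric aortic-arch phantom generator with analytically known
geometry (`PhantomSpec()` / `generatePhantom()` / `sampleCohort()`)
provides ground-truth scenes for validation, and `compareAngleSets()`
implements the cohort-level comparison (Shapiro–Wilk-gated t /
Mann–Whitney U test, 3°/5° difference bins). See the methods vignette
(`vignettes/arcview-methods.Rmd`) for the model, conventions and design
choices.

## Worked example

Generate a phantom whose arch plane is perpendicular to the ray at
LAO 48°, then run the full pipeline:

```r
library(arcview)
spec  <- PhantomSpec(archPlaneLao = 48, gridShape = c(96, 96, 96),
                     spacing = rep(160/96, 3))
scene <- generatePhantom(spec)
scene
#> VesselScene: 96 x 96 x 96 voxels, spacing 1.67 x 1.67 x 1.67 mm
#>   labels: background=0 (856330 vox), aorta=1 (27766 vox), LCCA=2 (320 vox), LSA=3 (320 vox)
#>   centerlines: aorta, LCCA, LSA

res <- selectForScene(scene)   # 0-90 deg sweep in 1 deg steps
res$adaptive
#> AdaptiveSelection: theta_optimal = 48.0 deg
#>   overlap-free angles: 51; theta_fsmin = 48.0 (p_fsmax = 1.0000), tier <=50
#>   fallback: none
res$standard
#> StandardSelection (corrected): theta_standard = 48.0 deg (objective 0.0000)

as.data.frame(res$profile)[44:49, ]
#>    theta_deg p_overlap      p_fs
#> 44        43         0 0.9988992
#> 45        44         0 0.9992952
#> 46        45         0 0.9996034
#> 47        46         0 0.9998237
#> 48        47         0 0.9999559
#> 49        48         0 1.0000000
```

Both selectors recover the arch-perpendicular view: at LAO 48° the branch
silhouettes are disjoint (p_overlap = 0) and the arch is displayed at full
length (p_fs = 1). The profile shows why shallower angles are rejected:
toward the AP view the branches overlap and the arch foreshortens.

The same pipeline is scriptable from a shell via `exec/arcview`
(`phantom`, `sweep`, `select`, `evaluate` subcommands), reading and
writing NIfTI label volumes, `x_mm,y_mm,z_mm` centerline CSVs and JSON
reports.

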