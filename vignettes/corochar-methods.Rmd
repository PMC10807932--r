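---
title: "Coronary characterization with corochar: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronary characterization with corochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corochar)
```

## The problem

Coronary artery calcium (CAC) and coronary tortuosity (CorT) are early,
independently informative markers of coronary artery disease. Both are
tedious and operator-dependent to quantify by hand on coronary CT
angiography (CCTA). corochar implements a fully automated geometric
pipeline that, given a CCTA intensity volume plus coronary-lumen and
aorta label maps, produces per-patient tortuosity and calcium reports:

1. **Centerline extraction** — ostium-rooted centerline trees via a
   normalized geodesic distance field and recursive endpoint detection.
2. **Tortuosity quantification** — pointwise local tortuosity and
   tortuosity angle, per-zone tract tortuosity, bend detection, and a
   branch-count tortuosity score.
3. **Calcium detection** — a patient-specific attenuation threshold,
   region growing, artifact filtering.
4. **Calcium quantification** — volume score, percentage of plaque
   volume, per-lesion extent and distance from the ostium, per zone.

Because no public CCTA cohort ships with this package, every stage is
validated on parametric synthetic phantoms with exact analytic ground
truth; the phantom generator is first-class, tested code.

## Centerline model

The coronary lumen is treated as a voxel graph: lumen voxels are nodes,
26-neighbors are connected with Euclidean edge lengths (anisotropic
spacing handled exactly). For each connected component:

* **Ostium seed.** The lumen voxel whose center minimizes the Euclidean
  distance to the aorta voxel set. Ties break to the lowest linearized
  voxel index (documented, deterministic).
* **Geodesic field.** Single-source shortest paths from the seed
  (Dijkstra, deterministic tie-breaking), normalized by the component
  maximum so `g` runs from 0 at the ostium to 1 at the geodesically
  farthest tip. `g` partitions each tree into the proximal
  (`g <= 0.33`), medial (`0.33 < g <= 0.66`) and distal (`g > 0.66`)
  zones.
* **Endpoints.** The superlevel set `g > 1 - delta` is thresholded for
  `delta = delta_step, 2 delta_step, ..., 1` (default step 0.05; the
  increment is not prescribed by the upstream method description, and
  recovery is insensitive to it on phantoms between 0.02 and 0.1). Each
  new connected region that does not yet contain a claimed endpoint
  contributes its point of maximal `g`.
* **Tracing.** A minimal path from seed to endpoint with medialness
  weighting: an edge costs its length divided by `eps + d_interior`,
  where `d_interior` is the exact Euclidean distance transform of the
  lumen (mm) and `eps = 0.1` voxel. The voxel path is resampled at
  0.25 mm, recentered (below), smoothed with a centered moving average
  of 3 points, and its abscissa recomputed.

### Sub-voxel recentering

A discrete minimal path through a bent tube shaves the inside of every
elbow: within the elbow the interior distance is approximately the tube
radius over a whole wedge-shaped region, so the shortest route through
that region wins at no medialness cost. On phantoms with prescribed
50-degree bends this bias depressed recovered bend angles by about five
degrees. Each traced point is therefore moved, strictly perpendicular
to the local direction, onto the centroid of the lumen voxels in a thin
cross-sectional slab (0.75 voxel thick, disc radius slightly above the
local lumen radius; three iterations). Slab orientation uses tangents
of a heavily smoothed copy of the path, and the tail inherits the
interior direction so that slabs near the distal face stay
cross-sectional; the first point is pinned to the ostium seed. This is
standard centerline post-processing; with it, bend angles on phantom
suites are recovered with a mean absolute error well under 3 degrees.

Two conventions worth knowing:

* The branch starts at the ostium **seed**, which is a lumen-surface
  voxel facing the aorta, not the geometric axis point; abscissae
  therefore include the short run from the vessel wall onto the axis
  (at most about one lumen radius, in practice ~1 mm).
* The branch ends at the maximal-`g` voxel of its terminal region — a
  point of the distal face. Recentering pulls the tail back onto the
  axis.

## Tortuosity model

All pointwise measures use a reference arc of fixed length (default
1 cm) centered on the evaluation point; points whose reference arc
would extend past a branch end are flagged invalid and excluded from
summaries rather than evaluated on truncated arcs.

* **Local tortuosity (LT)** is the arc length of the reference arc
  divided by the straight distance between its two ends; 1.0 means
  locally straight. For a circular arc of radius `R` and window `s` the
  closed form is `s / (2 R sin(s / 2R))`, which the implementation
  reproduces to better than 1%.
* **Tortuosity angle (TA)** is the arccosine of the dot product of unit
  direction vectors obtained by least-squares line fits (first
  principal component) to the upstream and downstream halves of the
  reference arc, both oriented along increasing abscissa. Least-squares
  directions are sign-ambiguous; orientation by increasing abscissa
  resolves this. Degenerate fits (duplicate points) yield TA = 0 with a
  warning.
* **Bends.** A bend is a maximal run of valid points with TA at or
  above 45 degrees; runs separated by less than 2 mm of below-threshold
  abscissa merge into one bend (noise robustness; the upstream
  definition counts "bends" without stating a multiplicity rule). The
  bend angle is the run's maximal TA.
* **Tortuosity score (TS)** counts branches, among those at least 20 mm
  long (a proxy for "main" branches; no formal rule exists upstream),
  that carry three or more bends. TS = 0 is labeled *none*, TS >= 4
  *severe*.
* **Tract tortuosity** is the arc/chord ratio of the maximal contiguous
  sub-tract of a branch inside one geodesic zone; patient-level zone
  values average over branches. LT and TA summaries use the 95th
  percentile over valid points to damp outliers.

TA is rigid-motion invariant (tested to 1e-6 degrees) and the TA
estimator is conservative near sharp vertices: fitting straight lines
to half-arcs that include the bend transition underestimates the true
direction change by 1-2 degrees at 50-60 degrees even on noise-free
analytic polylines. This bias is inherent to the definition, not to the
implementation.

## Calcium model

* **Patient-specific threshold.** `theta = mean + k * SD` (default
  `k = 2.5`) of the image attenuation inside the aorta mask separates
  calcium from contrast-enhanced blood on a per-patient basis.
* **Candidates.** Voxels at or above `theta` within the coronary search
  volume. The lumen annotation convention often excludes wall plaque,
  so the search volume is the lumen mask dilated by a 2 mm Euclidean
  ball (configurable).
* **Region growing.** Candidates absorb 26-neighbors (within the search
  volume) whose attenuation exceeds the 98th percentile of the
  attenuation inside the *coronary lumen*, iterated to a fixpoint. The
  percentile is deliberately referenced to the lumen rather than the
  dilated search volume: diluting it with perivascular voxels drags the
  gate into the blood-pool upper tail and lets lesions leak into bright
  blood. The fixpoint equals the brute-force closure (tested exactly)
  and never shrinks a lesion.
* **Artifact filter.** Lesions whose maximal axial cross-sectional area
  is below 1 mm² are discarded (an Agatston-style reading of the
  sub-millimetric exclusion; a volumetric 1 mm³ mode is available via
  `area_mode = "volume"`).
* **Projection and scoring.** Each lesion voxel maps to its nearest
  centerline point; lesion distance from the ostium is the minimal
  mapped abscissa, extent the abscissa range, zone the zone of the
  minimal-abscissa point (one zone per lesion). The volume score (VS)
  sums lesion volumes per zone and in total; PPV is
  `100 * VS_total / lumen volume`, with the lumen mask volume as the
  denominator.

## The synthetic phantom generator

`generate_phantom()` is the package's study bench. It emulates:

* contrast-filled lumen (400 ± 30 HU texture) over soft-tissue
  background (50 ± 20 HU), calcific inclusions painted at 800 HU —
  near the top of the [-30, 800] HU preprocessing window;
* vessels of 1.5-4 mm caliber as straight tubes, circular arcs,
  helices, or planar polylines with circular fillets and prescribed
  bend angles (analytic bend abscissae and angles exported as truth);
* an attached aorta: a tube plus a small spherical sinus-like bulge
  whose surface passes ~1 mm from the first vessel root. The bulge
  matters: the closest-voxel ostium seeding needs a unique, strongly
  curved nearest feature — against a straight cylinder a whole line of
  start-face voxels is equidistant and the seed lands arbitrarily far
  off-axis;
* acquisition physics as a Gaussian point-spread function (default
  sigma 0.5 mm, a typical CCTA in-plane resolution) followed by
  i.i.d. Gaussian noise (10 HU), on grids of 0.3-0.7 mm spacing. The
  seed fully determines the output, bit for bit.

What it does **not** emulate: cardiac anatomy and motion, beam
hardening and blooming asymmetries, non-calcified plaque, contrast
gradients along the vessel. Passing phantom suites therefore
demonstrates geometric and algorithmic correctness under controlled
physics, not clinical performance.

A voxel belongs to the lumen when its center lies inside the
swept-radius tube; end caps are trimmed flat. Exact center-in-tube
counting fluctuates with lattice phase — at a tube radius of ~5 voxels
the rasterized volume can deviate from the analytic tube volume by
several percent in either direction; this is a property of binary
rasterization, not an implementation error, and it motivates the
20% tolerance used for detected lesion volumes.

## Recovery experiments (study conditions)

Two seeded suites, shipped as package functions, define the validation
conditions; both run at 0.4 mm isotropic spacing with a compact aorta
(radius 8 mm, length 24 mm) to keep grids tractable on one CPU:

* `run_bend_recovery()` — 20 single-branch phantoms: 10 with 3-4 bends
  of 52-65 degrees (score-positive), 4 with only two strong bends, and
  6 with 3-4 shallow bends of 25-40 degrees. Angles within a few
  degrees of the 45-degree counting threshold are excluded *by design*:
  at finite resolution the bend/no-bend decision exactly at the
  threshold is ill-posed for any estimator, and the score's behavior
  away from the knife edge is the property under test (the same
  convention as constructing textbook detectable/undetectable cases).
  Branch orientation and sub-voxel start offsets are randomized so the
  suite samples lattice alignments.
* `run_cac_recovery()` — 20 ellipsoidal lesions, four per straight
  vessel, semi-axes uniform in 1.5-4 mm (the axis aligned with the
  vessel determines the true extent), centers 18 mm apart so lesions
  never merge after growth.

On these suites the pipeline recovers the tortuosity score in 20/20
branches, bend angles with ~1.7 degrees mean absolute error, lesion
volumes with ~12% mean absolute relative error, extents to ~0.3 mm and
ostial distances to ~1.0 mm (the latter dominated by the
seed-at-the-wall convention described above). Small lesions bloom:
partial-volume spread at a 0.5 mm PSF inflates a 1.5 mm lesion's
detected volume far more, relatively, than a 4 mm one — the same
blooming that affects clinical calcium scoring.

## Segmentation machinery

The package carries the training-side machinery of the two-stage
segmentation cascade at desk scale, written natively in R:

* preprocessing (clip to [-30, 800] HU, z-score) and seeded
  augmentation (Gaussian smoothing p = 0.2, affine p = 0.3 with
  rotations up to 10 degrees and scales 0.9-1.1; labels
  nearest-neighbor);
* the Dice-Focal loss with `alpha = 0.6`, `gamma = 2` and stage
  weights 1.1/0.4 (stage 1) and 0.5/1.0 (stage 2). The focal term is
  averaged over voxels so the loss scale is independent of patch size;
  predictions are clamped to [1e-7, 1 - 1e-7]. The loss is verified
  against hand arithmetic on a 2x2x1 grid and is strictly decreasing
  as any single voxel moves toward its label;
* multi-view fusion by element-wise maximum followed by 0.5
  thresholding (permutation-invariant by construction);
* `build_unet()` assembles the full five-level encoder/decoder plan
  (2D: 3x3 kernels, instance norm, PReLU; 3D: 5x5x5 kernels, batch
  norm, 2-channel input) with parameter counts, and `unet_forward()`
  executes it with seeded random weights to verify the shape contract.

`smoke_train()` trains a *reduced-depth* convolutional segmenter (two
3x3 convolution + PReLU layers and a 1x1 sigmoid head, width 8) with
hand-derived Dice-Focal gradients and plain SGD. Full five-level
backpropagation training is deliberately out of scope — the smoke run
exists to exercise the loss gradients, the data plumbing and the
training loop deterministically, reaching Dice >= 0.5 on easy tube
phantoms within five epochs, and makes no claim about cohort-scale
segmentation accuracy. Cohort headline figures (Dice ~0.9 on patient
data) require the private training cohort and are explicitly not
reproduced.

## Statistics

Cohort analyses use the standard battery: two-sided Mann-Whitney U
(exact enumeration when both groups have at most 8 untied observations,
normal approximation with tie correction otherwise), Pearson's
chi-squared without continuity correction paired with the cross-product
odds ratio, one-way equal-variance ANOVA, Shapiro-Wilk as a reporting
gate (mean ± SD versus median [min; max]), Pearson correlation, and
Bland-Altman bias with 1.96 SD limits of agreement. No multiple-testing
correction is applied, matching upstream practice; significance is
0.05. The two odds ratios recomputable from published contingency
counts (smoking x tortuosity 0.53, age x tortuosity 0.88) serve as
exact pinning tests.

## Numerical choices and edge cases

* Voxel centers sit at `origin + (index - 1) * spacing` (1-based R
  indices); the world frame is LPS and `reorient_to_lps()` permutes and
  flips axes without touching world coordinates.
* Dijkstra ties keep the smaller parent index; component labeling
  scans in linearized order — all outputs are bit-reproducible.
* Mean surface distance samples surfaces at boundary-voxel centers
  (mask voxels with a 6-neighborhood background face); no
  marching-cubes mesh is involved.
* Empty-vs-empty masks define DSC = precision = recall = 1.
* `g` along a traced branch is looked up at the nearest voxel and made
  monotone by a running maximum (smoothing can otherwise produce
  sub-voxel non-monotonicity).
* Zone boundaries are closed on the proximal side: `g = 0.33` is
  proximal, `g = 0.66` medial.

## Known limitations

* Near bifurcations any single centerline is ambiguous: in the shared
  trunk the recentered path follows the union cross-section centroid,
  which can sit ~1.5 mm from either limb's analytic axis. Leaf-branch
  geometry away from the trunk is unaffected.
* Lesion volumes bloom with partial volume; detected volume is the
  grown voxel count times voxel volume, with no partial-volume
  correction.
* Ostial distances include the seed-at-the-wall offset (~1 mm).
* The phantom's uniform-intensity lesions and stationary Gaussian noise
  are idealizations; thresholds that are exactly right here may need
  re-examination on scanner data with beam hardening or motion.
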