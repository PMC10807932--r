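# corochar

Automated characterization of coronary arteries from coronary CT
angiography (CCTA). Given an intensity volume in Hounsfield units plus
binary coronary-lumen and aorta label maps on the same grid, corochar

1. extracts **ostium-rooted centerline trees** — the ostium seed is the
   lumen voxel nearest the aorta; a normalized geodesic distance field
   *g* (0 at the ostium, 1 at the farthest tip) drives recursive
   endpoint detection; branches are traced as medialness-weighted
   minimal paths with sub-voxel recentering. *g* partitions each tree
   into proximal (*g* ≤ 0.33), medial (0.33 < *g* ≤ 0.66) and distal
   (*g* > 0.66) zones;
2. quantifies **3D tortuosity** — pointwise local tortuosity
   LT = L0/L over 1 cm reference arcs (arc length over chord),
   tortuosity angle TA = arccos(v̂Up · v̂Dw) between least-squares
   directions of the upstream/downstream half-arcs, per-zone tract
   tortuosity, bend detection (runs with TA ≥ 45°), and the tortuosity
   score TS = number of branches with ≥ 3 bends (0 = none, ≥ 4 =
   severe);
3. detects and scores **coronary calcium** — patient-specific threshold
   θ_HU = μ_Ao + 2.5 σ_Ao from the aortic blood pool, region growing
   gated at the 98th percentile of coronary attenuation, removal of
   sub-millimetric artifacts, projection of each lesion onto the
   centerline (distance from ostium, extent, zone), volume score VS and
   percentage of plaque volume PPV = 100 · VS / lumen volume.

A parametric synthetic-phantom generator with exact analytic ground
truth (tapering vessels, prescribed bends, ellipsoidal calcific
inclusions, attached aorta, PSF blur and noise) makes the whole
pipeline testable without patient data, and the package ships the
segmentation-side machinery (Dice–Focal loss with printed weights,
multi-view fusion, U-Net assembly, desk-scale smoke training) plus the
statistical battery used for cohort analyses (Mann–Whitney U, Pearson
χ² with odds ratios, one-way ANOVA, Shapiro–Wilk, Bland–Altman).

Intended users: imaging researchers who need objective, repeatable
CAC/CorT measurements from existing segmentations, and method
developers who need a fully specified, phantom-validated reference
pipeline.

## Worked example

```r
library(corochar)

# a two-branch synthetic tree: one branch with three prescribed bends
# (55, 50, 58 degrees), one straight branch carrying a calcific lesion
spec <- phantom_spec(
  list(make_bent_branch(c(55, 50, 58), 25, radius_start = 2),
       vessel_straight(55, 2.5, direction = c(1, -0.5, 0.2))),
  lesions = list(lesion_spec(18, c(2.5, 2, 2), vessel = 2)),
  aorta = list(radius = 8, length = 24), margin_mm = 4, seed = 7)
ph  <- generate_phantom(spec)
rep <- characterize(ph$image, ph$coronary, ph$aorta)
print(rep)
```

```
<patient_report>
<tortuosity_summary> TS = 1 (moderate), 2 branch(es)
  tract tortuosity: proximal 1.169, medial 1.087, distal 1.151
  LT95 1.229, TA95 46.7 deg, 5 bend(s)
<calcium_report> 1 lesion(s), VS 50.1 mm3, PPV 2.21%
  per zone: proximal 50.1, medial 0.0, distal 0.0 mm3
```

Reading the output: the bent branch contributes three bends above 45°
(plus junction-related direction changes at the shared trunk), so
exactly one branch has ≥ 3 bends and TS = 1 ("moderate"). The lesion
painted on vessel 2 (analytic volume 41.9 mm³, centered 18 mm from the
root) is detected in the proximal zone with VS = 50.1 mm³ — the ~20%
excess is partial-volume blooming at the 0.5 mm point-spread function,
the same effect that inflates clinical calcium scores. Ground truth
for every phantom is in `ph$truth` (`centerlines`, `bends`, `lesions`).

Per-stage results are available through `build_tree()`,
`summarize_tortuosity()`, `analyze_calcium()`; `write_report()` emits
JSON/CSV. A command-line wrapper is installed at
`inst/cli/corochar` (`corochar phantom|centerline|tortuosity|calcium|
characterize|eval`).

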