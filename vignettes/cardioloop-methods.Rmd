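---
title: "Methods: phantom design, feature definitions, curation and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom design, feature definitions, curation and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardioloop)
```

# Scope and model of the data

`cardioloop` analyses segmented short-axis cardiac MRI: grayscale cine (or
LGE) volumes indexed `[row, col, slice, phase]` with co-registered integer
label masks in the ACDC convention (0 background, 1 RV blood pool, 2 LV
myocardium, 3 LV blood pool).  Physical spacing is `(slice_mm, row_mm,
col_mm)`; voxel indices are 1-based in R and physical coordinates are
`(index - 1) * spacing`; slice 1 is the most basal slice by file order — no
anatomical re-sorting is attempted.  Cohorts follow a DICOM-like
Patient → Study → Case hierarchy.  Every segmentation lives in an
append-only *session* carrying its origin (`automatic`, `manual`,
`corrected`) and per-contour correction flags, so each feature-table row can
be traced back (via `resolve_provenance()`) to the exact mask that produced
it.  Session ids are content-addressed from the mask voxels, origin, case id
and a per-case sequence number.  A timestamp salt would make ids globally
unique across machines, but it would also break the package's reproducibility
contract (identical config + seed must reproduce identical artifacts), so the
deterministic sequence number is used instead.

# The synthetic phantom

No clinical data ship with the package; all end-to-end behaviour is
exercised on a programmable short-axis phantom.

**Geometry.** A stacked-disc left ventricle: on each slice the endocardium
and epicardium are concentric circles, with the radius tapering linearly by
40% from base to apex.  The RV blood pool is a crescent: a disc adjacent to
the LV at a fixed angular position, clipped away from the epicardium with a
1.5 mm margin.  Stacked discs keep the analytic slice volumes exact
(`pi * r^2 * slice_thickness`), which is what makes the voxel-count
validation (within 5% at the default 128×128, 1.5 mm grid) meaningful.

**Function.** The endocardial radius contracts as `r(t) = r_ED * (1 - cf *
w(t))` where `w` rises sinusoidally from 0 at end-diastole (phase 1) to 1 at
end-systole (phase `round(0.4 * phases)`, mirroring typical cine timing) and
back.  Since slice volumes scale with `r^2`, the programmed ejection
fraction is exactly `EF = 1 - (1 - cf)^2`.  The end-diastolic wall thickness
is constant along the slice stack; over the cycle the epicardial radius
follows so that each slice's myocardial ring area is conserved (systolic
wall thickening).

**Disease classes.** Classes differ only through geometry priors (Gaussian,
per class): `DCM` dilates the cavity (endo radius 33 ± 2.5 mm vs 25 ± 2 for
`NOR`) and contracts weakly (cf 0.15), `HCM` thickens the wall (15 ± 1.5 mm
vs 8 ± 1) around a smaller cavity, `RVA` scales the RV crescent by 1.5, and
`SCAR` adds a 60° transmural inferior wedge at blood-pool intensity to the
myocardium, standing in for LGE hyperenhancement.  These priors are package
defaults chosen to be physiologically plausible *synthetic* values — the
clinical literature informs their rough scale, but they are not clinical
claims.

**Intensity.** Blood pool 400, myocardium 150, background 80 (arbitrary
units, fixed defaults so texture features are reproducible), plus Gaussian
texture (SD 30) and global noise (SD 10).  No MR physics (bias fields,
k-space artifacts) and no papillary muscles or trabeculation are simulated —
texture features on the phantom therefore probe the *implementation*, not
radiological realism, and a pass on phantoms does not certify discriminative
value on patient data.

**Corruptions.** Three injectable failure modes mimic real segmentation
outliers: `slice_shift` translates one slice's labels (all phases, as an
acquisition misalignment would), `mask_dilate` dilates one structure at one
phase, `mask_dropout` erases one structure on one slice.  Defaults: shift
d = (10, 0) voxels, dilation radius 3.

**Reproducibility.** One RNG stream per case is derived from `(seed, case
index)`, so case *k* is identical no matter how many cases are generated.

# Feature definitions

Features the upstream literature names but does not define are implemented
with explicit, documented conventions (IBSI formulations for texture);
time-resolved features become curves over the cardiac phases, aggregated
with minimum, maximum, median and arithmetic mean.

* **Volume** — voxel count × voxel volume (ml).  An empty structure has
  volume 0, but every other feature of an absent structure is `NA`
  (missing, logged, never silently zero); median imputation happens only
  inside the classifier pipeline, fitted on training folds.
* **Surface area** — area of the triangulated 0.5-level isosurface.  The
  mesher is marching cubes whose 256-case table is generated at load time
  from per-face marching-squares segments (ambiguous faces resolved by a
  fixed rule depending only on the face's corner states, so neighbouring
  cells agree and the mesh is crack-free).  Binary data put all vertices at
  edge midpoints; the resulting staircase overestimates smooth surfaces by
  ~9%, so 10 Taubin passes (lambda 0.5, mu 0.53) low-pass the vertex graph:
  a digitized r = 10 mm ball then meshes to within ~0.7% of `4*pi*r^2`, a
  20-voxel cube's sphericity lands within 0.04 of the analytic
  `(pi/6)^(1/3)`.  Meshes under 30 vertices are left unsmoothed; a single
  1 mm voxel meshes to an octahedron of area `sqrt(3)` mm² exactly — the
  documented small-object behaviour of any midpoint mesher.
* **Sphericity** — `(36 pi V^2)^(1/3) / A`.
* **GLCM contrast, difference entropy, cluster tendency** — symmetric
  normalized co-occurrence at distance 1 over the four in-plane directions,
  computed per slice restricted to structure voxels (short-axis slices are
  5–10 mm thick, so through-plane co-occurrence would mix anisotropic
  physics), directions pooled by count accumulation, slices pooled by
  voxel-weighted averaging.  Quantization: min-max within the structure at
  that phase into `min(32, number of distinct values)` bins — the adaptive
  bin count keeps discrete few-level images (a two-level checkerboard) in
  adjacent bins, while continuous data use the full 32.  Constant
  structures: all three features 0 by convention.  Min-max binning makes all
  texture features invariant to intensity shifts.
* **NGTDM coarseness and complexity** — IBSI definitions, 2D
  8-neighbourhood per slice, voxel-weighted pooling; coarseness capped at
  1e6 (the cap value is what constant structures report).
* **Septum thickness** — rays from the LV blood-pool centroid toward the RV
  blood-pool centroid, within a ±30° sector (a package definition; the
  sector keeps the measurement on the interventricular wall); thickness =
  mean radial extent of the myocardium crossing; the relative value divides
  by the LV epicardial diameter along the septum axis.  `NA` when the RV is
  absent on the slice.
* **LV tortuosity** — endocardial contour perimeter divided by its convex
  hull perimeter, after light circular moving-average smoothing (window 5)
  of the marching-squares contour; without smoothing the half-voxel
  staircase alone inflates a circle's ratio by 5–8%.  This hull-ratio
  definition is an explicit package stand-in for a feature the literature
  names but does not define.
* **Box-counting fractal dimension** — boundary pixels (4-connectivity), box
  sizes {1, 2, 4, 8, 16} anchored at the image origin, least-squares slope
  of `log N(eps)` vs `log(1/eps)`.  Note the box-origin sensitivity for
  short segments: a full-row line scores exactly 1, a 45-pixel segment can
  score as low as 0.87.
* **EDV/ESV/EF** — curve extrema of the LV blood-pool volume curve (first
  occurrence on ties), per the standard cine convention; robust to variable
  phase counts.

Every texture feature is verified in the test suite against an independent
brute-force double-loop implementation to 1e-9 on random toy images.

# Curation operators

* **Shape-based slice interpolation** operates per structure on signed
  distance transforms (Euclidean, via distance maps of foreground and
  background): the intermediate slice is the zero super-level set of the
  linearly interpolated SDFs.  Concentric circles interpolate their radius
  linearly; identical bounding slices reproduce themselves; the operator is
  symmetric in its two inputs.
* **Temporal propagation** advects contour points through a deformation
  field estimated by a multi-resolution (×4, ×2, ×1; 60/40/20 iterations)
  demons-style intensity registration with Gaussian fluid (sigma 1) and
  elastic (sigma 1) regularization, computed per slice (thick slices make
  through-plane registration physically meaningless).  The registration is a
  deliberately simple transport mechanism satisfying an accuracy contract —
  mean endpoint error ≤ 1.5 voxels for smooth synthetic deformations of ≤ 5
  voxels — rather than a reproduction of any specific registration
  algorithm.  After each advection step the contour is rasterized (even-odd
  rule) and re-extracted (marching squares at the 0.5 level), which resolves
  self-intersections; the rasterize/extract round trip is accurate to 0.5
  voxel.
* **Consistency enforcement** applies the boolean precedence: the
  epicardial region is authoritative; `lv_pool := endo ∩ epi`,
  `rv := rv \ epi`, `myo := epi \ lv_pool`.  From a label mask the
  epicardial region is the hole-filled myocardium restricted to previously
  labelled voxels — the restriction guarantees the operator never increases
  the total labelled volume and stays idempotent.  When the epicardium
  itself is wrong this precedence propagates the error; that is a documented
  limitation, not a silent choice (no rule can decide which contour to trust
  from the mask alone).

All curation outputs are new sessions; correction flags are set exactly on
the edited (phase, slice, structure) triples.

# Outlier detection

Feature-space screening uses robust z-scores, `(x - median) / (1.4826 *
MAD)`, per watched feature column (defaults mirror the axes an expert
typically brushes: myocardial texture, septum thickness, LV tortuosity,
blood-pool coarseness; mean and max aggregates).  MAD-based scores stay
stable in the presence of the very outliers being sought; they are invariant
under monotone affine transforms of a column, and flagging is monotone in
the threshold (default |z| > 3).  Columns with MAD = 0 are skipped with a
warning.  Geometric screening scores slice misalignment at end-diastole: the
maximum adjacent-slice LV blood-pool centroid shift divided by the pool's
equivalent radius (resolution-independent; flag at 0.5), plus the maximum
adjacent-slice area jump ratio over all three structures (flag at 0.6,
comfortably above the ~0.25 jump the 40% apex taper produces at default
slice counts) — monitoring endocardial and epicardial areas is what catches
dropout, which has no centroid left to displace.  The worklist is the
score-ordered union of flagged cases with deterministic tie-breaks.
Thresholds are validated on phantoms only; on clinical cohorts they are
starting points, not calibrated operating points.

# Classification

Nested cross-validation: stratified outer folds (default 8; reduced with a
warning when a class is smaller); per outer-training set an inner stratified
CV (default 8) grid-searches classifier configurations × feature-class
subsets by mean inner accuracy (accuracy is the headline metric of the
upstream evaluation; grids are deliberately small and overridable).  The
five families are random forest and extra-trees (ranger), gradient boosting
(xgboost), RBF-SVM (e1071) and multinomial logistic regression (nnet); the
tree defaults reproduce the tuned configurations reported for this kind of
cohort (RF: 230 trees, Gini, depth 6, min leaf 6; extra-trees: 190 trees).
`min_samples_split` has no ranger equivalent and is represented by the
leaf-size constraint.  Feature-*class* subsets ({shape, cardiac, glcm,
ngtdm, first-order, clinical} combinations) rather than per-feature
selection implement the "select relevant feature classes" idea.  Ties in
the grid search resolve to the earlier candidate; the default grid is
ordered simple → complex.  Median imputation and z-standardization are
fitted on training folds only; the no-leakage property is asserted in the
tests.  One-vs-rest AUC uses the rank (Mann-Whitney) statistic on predicted
class probabilities (decision values min-max rescaled where no native
probability exists); macro AUC is the unweighted mean.

Permutation importance shuffles one evaluation column at a time (default 10
repeats), reporting baseline minus mean permuted score; a constant column
has importance exactly 0, and perfectly collinear informative features split
their importance — both asserted in the tests.

# The improvement loop

`improvement_loop()` composes the pipeline the way an expert-in-the-loop
deployment would run it: corrupt a fraction of cases (default 10%), extract,
classify (nested CV), flag outliers, restore the true masks of flagged cases
as `corrected` sessions (the simulated expert), re-extract exactly the
affected rows, re-classify with the same seed.  At corruption rate 0 the
loop is a provable no-op.  The package asserts only the *direction* of the
improvement (accuracy after ≥ before in the majority of seeds): absolute
accuracies depend on the phantom's programmed class separation, and
reproducing any specific clinical accuracy pair is out of scope.

# Problem sizes and numerical choices

The simulation studies in the tests and the acceptance script use scaled
phantom cohorts chosen as the package's own evaluation conditions: texture
oracle checks on 200 random ≤8×8 images; outlier detection on a 100-case
cohort (6 phases, 6 slices, 72² grid) with 5 injected corruptions;
classification recovery on a 200-case 4-class cohort (5 phases, 6 slices,
64² grid) with 8×8 nested CV; the improvement loop on 20 seeds × 120-case
cohorts with a reduced (random-forest) grid and 4×3 CV.  Other fixed
numerical choices: mesh smoothing 10 Taubin passes; GLCM bins 32; demons
schedule (4, 2, 1) × (60, 40, 20); SDF threshold at the ≥ 0 super-level;
rasterization at integer pixel centers with half-integer contour vertices
(which avoids degenerate ray crossings).

# Known limitations

The phantom has circular cross-sections — tortuosity and fractal dimension
have little dynamic range on it and their discriminative behaviour is
exercised on explicit analytic shapes instead.  Texture realism is Gaussian
noise; GLCM/NGTDM separate phantom classes mostly through segmentation
mistakes (which is exactly what the outlier detector exploits).  The demons
registration is 2D per slice and first-order; through-plane motion is not
recovered.  The consistency operator trusts the epicardium.  Clinical
covariates are carried through but no claim is made about their effect on
real cohorts.
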