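# cardioloop

Expert-in-the-loop analysis of segmented short-axis cardiac MRI, as a
scriptable R package.  `cardioloop` is aimed at researchers who already have
cine (or LGE) image volumes with ventricular segmentation masks — typically
produced by an automatic model — and who want the downstream pipeline that
usually hides inside interactive viewers: radiomics feature curves,
cardiac-anatomy biomarkers, automated screening for segmentation failures, a
set of mask-correction operators with full provenance, and nested
cross-validated disease classification with permutation feature importance.

The package also ships a synthetic short-axis cardiac phantom generator with
programmed geometry, cardiac function and injectable segmentation
corruptions, so every stage can be exercised and validated end-to-end with
no clinical data.

## What it computes

For each case (a 4D `[row, col, slice, phase]` volume plus an ACDC-style
label mask: 1 = RV blood pool, 2 = LV myocardium, 3 = LV blood pool), each
feature is computed at every cardiac phase — a *feature curve* — and
aggregated with min/max/median/mean:

* shape: volume (ml), mesh surface area (mm²), sphericity
  `(36πV²)^(1/3)/A`, endocardial tortuosity (perimeter over convex-hull
  perimeter), box-counting (Minkowski–Bouligand) fractal dimension;
* texture (IBSI definitions, 2D per slice, 32 grey bins): GLCM contrast
  `Σ(i−j)²p(i,j)`, difference entropy, cluster tendency; NGTDM coarseness
  and complexity;
* cardiac anatomy and function: interventricular septum thickness (mean
  radial wall thickness in a ±30° sector toward the RV centroid) and its
  value relative to the LV epicardial diameter; EDV, ESV and ejection
  fraction `EF = (EDV − ESV)/EDV` from the LV volume-curve extrema.

Segmentation QC flags cases by robust z-score `(x − median)/(1.4826·MAD)`
on the brushed feature axes and by a slice-misalignment score (adjacent
slice centroid shift over the pool's equivalent radius, plus inter-slice
area jumps).  Curation operators — signed-distance-transform slice
interpolation, demons-based contour propagation across phases, and boolean
consistency enforcement (epicardium authoritative) — emit new segmentation
*sessions* so every derived number stays traceable to the mask that
produced it.  Classification runs eight-fold nested CV over five classifier
families (random forest, extra-trees, gradient boosting, RBF-SVM, logistic
regression) with feature-class subset selection, and reports pooled
confusion matrices, per-class precision/recall, one-vs-rest AUC and
permutation feature importance.

## Worked example

```r
library(cardioloop)

# a 24-case phantom cohort: normal, dilated, hypertrophic, abnormal-RV
cfg <- phantom_config(n_cases = 24, phases = 8, slices = 6, grid = c(64, 64),
                      spacing_mm = c(8, 2, 2), seed = 1,
                      class_mix = c(NOR = .25, DCM = .25, HCM = .25, RVA = .25))
gen <- generate_cohort(cfg)
head(gen$truth[, c("case_id", "class", "edv_ml", "ef", "wall_thickness_mm")], 4)
#>    case_id class    edv_ml        ef wall_thickness_mm
#> 1 case_001   DCM 105.35040 0.2909583          6.293771
#> 2 case_002   RVA  57.66766 0.4814489          7.230314
#> 3 case_003   HCM  38.01973 0.5757173         12.486461
#> 4 case_004   DCM  90.49765 0.2822970          6.394589

tab <- extract_feature_table(gen$cohort, "standard")
round(tab[1, c("lv.ef", "lv_myocardium.septum_thickness.mean")], 4)
#>    lv.ef lv_myocardium.septum_thickness.mean
#> 1 0.2883                              6.7517

res <- nested_cv(tab, outer_folds = 4, inner_folds = 3, seed = 1)
print(res)
#> <cmr_cv> 3 outer folds; pooled accuracy 1.000, macro AUC 1.000
#>   selected: logistic(shape_cardiac), logistic(shape_cardiac), logistic(all)
```

The EF of the first (DCM) case, 0.2883, recovers its programmed 0.2910 from
the mask alone; the mean septum thickness, 6.75 mm, sits between the
programmed end-diastolic wall of 6.29 mm and its thickened systolic values,
as a cycle average should.  The four phantom classes separate perfectly
because their geometry priors do (folds are reduced to 3 with a warning at
this small n).  `improvement_loop()` runs the full
corrupt → classify → flag → correct → re-classify experiment and reports
the accuracy before and after simulated expert correction.

A thin command-line wrapper is installed with the package
(`system.file("cli", "cardioloop", package = "cardioloop")`) with
subcommands `simulate`, `extract`, `outliers`, `train`, `importance`,
`loop` and `run`.

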