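# shapegrade

Non-invasive grading support for meningiomas from tumor *shape*. Given a
binary segmentation mask of the contrast-enhancing tumor component (NIfTI,
with voxel spacing), `shapegrade` computes four size-invariant 3D markers
and runs the full grading statistics against WHO grade and mitotic rate.

**The markers.** With total volume *TV* (mm³) and total surface area *TS*
(mm²) measured on a watertight iso-surface mesh of the mask:

* surface regularity — S_R = 6·√π · TV / TS^(3/2); 1 for a sphere, → 0 for
  fractal-like surfaces
* sphericity — (36π · TV²)^(1/3) / TS; satisfies sphericity^(3/2) = S_R
  exactly (both are computed from the same mesh)
* elongation — √(λ_minor/λ_major), flatness — √(λ_least/λ_major), from the
  population-covariance eigenvalues of the foreground voxel centers
  ("inverse" radiomics convention: **lower = more elongated / flatter**)

All four decrease with increasing surface irregularity and tumor grade, so
ROC analyses for high-grade detection use an explicit `lower_is_positive`
direction.

**The statistics** (`run_grading_analysis()`): per marker, OLS regression on
mitotic rate (R², p), one-way ANOVA across grades, pairwise two-tailed
t-tests (Welch by default, pooled switchable), ROC/AUROC with stratified
bootstrap or DeLong 95% CIs for the contrasts 1 vs 3, {1,2} vs 3 and
1 vs {2,3}, and Youden cutoffs for grade-1 and grade-3 identification.

A synthetic module makes the whole pipeline testable without patient data:
spherical-harmonic-perturbed ball phantoms with controllable irregularity,
and cohort simulation calibrated to published grade-wise means
(n = 62/71/19; S_R 0.59/0.55/0.45; sphericity 0.69/0.63/0.55; elongation
0.85/0.84/0.73; flatness 0.66/0.65/0.52; mitotic-rate means
0.83/2.73/24.84). See `vignettes/shape-grading-methods.Rmd` for the models,
calibration derivations and limits.

## Worked example

```r
library(shapegrade)

# a digital ball, radius 20 mm at 1 mm spacing, through the full marker stack
compute_features(make_ball(20))
#> <shape_features>
#>   TV 3.311e+04 mm^3   TS 5011 mm^2
#>   surface regularity 0.9927   sphericity 0.9951
#>   elongation 1.0000   flatness 1.0000
```

A perfect sphere has S_R = 1; the 0.7% deficit is the discretization cost at
this resolution (the closed-form value is exact in the package's own tests).

```r
coh <- simulate_cohort(cohort_spec(seed = 1))   # 152 cases, 62/71/19 per grade
rep <- run_grading_analysis(coh, ci = "none")
print(rep)
#> <grading_report> n per grade: 62/71/19
#> surface_regularity  means 0.591/0.545/0.462 | ANOVA F=23.2 p=1.7e-09 | R2=0.112 | AUROC 1v3 0.90, 12v3 0.84, 1v23 0.71
#> sphericity          means 0.698/0.631/0.547 | ANOVA F=31.9 p=3e-12 | R2=0.058 | AUROC 1v3 0.94, 12v3 0.86, 1v23 0.77
#> elongation          means 0.843/0.834/0.716 | ANOVA F=21.9 p=4.7e-09 | R2=0.093 | AUROC 1v3 0.88, 12v3 0.87, 1v23 0.60
#> flatness            means 0.661/0.666/0.526 | ANOVA F=16.4 p=3.8e-07 | R2=0.110 | AUROC 1v3 0.86, 12v3 0.85, 1v23 0.58
```

Reading it: grade-wise marker means fall from grade 1 to 3; all four ANOVAs
are strongly significant; discrimination is best for the 1-vs-3 contrast
(AUROC ≈ 0.86–0.94) and weakest for 1 vs {2,3}; the regression R² against
mitotic rate is small (~0.06–0.11) — the association is real but weak. The
grade-3 cutoff selected for surface regularity in this run is
`S_R < 0.517` (sensitivity 0.84, specificity 0.75).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "shapegrade", package = "shapegrade"))')
Rscript "$CLI" simulate --out sim --seed 11                 # features.csv (tabular)
Rscript "$CLI" simulate --out simg --seed 11 --mode geometric   # NIfTI masks + cohort.csv
Rscript "$CLI" features --cohort simg/cohort.csv --out feats [--isotropic 1.0] [--largest-component]
Rscript "$CLI" analyze  --features sim/features.csv --out report.json [--ttest welch|pooled] [--ci bootstrap|delong|none]
```

Per-case failures in `features` are logged and skipped (non-zero exit);
every run is reproducible bit-for-bit from its seed and config, and
`report.json` embeds the resolved configuration and package version.

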