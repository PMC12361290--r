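# casm

Whole-joint cartilage thickness mapping and surface-based statistical
parametric mapping for knee osteoarthritis morphometry, in R.

Regional summaries (mean thickness per anatomical subregion) discard the
spatial pattern of cartilage loss. Cartilage surface mapping instead
measures thickness at **every vertex** of a triangle mesh of the bone
surface, registers all subjects to a canonical template so vertices
correspond across a cohort, and fits a general linear model at each
vertex with principled control of the tens of thousands of simultaneous
tests. `casm` implements that pipeline end to end for researchers in
quantitative musculoskeletal imaging:

* **Thickness measurement** — from a paired outer/inner surface by
  ray casting along vertex normals, or from per-vertex 1-D image
  intensity profiles by model-based deconvolution: the profile is fitted
  with two Gaussian-blurred steps,
  `y(x) = L_out + (L_cart − L_out)·Φ((x − x_outer)/σ) + (L_bone − L_cart)·Φ((x − x_inner)/σ)`,
  and thickness is `x_inner − x_outer`.
* **Registration** — closed-form similarity alignment (Umeyama) started
  from principal-axis candidates and refined by iterative closest point,
  followed by a 3-D thin-plate spline warp (kernel `U(r) = r`);
  per-vertex correspondence by closest-point projection with barycentric
  field transfer.
* **Vertex-wise inference** — ordinary least squares per vertex,
  `t(v) = c'β̂(v) / √(c'(X'X)⁻¹c · σ̂²(v))`, residual smoothness estimated
  from edge-wise gradients of the normalised residuals, and a
  significance threshold taken as the **minimum of** the random field
  theory peak threshold (expected Euler characteristic of the t field,
  Worsley densities over resels R0, R1, R2) **and** the
  Benjamini–Hochberg FDR threshold, two-sided at α = 0.05.
* **Model catalogue** — the analysis plan as data: univariable and
  multivariable demographic models, pathology models (KL grade, joint
  space narrowing, meniscal extrusion, bone marrow lesions, osteophytes)
  adjusted for sex, age and height, MOAKS compartment scores as
  subregion maxima, presence/absence subregional models with an `n < 20`
  exclusion rule, and JSN models adjusted for ipsilateral meniscal
  extrusion.
* **Synthetic data** — canonical femur/tibia-like patches, a cohort
  generator matching the published demographic and pathology mix of a
  287-patient knee OA cohort, smooth ground-truth effect maps and
  spatially correlated noise, so every stage is testable without
  patient data.

## Worked example

Simulate a 287-subject cohort with known demographic effect maps on a
synthetic femoral patch, fit the multivariable sex contrast, and map
where cartilage is thicker in men:

```r
library(casm)

mesh <- make_canonical_patch("femur", n_vertices = 1000, seed = 1)
ds <- simulate_cohort_dataset(cohort_spec(n_subjects = 287, seed = 7),
                              scenario = "demographics", mesh = mesh, seed = 7)
design <- build_design(ds$cohort, "multi_sex")   # sex adjusted for age, weight, height
spm <- run_spm(ds$thickness_matrix, design, mesh)
spm
#> <casm_spm> 1015 vertices analysed, df = 282, FWHM = 6.12 mm
#>   thresholds: RFT 4.037, FDR 2.127, final 2.127 (alpha = 0.05)
#>   significant vertices: 707 (69.7%)

glance(spm)[, c("fwhm_mm", "resels_2", "t_threshold_final", "n_significant")]
#>   fwhm_mm resels_2 t_threshold_final n_significant
#> 1    6.12     87.3              2.13           707

cor(spm$beta["sex", ], ds$effects$effects$sex)
#> [1] 0.854
autoplot(spm)          # t map; non-significant vertices washed out
```

Reading the output: the residual fields have an effective smoothness of
6.1 mm FWHM, giving 87 two-dimensional resels; at α = 0.05 the FDR
threshold (|t| ≥ 2.13) is less conservative than the random-field peak
threshold (4.04), so it sets the final mask. 707 vertices — the
trochlear bump where the generator placed the 0.5 mm male–female
difference plus the mild widespread component — survive correction, and
the fitted effect map correlates 0.85 with the planted truth on this
seed. A full multi-stage run (simulation → per-subject registration →
SPM → mean/SD maps, with logs and a reproducibility manifest) is one
call: `run_pipeline(run_config("out_dir", ...))`.

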