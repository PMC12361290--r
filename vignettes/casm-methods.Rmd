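---
title: "Methods: cartilage surface mapping and surface SPM in casm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cartilage surface mapping and surface SPM in casm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`casm` analyses the spatial distribution of articular cartilage
thickness over triangle meshes of knee bone surfaces: per-vertex
thickness measurement, registration of every subject to a canonical
template, and vertex-wise general linear models with multiple-comparison
control. This vignette records the model, its assumptions, the tunable
parameters, and the design decisions that were genuinely open.

## Thickness measurement

**Surface pairs.** When outer and inner cartilage surfaces are
available, thickness at an outer vertex is the distance to the first
intersection of the inward-normal ray with the inner mesh
(Möller–Trumbore, origin offset 1e-6 mm against self-intersection).
Rays that miss within `max_thickness` fall back to unsigned
closest-point distance; `max_thickness` defaults to 10 mm, a physiologic
ceiling for knee cartilage. Normals are angle-weighted averages of
incident face normals — the standard estimator on irregular
triangulations; its error is first-order in edge length, which is why
the sphere oracle in the tests uses a fine tessellation. Inconsistent
winding is diagnosed by probing the opposite ray direction: if outward
rays hit while inward rays miss, the function raises an orientation
error rather than returning silently wrong values.

**Intensity profiles.** When only the outer surface and image
intensities along its normals are available, both interfaces are
localised by fitting two Gaussian-blurred intensity steps with three
plateaus (outside / cartilage / bone) and a single point-spread scale
σ shared by both interfaces (one scanner PSF):

$$y(x) = L_{out} + (L_{cart}-L_{out})\,\Phi\!\left(\tfrac{x-x_{outer}}{\sigma}\right)
       + (L_{bone}-L_{cart})\,\Phi\!\left(\tfrac{x-x_{inner}}{\sigma}\right).$$

The three plateaus are linear parameters and are profiled out by least
squares at every trial of the nonlinear triple (outer position,
separation ≥ 0, σ within `psf_bounds`, default 0.1–1.0 mm); the
nonlinear part is optimised by bounded quasi-Newton iterations from up
to 8 seeded starts at pairs of gradient-magnitude extrema. When the
line search aborts on a flat gradient, a derivative-free polish
confirms (or refutes) convergence. A fit is reported `converged` only
if the optimiser converged *and* the fitted contrast exceeds four times
the residual noise scale — flat profiles are flagged, not fitted.

Noiseless forward-model profiles are recovered to ~1e-6 mm. Under
noise the estimator is efficient: its per-interface RMSE matches the
Cramér–Rao bound of the six-parameter model within a few percent
(at 0.25 mm spacing, 2% noise and σ = 0.4 mm the bound itself is
≈ 0.015–0.019 mm per interface, and no unbiased estimator can do
better; the tests assert efficiency against that bound rather than an
arbitrary absolute number). Non-converged fits and separations below
`min_separation` (0.25 mm) are encoded as thickness 0 with a quality
flag — the same encoding as denuded bone — so cohorts stay complete and
downstream models can exclude flagged vertices if desired.

## Registration

Subjects are aligned to the canonical template in three stages:

1. **Similarity initialisation.** Closed-form least-squares similarity
   (SVD-based, always a proper rotation) inside an iterative
   closest-point loop over a farthest-point vertex subset (default 500
   points). The loop is started from the four proper principal-axis
   alignments; using only these (no identity candidate) makes the whole
   registration exactly equivariant under rigid motion of the subject,
   a property the tests check to 1e-6 mm.
2. **Thin-plate spline refinement.** `n_control` (default 400)
   farthest-point control points on the canonical surface are paired
   with their current closest points on the subject and a 3-D TPS is
   refitted `iterations` (default 5) times. The kernel is U(r) = r; the
   bordered system is assembled internally with the −r (conditionally
   positive definite) sign plus the ridge λ, because with the +r matrix
   a positive diagonal ridge acts as a *negative* penalty — bending
   energy would first grow with λ. With the CPD assembly the energy is
   non-negative, decreases monotonically in λ, and the warp tends to
   the least-squares affine fit as λ → ∞. λ defaults to 1e-3 × mesh
   diameter. The system is solved in centred unit-scale coordinates
   with one step of iterative refinement; interpolation at λ = 0 is
   exact to ~1e-9 mm. Distance matrices use coordinate-wise
   differences, not the expanded-square identity, which loses six
   digits near r = 0.
3. **Correspondence.** Every warped canonical vertex is projected to
   its closest point on the subject mesh (candidate faces from the 8
   nearest vertices, exact point-triangle closest points) and stored as
   face + barycentric weights. Correspondences farther than 3× the
   median subject edge length are marked missing (extrapolation guard);
   a residual RMS above that guard flags the registration
   non-converged, never silently.

Field transfer is barycentric interpolation — exact for linear fields,
bounded by the subject field's range by convexity. One caveat is
inherent to all geometry-only surface registration: the *surface* is
recovered to ~0.03 mm RMS under a 2 mm synthetic warp, but tangential
correspondence on a featureless patch is not identifiable, so
corresponded points can slide ~1–2 mm along the surface. Transferred
values are therefore accurate in proportion to the field's in-surface
gradient; the acceptance check uses a 0.006 mm/mm field (≈0.5 mm
variation across an 80 mm patch, a typical thickness-map slope).

## Vertex-wise inference

At each vertex, ordinary least squares with the cohort design matrix;
the contrast t statistic uses the pooled per-vertex error variance with
n − p degrees of freedom and two-sided Student p-values. Two-sided
inference is deliberate: thickness differences in either direction are
of interest (both thinning with pathology and the thicker anterior
cartilage seen with increasing disease states), and the result maps
carry the sign of t as the direction. Vertices missing in any subject
are dropped for all subjects (complete-vertex analysis) — simpler and
conservative — and the smoothness/resel computation runs on the
retained sub-mesh.

**Smoothness.** Residual vectors are normalised to unit norm per
vertex; for each edge, the squared difference of normalised residuals
summed over subjects divided by squared edge length estimates the
variance of the spatial derivative of the unit-variance error field;
pooling over edges gives λ̄ and FWHM = √(4 ln 2 / λ̄). This is the
estimator for which "pre-smoothed at FWHM w" is recovered as w (the
tests verify 8 mm within 20%). For discrete white noise its expectation
is FWHM = √(2 ln 2 / mean(1/len²)) ≈ 1.13× the mean edge length once
the mixed unit/diagonal edge lengths of a grid are accounted for; the
white-noise test freezes that derived closed form.

**Thresholds.** The random-field-theory threshold solves
E[EC](t) = α/2 (two tails) by bisection to 1e-6, with the standard
t-field Euler-characteristic densities over resels
(R0 = Euler characteristic, R1 = boundary/2FWHM, R2 = area/FWHM²).
The FDR threshold is Benjamini–Hochberg step-up on the vertex
p-values, mapped back to the |t| of the smallest rejected statistic.
The final criterion is the **minimum** of the two — the less
conservative, read literally from the combined-correction rule — and
the package verifies by simulation that the union still controls the
family-wise error on null cohorts (empirical FWER ≈ 0.03 at nominal
0.05 over 200 simulations; the two rejection events are driven by the
same extreme statistics, so their union is far below the Bonferroni
sum). Pre-smoothing of thickness maps before the GLM is exposed
(`smooth_fwhm`, mean-preserving graph diffusion calibrated in mm) but
**off by default**: the upstream description of this analysis style
does not smooth, even though related surface-statistics toolchains
commonly do.

**Model catalogue.** Ordinal grades (KL 0–4, JSN 0–3, MOAKS 0–3) enter
as linear covariates — per-grade slopes are the reported quantity.
Compartment scores are subregion maxima. Binary subregional models use
presence/absence and are excluded when fewer than 20 subjects are
affected (boundary inclusive: exactly 20 is analysed). Sex is coded
male = 1 so positive coefficients mean thicker cartilage in men. The
radiographic-OA dichotomy (KL ≥ 2) ships as an exploratory model.

## The synthetic generator

The generator emulates the study conditions so every stage is testable
at desk scale. Demographics: 22% male; age 66.4 (7.1) y; height
167.1 (10.0) cm with male subjects 10 cm taller on average
(sex-conditional means constructed so the *marginal* mean and SD stay
at the configured values); weight 78.2 (15.8) kg correlated 0.4 with
height; BMI is **derived** as weight/height² rather than drawn
independently — an independent BMI would contradict the height/weight
collinearity that justifies excluding it from multivariable models.
KL grades follow the multinomial (54, 76, 63, 84, 10)/287; compartment
prevalences of grade > 0 are 60/16% (extrusion medial/lateral),
35/24/56% (BMLs medial/lateral/patellofemoral), 79/64/67%
(osteophytes), 47/15% (JSN medial/lateral), with conditional grades
1–3 at (0.5, 0.35, 0.15). Subregion scores are spread so the
compartment maximum equals the drawn grade exactly.

Geometry: the canonical femur is an open saddle-like sheet with two
condylar bumps and a trochlear groove; tibiae are gently domed
elliptical discs; triangulations are jittered but quality-bounded
(min angle > 15°, edge-length CV < 0.5). Region names (trochlea,
medial femur, …) are parametric-coordinate analogues on these synthetic
patches, not anatomical claims. Baseline thickness is a smooth
1.4–2.6 mm field, thinner medially. Effect maps are smooth regional
bumps at the reported per-unit magnitudes (0.5 mm sex peak in the
trochlea, −0.035 mm/y age, +0.025 mm/cm height, −0.2…−0.5 mm per
pathology grade, +0.3 mm anterior thickening per osteophyte grade)
with a default bump FWHM of 25 mm. That width is a calibration, not a
fit: the generator's contract is that effect recovery at n = 287 with
0.3 mm noise is attainable (median β̂-to-truth correlation ≥ 0.9 over
seeds); with the per-vertex OLS noise floor ≈ 0.043 mm for the sex
contrast at that n, compartment-scale (25 mm) regions meet the
contract while small 18 mm spots cannot, for any estimator. Noise is
white Gaussian diffused to FWHM = 3× the mean edge length and rescaled
to SD 0.3 mm per field; thickness is clipped at zero (clip fraction
reported, < 1% at defaults) mimicking denuded bone. Subject geometry is
a random similarity (scale 0.9–1.1, rotation ≤ 10°, translation ≤ 5 mm)
followed by a random landmark-interpolating TPS of amplitude 2 mm, with
the generating transforms retained as ground truth. All randomness
flows from one root seed through fixed arithmetic sub-streams.

What passing tests do **not** show about real data: no MRI artefacts,
partial-volume or pulse-sequence effects; deformations are not
biomechanically constrained; pathology grades are sampled independently
of the thickness field (unless coupled explicitly), so confounding
structure present in patients is absent; and the synthetic patches are
far smoother than segmented anatomy. The generator supports the
*software's* correctness claims, not clinical ones.

## Problem sizes and runtime choices

The shipped tests run the spheres oracle at ~2,500 vertices, the
deconvolution Monte-Carlo at 100 replicates, registration recovery at
2,000 vertices, the null FWER study at 200 cohorts × 100 subjects ×
~1,000 vertices, and effect recovery at 10 cohorts of 287 × ~1,000 —
sizes at which the statistical contrasts of interest are resolvable
while the whole suite completes in a couple of minutes on one core.
The FWER study draws all cohort noise through a single prebuilt
diffusion operator per mesh, which is what makes 20,000 smooth fields
cheap.

## Known limitations

* Cross-sectional models only; no longitudinal or mixed-effects
  support, and no interaction or non-linear terms.
* Peak-level RFT only (no cluster-extent inference).
* Geodesic quantities (smoothing, FWHM) are edge-graph approximations.
* Tangential registration correspondence is unidentifiable on smooth
  featureless patches (see above); transferred maps inherit that
  blur.
* The deconvolution model assumes three plateaus and a shared Gaussian
  PSF; layered cartilage signal or non-Gaussian blur is not modelled.
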