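---
title: "Inertia-based bone positioning and discriminant sex estimation: methods and design notes"
author: "osteoinertia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inertia-based bone positioning and discriminant sex estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoinertia)
```

This vignette explains what the package computes, the assumptions behind each
step, and the design decisions taken where the method left choices open. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The measurement model

### Gray values and voxel mass

CT attenuation is carried on a shifted scale with air at 0 and water at 1024,
i.e. `gray = HU + 1024`, calibrated over −1024 to 4145 HU. Each voxel of a
segmented bone is treated as a **point mass** `m_i = g_i / 1024` at its
center. Mass is therefore dimensionless ("water-equivalent voxels") and the
inertia tensor has units mass·mm². Two consequences:

* Treating voxels as point masses omits each voxel's own second moment,
  a `spacing²/12` term per axis. The omission is O(h²) and cancels in
  normalized quantities; `mass_properties(..., self_moment = TRUE)` adds the
  exact cuboid correction (the unit tests show it reproduces the continuum
  cube moment to rounding).
* The density variable `d = mean(g_i)/1024` is a unitless HU ratio
  (water = 1), not a calibrated mineral density.

### The body frame

The bone's coordinate system is intrinsic: origin at the density-weighted
COM, axes along the principal axes of inertia. For an elongated bone the
long (head-to-base) axis has the *smallest* principal moment and is labeled
**z**. The transverse axes are ambiguous from eigenvalues alone: the
reference tables themselves show that the plantar–dorsal moment exceeds the
medial–lateral one for some metatarsals and not others, so no fixed
eigenvalue-order rule can reproduce anatomy for all five bones.
`principal_frame()` therefore accepts approximate anatomical reference
directions (e.g. scanner "up" for a supine, feet-first posture) and labels
x/y by maximal |cosine| with them; without references it falls back to
x = intermediate moment, y = largest moment, and records which rule was used.

Axis *signs* never affect the eight variables (extents and moments are
sign-invariant). Without references, the z sign is fixed by requiring the
third central moment of mass along z to be non-negative — a stand-in
convention for head-vs-base direction, flagged as such — and the frame is
completed right-handed.

Near-degenerate moment pairs (relative gap below `1e-6` of the largest
moment) raise an error asking for references rather than silently picking an
arbitrary basis; a sphere-like body simply has no intrinsic transverse axes.

### Surface, extents, and the eight variables

The surface is extracted by **marching tetrahedra** (each grid cube split
into six tetrahedra around a fixed diagonal; the decomposition is
translation-invariant, so shared faces match and the mesh is watertight by
construction; an explicit edge-pairing check is available). Two numerical
choices matter:

* **Field smoothing.** Contouring a raw binary mask yields the midpoint
  staircase: exact for axis-aligned planes but heavily biased for oblique
  smooth surfaces (the suite measures +27% area on a 0.25 mm sphere). One
  separable 3-voxel box-filter pass before contouring encodes the local
  surface orientation in the field and drops the sphere area error to about
  +0.5%, with symmetric profiles keeping flat faces exactly at the
  half-voxel boundary. The cost is that *sharp edges* are chamfered over
  about one voxel (−8% area on a 10 mm cube at 0.5 mm). Bones are smooth at
  CT resolution, so smoothing is the default; synthetic polyhedral phantoms
  should be contoured with `smoothing = FALSE`. Structures thinner than the
  smoothing support fall back to raw contouring automatically.
* **Extents from mesh vertices.** `Lp, Wp, Hp` are ranges of surface-vertex
  coordinates in the body frame, not of voxel centers, avoiding the
  half-voxel shrinkage of center-based ranges.

Area is the triangle-area sum; volume uses the divergence theorem and is
reported positive regardless of global orientation; `SA:V` uses the
mesh-enclosed volume by default (`volume_from = "voxels"` gives
`N · h³` instead). Both normalized triplets are stored as **fractions
summing to one**; the ×100 of the defining equations is presentational
(the reference tables print fractions), available via `percent = TRUE`.

## 2. Segmentation

`segment_bone()` is a deliberate, minimal emulation of the reconstruction
protocol: inclusive gray-value band threshold, then morphological closing
with a discrete Euclidean ball (default radius 1 voxel; the original
software's kernel is undocumented). Hole filling and largest-component
filtering are **off by default** — matching the protocol — and available as
explicit opt-ins. The bone threshold has *no default*: the protocol
deselected the predefined bone preset without stating the band, so the
threshold is a required, recorded parameter. The closing radius is counted
in voxels; with anisotropic spacing it is therefore anisotropic in mm,
which is documented rather than resampled away.

## 3. Dimorphism statistics

* `sdi()` is antisymmetric under sex swap and scale-invariant; its sign says
  which sex is larger.
* `compare_sexes()` implements the dispatch: Shapiro–Wilk per sex and
  Levene's test (centered on the mean, the SPSS convention) at α = 0.05;
  both normal + homoscedastic → pooled *t*; normal + heteroscedastic →
  Welch; any non-normality → Mann–Whitney U. The full audit trail (all
  driving p-values) is returned. Normality is assessed per sex, not pooled.
  No multiple-testing correction is applied, matching the reporting
  convention the registry functions came from; `p.adjust` can be applied
  downstream by the user.
* `assumption_battery()` gives Mardia's multivariate skewness/kurtosis per
  sex (ML covariance convention), within-sex Mahalanobis distances with
  χ²(p) tail probabilities (outlier iff p < 0.001), and Box's M with its χ²
  approximation (pass iff p > 0.001). Both 0.001 thresholds are parameters.
  Note that the *full* eight-variable set is exactly collinear by
  construction (each triplet sums to one), so the battery must be run on a
  subset — the error names the offending variables.
* `icc_agreement()` is the two-way mixed-effects, absolute-agreement,
  single-measurement ICC: the natural form when the two "raters" are repeat
  scan/reconstruction passes over the same bones. The exact null spread is
  wide at n = 60 (SD ≈ 0.13), which the tests acknowledge.
* `correlation_screen()` flags |Pearson r| > 0.80 among variables (the
  multicollinearity exclusion rule feeding discriminant variable choice) and
  reports Spearman correlations against body height/weight when covariates
  exist. Screening operates per bone record; whether one should average
  sides per subject first is left to the caller.

## 4. Discriminant analysis

`sdfa()` is the package's modelling centerpiece, in the classic
formula-interface idiom. The canonical direction is
`w ∝ Sp⁻¹ (x̄₁ − x̄₂)` with `Sp` the pooled within-group covariance, scaled
so the pooled within-group score variance is exactly 1, and shifted so the
case-weighted overall mean score is 0 (hence equal group sizes give
symmetric centroids). Standardized coefficients are `a_j · sd_pool(x_j)`;
the structure matrix is the pooled within-group correlation between each
variable and the score, computed as `(Sp a)_j / sd_pool(x_j)` (score SD
is 1). Wilks' Λ is `det(W)/det(T)`; its test is Bartlett's
`−(n − 1 − (p + g)/2) ln Λ` on p df — the suite checks this reproduces the
printed χ² of the registry's first left function from its printed Λ at
n = 59.

**Stepwise selection** enters, at each step, the candidate minimizing the
overall Λ provided its partial F-to-enter ≥ 3.84, then removes any included
variable whose partial F-to-remove < 2.71 (smallest first), iterating to a
fixed point with a cycle guard. Partial F uses the Λ-ratio form
`F = (Λ_small/Λ_large − 1)(n − g − p)/(g − 1)` with `p` the size of the
smaller model and g = 2; for p = 0 this reduces to the one-way ANOVA F. An
empty selection is a valid result, not an error. The tests verify the whole
path against an independent oracle that enumerates Λ for *all* subsets via
`stats::manova` and replays the gates from that table, and verify the
canonical direction against `MASS::lda`.

**Sign convention.** The canonical axis sign is arbitrary; fitted models
orient it so the largest-|standardized-coefficient| variable is positive,
while the registry stores printed signs verbatim. Classification — side of
the sectioning point matching the side of each group's centroid, exact ties
"indeterminate" — is invariant to the convention.

**Leave-one-out.** `loo_accuracy()` refits coefficients on each n−1 subset
with the variable set *fixed* (matching the cross-validation semantics of
the software the published functions came from); `reselect = TRUE` repeats
the stepwise selection inside every fold for a stricter protocol. Reports
carry per-sex counts/percentages and totals for both the original and
cross-validated blocks.

**Registry.** `published_functions()` returns the ten published side- and
metatarsal-specific functions with coefficients, constants, Λ, χ²,
standardized coefficients, structure matrices, centroids and sectioning
points stored exactly as printed, keyed by side and metatarsal.
`mt_reference_stats()` exposes the reference cohort's per-sex mean/SD/range
for all eight variables, sides, and metatarsals. Reproduction tolerances
follow the printing precision: scoring 3-dp rounded means against
coefficients of magnitude up to ~65 propagates half-ULP input error to
roughly 0.03, hence the ±0.05 band used when recovering printed centroids.

## 5. Synthetic data

### Phantoms

Phantoms compose spheres, ellipsoids, cuboids and elliptical cylinders, each
with closed-form mass and inertia, combined by the parallel-axis theorem —
an *exact* oracle for the voxel estimators. Voxelization is by
center-inclusion on a grid centered on the composite bounding box, so
symmetric bodies rasterize symmetrically and their voxel COM matches the
analytic COM to rounding. Analytic masses are continuous (density × mm³)
while voxel masses are per-voxel, so oracle comparisons use specific
(mass-normalized) moments, which are convention-free. Primitives must not
overlap (tangency is fine); overlap would double-count analytic mass.

The `metatarsal_phantom()` preset is a stylized elongated body — an
elliptical-cylinder shaft with two tangent ellipsoidal ends of different
size — chosen to have three distinct principal moments, nonzero mass
skewness along z (so the sign convention engages), and gross metatarsal-like
proportions (~66 mm long, density 1.6). It is *not* anatomical: no
curvature, no trabecular structure, no cortical shell, and its tangent necks
pinch to zero width. Passing the equivariance and oracle suites on it shows
the *pipeline* is correct and pose-independent, not that real metatarsals
will show the reference cohort's effect sizes.

`random_rigid_transform()` rotates the *geometry* (uniform quaternion
rotation, ±2 mm translations) and re-voxelizes at the same spacing. This is
deliberate: re-voxelizing the underlying solid is the honest model of
re-scanning in a new pose, whereas resampling an already-voxelized volume
would convolve two discretizations.

### Cohorts

`simulate_cohort()` draws per-sex multivariate normals with the reference
per-sex means and SDs as defaults (any subset overridable), rejects and
redraws records outside the printed min/max envelopes (projection-clipping
would pile probability on the bounds), then renormalizes both triplets to
sum to one. Variables are **independent by default** because only marginal
statistics were published; a correlation matrix can be supplied, and
simulated classification accuracies are approximate to the extent real
variables co-vary. Optional height/weight covariates use realistic
young-adult East-Asian values (male 176.6 ± 5.5 cm, female 163.5 ± 5.2 cm,
weights coupled to height), chosen once as plausible and documented here;
`sa_v_height_r` couples SA:V to height through the latent normals for the
correlation-screening tests.

## 6. Problem sizes and what the tests show

Validation scales chosen for the suite (a few minutes end to end): phantom
oracles at 0.25 mm voxels (≈0.6–1.4 M voxels; COM to 1e−6 mm, specific
moments within 1%); rigid-motion equivariance with 100 seeded poses of the
metatarsal preset at 0.4 mm (relative SD of every normalized variable below
1.5%); stepwise-vs-enumeration agreement on 200 random small cohorts
(n ≤ 20, p ≤ 3, 100% agreement required); 100-seed cross-validated accuracy
on cohorts simulated from the left-third-metatarsal reference statistics
(≥90% total accuracy in ≥90 seeds); Mardia null uniformity at n = 500 × 200
replicates and Box's M size at 200 nulls.

What passing these does *not* show: agreement with the original subjects'
raw test statistics and accuracies (their scans are not available), the
behavior of the segmentation on real CT noise, metal artifacts or partial
volumes, and population transferability of the registry functions — the
registry is population-specific by construction, and refitting via `sdfa()`
on a local cohort is the supported route.

## 7. Known limitations

* DICOM series are not read directly; convert to NIfTI/MetaImage first.
* Anatomical x/y labeling without reference directions follows eigenvalue
  order and can swap width/height for bones whose plantar–dorsal and
  medial–lateral moments invert (the first metatarsal, per the reference
  tables); supply `anatomical_refs` when anatomy matters.
* The head-vs-base z sign uses a skewness convention, not anatomy.
* Mesh smoothing chamfers sharp edges; disable it for polyhedral solids.
* ICC form is fixed to absolute-agreement single-measures; other forms are
  out of scope.
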