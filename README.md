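# osteoinertia

Forensic sex estimation from CT scans of metatarsal bones, using geometric
*and* inertial bone properties. The package is aimed at forensic
anthropologists and osteometry researchers who have a segmented (or
segmentable) CT density volume of a metatarsal and want reproducible,
posture-independent measurements and a sex classification.

## The method

Manual osteometry depends on how the bone is oriented. Here the bone defines
its own coordinate system from its mass distribution:

1. **Positioning.** Each voxel gets a mass `m_i = g_i / g_w`, where `g_i` is
   its gray value and `g_w = 1024` is water (air is 0, so gray = HU + 1024).
   The center of mass (COM) becomes the origin, and the three principal axes
   of inertia (PAI) — the eigenvectors of the inertia tensor about the COM —
   become the body axes. The long (head-to-base) axis carries the smallest
   principal moment and is labeled *z*; the plantar–dorsal axis is *x* and
   the medial–lateral axis is *y*. Any rigid motion of the scan leaves the
   positioned bone unchanged, which is the point.

2. **Eight variables.** From the positioned bone: normalized extents
   `Ln = Lp/(Lp+Wp+Hp)` (likewise `Wn`, `Hn`), the surface-area-to-volume
   ratio `SA:V = S/V` (1/mm), the relative bone density
   `d = (1/N) Σ g_i/g_w`, and the three normalized principal moments of
   inertia `PMIk / (PMIx+PMIy+PMIz)`. Both normalized triplets sum to 1, so
   the shape descriptors are scale-free.

3. **Dimorphism and classification.** Cohort statistics include the sexual
   dimorphism index `SDI = (X̄m − X̄f)/(X̄m + X̄f) × 100` and a test-dispatch
   rule (Shapiro–Wilk and Levene checks choosing pooled *t*, Welch, or
   Mann–Whitney). Sex classification uses two-group stepwise discriminant
   function analysis on Wilks' Λ with partial-F gates (enter 3.84 / remove
   2.71): the fitted function `Y = a₁x₁ + … + aₙxₙ + C` is scaled to unit
   pooled within-group variance, group centroids are the scores of the group
   means, and the equal-priors sectioning point is their midpoint.
   Leave-one-out cross-validation reports honest accuracies, and the ten
   published metatarsal discriminant functions (five per side) ship as a
   ready-to-use registry.

Because no CT scans are distributable, the package also contains a
first-class synthetic module: voxel phantoms (sphere, ellipsoid, cuboid,
elliptical cylinder, and a stylized metatarsal) with *closed-form* mass
properties as oracles, and a cohort simulator parameterized by the reference
cohort's per-sex means, SDs and ranges.

## Worked example

Measure a synthetic metatarsal in a random scanner pose and classify it with
a published function:

```r
library(osteoinertia)

spec <- random_rigid_transform(metatarsal_phantom(voxel_size = 0.4), seed = 7)$spec
ph   <- make_phantom(spec)
mask <- segment_bone(ph$volume, lower = hu_to_gray(226),
                     upper = hu_to_gray(4145), close_radius = 1)
rec  <- measure_bone(ph$volume, mask, side = "left", metatarsal = 3L)
rec
#> <bone_record> left MT3 (unknown)
#>      Ln      Wn      Hn    sa_v density   pmi_x   pmi_y   pmi_z
#>  0.6873  0.1459  0.1668  0.4685  1.5925  0.4906  0.4933  0.0161
predict(published_function("left", 3), rec, type = "score")
#> [1] 3.684
predict(published_function("left", 3), rec)
#> [1] "female"
```

The record reads: the positioned bone's length is 68.7% of the summed
extents, its normalized long-axis moment (`pmi_z` = 0.016) is far below the
transverse moments (elongated body), and its SA:V of 0.47/mm — well above
the male mean of the left third metatarsal (0.386) — drives the score of
3.68 past the sectioning point on the female side. Re-running with a
different pose seed changes these numbers only in the fourth decimal: the
positioning is rigid-motion equivariant.

Fitting your own function on a (here: simulated) cohort:

```r
cohort <- simulate_cohort(cohort_spec("left", 3), seed = 1)
fit <- sdfa(sex ~ sa_v + Hn + density + pmi_z + Wn, cohort)
fit
#> <sdfa> fitted two-group discriminant function
#>   Y = +55.2*sa_v -61.25*Hn -11.05
#>   Wilks' lambda 0.1671, chi-square 102 (df 2), p = 7.11e-23
#>   centroids: male = -2.195, female = 2.195; sectioning point 1.776e-15
loo_accuracy(fit)
#> <classification_report> 60 cases, variables: sa_v, Hn
#>   original:      male 30/30 (100.0%)  female 30/30 (100.0%)  total 100.0%
#>   cross-validated: the same on this seed
```

The stepwise gate kept `sa_v` and `Hn` and discarded the three noise-level
candidates; with equal group sizes the centroids are symmetric and the
sectioning point is zero to rounding.

A thin command-line wrapper exposes the same pipeline
(`system.file("cli", "osteoinertia", package = "osteoinertia")`) with
subcommands `segment`, `align`, `measure`, `stats`, `sdfa`, `classify` and
`simulate`.

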