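# labyrinthometry

Automated 3-D morphometry of the inner ear from labeled voxel volumes.

Quantitative studies of Meniere's disease and endolymphatic hydrops need
reproducible measurements of cochlear and vestibular anatomy from
ultra-high-resolution CT (0.1 mm isotropic) of the temporal bone.
Manual calipers on 2-D slices are subjective and miss the spatial
relationships between structures. Given a segmentation of the bony
labyrinth — one integer label each for the cochlea, vestibule and the
posterior/lateral/superior semicircular canals (PSC/LSC/SSC) — this
package computes a fixed panel of anatomical metrics, and ships the
synthetic phantoms and cohort simulators needed to validate every step
without patient data. It is aimed at neuroradiology and otology imaging
groups and at methodologists who want a tested reference implementation
of the measurement chain.

## What it computes

**Cochlea** — principal component analysis of the voxel coordinates
gives the cochlear coordinate system: the spiral lies in the plane of
the first two axes and the third (least-variance) axis is the modiolar
axis. In the calibrated plane, the round window is the max-x point, the
basal long diameter (BLD) is the farthest distance from it, and the
basal short diameter (BSD) is the largest perpendicular extent in the
rotated basal frame. Cochlear height (CH) is the axial extent along the
modiolar axis. Duct lengths are affine regressions on BLD:

    CDL = 4.16 · BLD − 4
    2TL = 3.65 · (BLD − 1)
    BTL = 2.43 · (BLD − 1)        (all mm)

Each modiolus–canal angle is `θ = arccos(u·n / |u||n|)` between the
modiolar axis `u` and the total-least-squares canal-plane normal `n`,
folded into [0°, 90°].

**Vestibule** — voxel-count volume plus a least-squares ellipsoid fit:
after rotation into the PCA frame, `(x/a)² + (y/b)² + (z/c)² = 1`
linearizes to `AX + BY + CZ = 1` with `X = x²` etc., solved by ordinary
least squares over surface voxels. The fit yields principal diameters
A ≥ B ≥ C, central cross-section areas `π/4 · d₁d₂` (AB, AC, BC), and
nine folded angles between the section-plane normals and the three
canal planes.

**Statistics** — three-group (affected / unaffected / control ears)
one-way ANOVA with post hoc pairwise tests, Spearman correlations of
metrics with ordinal endolymphatic-hydrops grades, duration-stratified
t tests, and demographic summary tables.

**Synthetic data** — `phantom_spec()` / `assemble_labyrinth()` build a
five-structure voxel phantom (helical cochlear tube, ellipsoidal
vestibule, partial-torus canals) with exact ground truth for every
quantity the chain estimates; `cohort_spec()` / `simulate_cohort()`
draw measurement-level cohorts with configurable group effects, a
calibrated ordinal hydrops-grade link and disease-duration structure.

## Worked example

```r
library(labyrinthometry)

spec <- phantom_spec()                 # default labyrinth at 0.1 mm
asm  <- assemble_labyrinth(spec)
print(asm$volume)
#> label_volume: 221 x 125 x 112 voxels @ 0.1 x 0.1 x 0.1 mm
#>   cochlea    label 1: 61073 voxels
#>   vestibule  label 2: 32360 voxels
#>   PSC        label 3: 7407 voxels
#>   LSC        label 4: 8721 voxels
#>   SSC        label 5: 7866 voxels

fits <- lapply(c(PSC = "PSC", LSC = "LSC", SSC = "SSC"), function(nm)
  fit_plane(extract_voxel_cloud(asm$volume, nm)$points_mm))

measure_cochlea(extract_voxel_cloud(asm$volume, "cochlea"), fits)
#> Cochlear metrics
#>   volume 61.07 mm^3 | BLD 8.72  BSD 7.92  CH 3.91 mm
#>   CDL 32.28  2TL 28.18  BTL 18.76 mm
#>   modiolus angles: LSC 58.0  PSC 74.0  SSC 41.3 deg

measure_vestibule(extract_voxel_cloud(asm$volume, "vestibule"), fits)
#> Vestibular metrics
#>   volume 32.36 mm^3 | lengths A 6.15  B 4.61  C 2.20 mm
#>   areas AB 22.25  AC 10.61  BC 7.95 mm^2
```

The phantom was built with a 4.0 mm axial extent, a ~8.8 mm maximal
basal chord, canal planes at 57.89°/73.92°/41.52° to the modiolar axis
and vestibular semi-axes 3.07/2.295/1.095 mm: CH is recovered within
0.1 mm, BLD within 0.12 mm, the angles within 0.2° and the diameters
within 0.5%. Statistics run the same way on simulated cohorts:

```r
rec <- simulate_cohort(cohort_spec(seed = 1))   # 105/105/100 ears
three_group_comparison(rec, "CH_mm")
#> CH_mm: F = 0.947, p = 0.3889 (bonferroni post hoc)
#>   MDAE n=105  4.037 +/- 0.243
#>   MDUE n=105  4.021 +/- 0.254
#>   HC   n=100  3.991 +/- 0.226
```

A thin command-line front end (`exec/labyrinthometry`) exposes
`simulate-phantom`, `measure`, `simulate-cohort` and `stats`
subcommands over the same functions, and `run_pipeline()` orchestrates
measurement of a directory of NIfTI volumes joined to a clinical
metadata table into the full set of report tables.

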