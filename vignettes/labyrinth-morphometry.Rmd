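---
title: "Measuring the bony labyrinth: models, phantoms and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the bony labyrinth: models, phantoms and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Ultra-high-resolution CT of the temporal bone resolves the bony labyrinth
at 0.1 mm isotropic voxels, and automated segmentation yields one integer
label per substructure: cochlea, vestibule, and the posterior, lateral
and superior semicircular canals (PSC, LSC, SSC). `labyrinthometry` turns
such a labeled volume into a fixed panel of scalar anatomical metrics.
Everything downstream of segmentation is geometry: the package never
touches image intensities, only voxel labels, their spacing and their
world coordinates.

A voxel with 0-based index $(i, j, k)$ has its center at
$\mathrm{origin} + (\mathrm{index} + \tfrac12)\,\mathrm{spacing}$ per
axis. This convention is fixed in one place (`extract_voxel_cloud()`)
and shared by every module; the NIfTI sform is written so that voxel
coordinates address voxel centers, which makes the write–read–extract
cycle lossless. Structure volumes are always voxel counts times the
voxel volume computed from the header spacing — at 0.1 mm isotropic
spacing one voxel is 0.001 mm³. The conversion is never hard-coded:
only this constant reproduces cochlear volumes of ~75 mm³ and
vestibular volumes of ~54 mm³ from plausible voxel counts at this
resolution.

# Cochlear chain

The cochlea spirals about its modiolus, so principal component analysis
of the voxel coordinates supplies a natural *cochlear coordinate
system*: the spiral lies in the plane of the first two principal axes
and the third (least-variance) axis represents the modiolar axis. PCA
eigenvectors carry a sign ambiguity; we resolve it by a documented
convention (largest-magnitude component positive, third axis flipped to
keep the frame right-handed) and require — and test — that every
reported metric is invariant to the underlying sign.

In the calibrated plane (`coords2`):

* the **round window** is the point of maximal first coordinate (ties
  broken by maximal second coordinate);
* the **basal long diameter** (BLD) is the maximal Euclidean distance
  from the round window to any other point;
* the **basal short diameter** (BSD) rotates the plane so the
  round-window-to-far-point line lies on +x, groups points into x bins,
  and takes the maximal within-bin y range. Continuous coordinates never
  share an exact x value, so the bin width (default: one voxel spacing)
  stands in for "points sharing the same x-coordinate". Halving the bin
  width on dense data moves BSD by less than two bin widths (tested).

**Cochlear height** (CH) is the axial extent $\max Z - \min Z$ of the
calibrated coordinates. A literal mode computing
$\max|Z| - \min|Z|$ is retained for fidelity experiments; on centered
PCA coordinates it returns roughly half the anatomical height, while
published CH values (~4 mm) match the full axial extent, so extent mode
is the default.

**Duct lengths** are affine regressions on BLD:

$$\mathrm{CDL} = 4.16\,\mathrm{BLD} - 4,\qquad
  \mathrm{2TL} = 3.65\,(\mathrm{BLD}-1),\qquad
  \mathrm{BTL} = 2.43\,(\mathrm{BLD}-1)\ \text{(mm)}.$$

A transcribed intercept form $-4.16\,\mathrm{BLD}-4$ circulates in some
sources; it yields negative lengths for every positive BLD, while the
corrected sign reproduces the published group means (BLD 9.08 mm gives
CDL 33.77 mm) to two decimals. The package refuses the literal form
with an explanatory error.

**Modiolus–canal angles.** Each canal is summarized by a total
least-squares plane (normal = eigenvector of the smallest covariance
eigenvalue; no axis is privileged, so orthogonal regression is the
right fit). The angle between the modiolar axis and each canal is the
arccos of the normalized dot product with the canal-plane normal,
*folded* into [0°, 90°] as $\min(\theta, 180°-\theta)$. Folding makes
the result insensitive to the arbitrary orientation of both vectors;
every published inter-structure angle is ≤ 90°, consistent with this
choice. Whether "the canal" in the angle formula means the plane normal
is the one genuinely open reading in the printed procedure; we use the
normal because it is the only interpretation under which the arccos
formula is well defined for a planar structure.

# Vestibular chain

The vestibule is approximately ellipsoidal. The canonical equation
$(x/a)^2 + (y/b)^2 + (z/c)^2 = 1$ becomes linear,
$AX + BY + CZ = 1$ with $X = x^2$ etc., once the ellipsoid is
axis-aligned. The printed three-coefficient form contains no cross
terms, so we first rotate the points into their PCA frame — which makes
the ellipsoid approximately axis-aligned — and then solve the
overdetermined linear system by ordinary least squares; semi-axes are
$1/\sqrt{\text{coef}}$. A 9-parameter general quadric mode (cross and
linear terms, eigendecomposition of the quadratic form) is available
behind `method = "general"` for sensitivity analysis; on exact samples
both modes agree to 1e-6.

Two discretization choices matter at 0.1 mm:

* **Surface selection.** Fitting the surface equation to *solid* voxel
  clouds biases semi-axes low by ~15% (tested); the fit therefore uses
  surface voxels, defined as occupied voxels with at least one empty
  6-neighbor. The PCA frame and center still come from the full solid
  cloud, which is denser and yields axis directions good to ~0.05°.
* **Half-voxel correction.** Boundary-voxel centers sit on average half
  a voxel inside the continuum surface, so each recovered semi-axis is
  enlarged by spacing/2. With this correction the recovered diameters
  of a voxelized ellipsoid with semi-axes 3.07/2.295/1.095 mm are
  within 2% of truth (mostly within 0.5%); without it the smallest
  diameter is ~4% low. The correction applies only to voxel-derived
  surfaces, never to exact surface samples.

Principal *diameters* A ≥ B ≥ C are full axes (twice the semi-axes) —
the published length C of ~2.19 mm is twice a ~1.1 mm semi-axis, and
the central-section areas $\pi/4 \cdot d_1 d_2$ reproduce the published
mean areas within 0.5%. The residual at the group level is structural,
not numerical: the mean of per-subject areas is not the area at the
mean diameters (by Jensen-type covariance terms), so exact equality is
not expected and is not tuned for. Section planes are named by the
diameter pair spanning them; the plane normal is the remaining axis
(AB ↔ C, AC ↔ B, BC ↔ A). The reported vestibular volume is always the
voxel count — by design independent of anything the fit does.

# The labyrinth phantom

No public dataset accompanies the measurement procedure, so the package
ships a voxel phantom generator with exact ground truth; the measurement
chain, not anatomy, is under test.

* **Cochlea**: a conical spiral centerline (2.5 turns, spiral radius
  tapering to 12.5% of its basal value) swept by a sphere of linearly
  tapering radius (1.1 → 0.5 mm); the swept union of stamped balls *is*
  the tube, with hemispherical caps at both ends. Defaults give a ~9 mm
  maximal basal chord, 4 mm axial extent and ~70 mm³ of tube volume.
* **Vestibule**: a solid ellipsoid, default semi-axes
  3.07/2.295/1.095 mm (analytic volume 32.3 mm³), optionally perturbed
  by a smooth random radial field for robustness experiments.
* **Canals**: partial tori (default 75% arcs, major radii 2.8–3.1 mm,
  minor radii 0.40–0.45 mm) lying exactly in planes whose normals sit at
  the population-mean angles to the modiolar axis (LSC 57.89°, PSC
  73.92°, SSC 41.52°).

**Moment alignment.** The measurement chain defines the modiolar axis
*operationally* as the least-variance PCA axis. A naive conical helix
has its mass centered low and outward, so its PCA frame is tilted 3–6°
from the coil axis and rotated ~35° in-plane — the ground truth would
then be systematically wrong for the quantity the chain estimates. The
generator therefore computes the continuous tube model's first and
second moments (disc cross-sections by quadrature along the centerline,
plus the end caps) and builds the phantom in the frame where that
tensor is diagonal. It also solves the nominal coil height so the
model's true axial extent equals the requested `height_mm`. Ground
truth is then exact for modiolar axis, axial extent and maximal basal
chord, and the voxel-level chain recovers them to ~0.2°, ~0.1 mm and
~0.1 mm respectively.

**Round-window localization accuracy.** The max-x rule can only localize
the round window to the voxel-lattice band of the outer basal arc: on an
arc of radius $\rho \approx 4.4$ mm at spacing $h = 0.1$ mm, any voxel
within $\Delta x \le h$ of the extreme x can win, which corresponds to an
arc slide of up to $\rho\sqrt{2h/\rho} \approx 1$ mm. The tests
therefore require the measured round window to lie on the outer edge of
the basal turn within 1 mm of the constructed basal endpoint; a tighter
bound would test the lattice, not the method. BLD itself is insensitive
to this slide (the far point moves with the near point), which is why
BLD is recovered ~10× more tightly than the landmark that anchors it.

**What the phantom does not emulate**: real cochlear turns merge through
the bony septum (the phantom's turns at most touch, so its voxel volume
of ~61 mm³ sits below the published ~75 mm³ mean); the vestibule is not
a true ellipsoid (hence published voxel volumes of ~54 mm³ versus
32.3 mm³ for the fitted-scale ellipsoid — the package's volume comes
from voxel counts precisely so this discrepancy does not propagate);
there is no CT noise, partial-volume effect or segmentation error; and
the basal short diameter of a circular swept tube is an emergent
quantity, not an input — the phantom spec deliberately has no BSD field.
Passing phantom tests therefore demonstrates correctness of the
geometry chain at study resolution, not robustness to segmentation
artifacts.

# Simulated cohorts

`simulate_cohort()` works at the *metric* level: per-ear metric values
are drawn directly from group-specific Gaussians, which makes power
studies over thousands of cohorts affordable. The generating means and
SDs default to the published three-group values (e.g. cochlear height
4.06/4.02/3.98 ± 0.22 mm for affected/unaffected/control ears at
n = 105/105/100). A mechanistic alternative
(`measure_phantom_cohort()`) voxelizes and measures jittered phantoms;
it validates the chain end to end at small n.

Design choices, each configurable:

* Duct lengths and section areas are *derived* from the drawn BLD and
  vestibular diameters by the same formulas the measurement chain uses,
  so simulated records satisfy the package's internal identities and
  reproduce the near-identical F statistics of BLD-derived metrics.
* Affected and unaffected ears are paired per patient (shared
  demographics and duration); metric values are drawn independently, and
  group comparisons use the unpaired one-way ANOVA that the published
  analysis used. A paired analysis would be a natural extension; it is
  deliberately not the default so simulated results remain comparable.
* Disease duration is a three-stratum mixture (<1, 1–5, >5 years at
  3.81/40.95/55.24%); long-duration affected ears receive additive
  vestibular size shifts (+2.73 mm³ volume, +0.19 mm length B), with
  stratum baselines offset so the overall group mean is preserved.
  Long duration means strictly >5 years; the strictness and cutoff are
  arguments because published stratum labels are ambiguous at exactly
  5 years.
* Vestibular EH grades (0–3) arise from a thresholded latent Gaussian
  correlated with one driver metric (default: the modiolus–SSC angle,
  target Spearman 0.243). The latent Pearson correlation is calibrated
  *analytically*: the population Spearman between a normal metric and a
  graded latent has a closed form up to one-dimensional quadrature
  (`spearman_of_latent()`), inverted with `uniroot()`. Discretization
  into four grades attenuates rank correlation, so the calibrated
  latent correlation (0.269) exceeds the target; empirical cohorts at
  n = 105 recover 0.243 ± 0.10. The published grade split for grades
  2–3 of the vestibule is not printed; the default (28.57/9.52%) keeps
  the printed "no EH" (14.29%) and grade-1 (47.62%) frequencies and
  allows grade 3, whose existence the published imaging example
  documents. A single latent driver cannot simultaneously reproduce the
  published positive (modiolus–SSC) and negative (AB–PSC/AB–SSC)
  correlations; the generator models the positive one and leaves the
  rest null.

# Statistics

All inference uses base R: `aov()` for the one-way ANOVA,
`pairwise.t.test()` (Bonferroni) or `TukeyHSD()` post hoc — the
published analysis does not name its adjustment, so Bonferroni is the
default and both are tested — `cor.test(method = "spearman")` with
average ranks and asymptotic p values (grades are heavily tied, so
exact p values are unavailable anyway), and pooled-variance `t.test()`
for the duration strata (matching conventional SPSS output; Welch is a
flag). A constant grade vector yields a flagged `NA`, never a silent
zero. Normality is assumed throughout, as in the source analysis; there
is no automatic nonparametric fallback.

Calibration is verified by simulation: under the null the three-group
ANOVA rejects at 5.0% (4,000 independent cohorts), and at the published
cochlear-height effect scale the analytic power is 63.6%
(noncentral F with $\lambda = 6.77$), matching the simulated 64%.

# Problem sizes and numerical notes

The test suite and acceptance script use: phantoms at the study
resolution of 0.1 mm (~61,000 cochlear voxels; coarse 0.2 mm phantoms
where only plumbing is under test); 100 random rigid poses for the
invariance study (pose-to-pose coefficient of variation < 2% for every
length, SD < 2° for every angle — cochlear height is the widest mover
because the voxel-center extent loses up to one spacing per end
depending on grid phase); 1,000 simulated cohorts each for null
calibration and power; 100 replicate cohorts for the EH-correlation
calibration. Degenerate inputs fail loudly and early: collinear clouds,
non-ellipsoidal fits (any nonpositive solved coefficient), empty
structures, zero-variance ANOVA, strata of size < 2, tubes thinner than
two voxels. Planar clouds are accepted by the PCA frame (the third
axis is the plane normal, supporting the flat-disc limit of the
cochlear chain); only collinear clouds are rejected.

# Limitations

CDL is regression-derived from BLD, not traced along the duct; the
ellipsoid model ignores vestibular surface detail by construction; the
phantom tests discretization and geometry, not segmentation quality;
and simulated cohorts inherit the independence assumptions listed
above. These mirror the stated limitations of the measurement procedure
itself and bound what a green test suite demonstrates about real ears.
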