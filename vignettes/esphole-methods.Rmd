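---
title: "Sector-validated detection of metal-centered pi-holes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sector-validated detection of metal-centered pi-holes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esphole)
```

## The problem and the model

Dicationic tetraazamacrocycle complexes {TM(cyclen)}²⁺ are
pseudoplanar: the metal sits in (or near) the plane of its four
nitrogen donors, leaving the axial directions open. Depletion of
electron density along the pseudo-z axis can create a **π-hole** — a
local enhancement of the electrostatic potential above the metal that
steers nucleophiles into axial (semicoordination-like) contacts.

The classical surface descriptor V_s,max (maximum ESP over the
ρ = 0.001 e bohr⁻³ isodensity surface) cannot diagnose this feature on
cations: every {TM(cyclen)}²⁺ fragment has a large positive V_s,max
whether or not its axial region is special. `esphole` therefore
measures a candidate *against its own angular background*:

* a candidate is a local ESP maximum on the π-axis (first derivative
  changes sign + to −, second derivative negative), found by scanning
  the interpolated grid from the N₄ centroid to `zmax = 3.0` Å at
  `step = 0.05` Å in both hemispheres, laterally confirmed against
  eight probes on the 1.0 Å candidate-cylinder wall;
* its background is the cylinder of radius 2.5 Å, height ±0.25 Å
  around it, split into eight 45° azimuthal sectors, each sampled with
  1000 evenly distributed points; the sector means V̄ᵢ give

  V_hole,mean = V − mean(V̄ᵢ),  V_hole,max = V − min(V̄ᵢ),
  V_hole,min = V − max(V̄ᵢ),  ΔV_hole = max(V̄ᵢ) − min(V̄ᵢ),

  and ΔV_angle, the circular separation of the extreme sectors'
  center angles (a multiple of 45°);
* the candidate is **valid** iff V_hole,mean > Δ_thr = 5 kcal/mol, a
  threshold excluding minor surface undulations.

One deliberate reading is baked in: in all V_hole formulas the hole
potential is the **candidate's own local-maximum ESP**, not the global
surface maximum. The global reading is arithmetically inconsistent
with strongly positive surface maxima coexisting with negative
V_hole,mean values on hole-free complexes (such rows occur on real
crystallographic geometries); the global value is still computed and
reported separately as `Vs_max`.

## The aligned frame

All descriptors live in a molecule-intrinsic frame: the centroid of
the four donor nitrogens is the origin; the normal of their
least-squares plane (smallest-variance direction) is the π-axis; the
in-plane x-axis is the projection of the shortest N–N difference
vector, with y completing a right-handed triad — i.e. the two shortest
noncollinear N–N vectors fix the in-plane orientation. Points map as
`(r - centroid) %*% Rot`.

Two conventions make the frame stable under rigid motion of the input,
which the test suite verifies directly:

* near-equal N–N distances (within 10⁻⁶ Å, the generic case for
  near-square donor sets) tie-break to the lowest donor-index pair
  rather than to floating-point noise;
* the normal's sign makes the donors wind counterclockwise in ring
  order viewed from +z; when substituent role tags are present, the
  majority U side overrides it. Both hemispheres are always analyzed,
  so the sign only affects labels.

τ₄ = [360° − (α + β)] / 141°, with α ≥ β the two largest
donor–metal–donor angles, quantifies the square-planar (0) to
tetrahedral (1) distortion. Angles use the `atan2(|u×w|, u·w)` form:
`acos` loses half the significant digits exactly at the 180° trans
angles of the square-planar reference, where the index must vanish to
high accuracy.

## Structure generation

Templates place the 12-membered N-C-C ring on a circle (z = 0) with
N–C 1.47 Å, C–C 1.54 Å, the radius solved so the chord angles close;
hydrogens are added by local tetrahedral construction (C–H 1.09 Å, N–H
1.02 Å), with the N–H z-sign following the U/D letter and non-UUUU
patterns produced by mirroring hydrogens across the plane. Exact
template values are internal choices — downstream engines re-optimize
geometries — but every constant that the detection or substitution
logic depends on (1.47 Å N–C on substitution, 0.8 Å clash, 10°
rotation, 1.5 Å RMSD) is part of the method's parameter registry
(`run_config()`) and is exercised by tests.

The U/D conformer space of a 4-ring collapses to four classes under
ring rotation, ring reflection and global inversion; the canonical
representative minimizes the number of D letters and then sorts
lexicographically, yielding UUUU, DUUU, DDUU, DUDU. A brute-force
orbit partition of all 16 strings serves as the oracle in the tests.

Substitution replaces an N–H hydrogen by a rigid Me/Et template whose
root carbon sits 1.47 Å along the former N–H vector; if any
interatomic distance falls below 0.8 Å the group rotates about that
axis in 10° steps (0°–350°, first pass wins — a deterministic
tie-break; a dense 1° replay in the tests confirms the first passing
grid angle is selected). The rotation-zero reference direction is
anchored to the nearest ring carbon (pointing away from it), keeping
the construction equivariant under rigid motion; exact ties break to
the lowest atom index.

With 4 metals, 4 conformers and the {H, Me, Et}⁴ patterns the
enumeration yields 16 unsubstituted plus 1280 substituted structures —
1296 in total, none rejected by the clash rule and none collapsed by
the RMSD filter.

**RMSD filter scoping.** Kabsch superposition in the canonical
generated atom order is only chemically meaningful when the element
*sequences* agree index-wise (multiset equality would pair carbons
onto hydrogens), and the U/D conformer label — like the metal — is
part of a dataset entry's identity: on planar templates two conformers
differ only by mirrored N–H hydrogens, a ~0.3 Å RMSD that does not
make them the same entry. `dedup()` therefore compares rows within
(metal, conformer) groups with identical element sequences. The filter
still catches true redundancies — a doubled manifest has all its
second copies flagged — and is idempotent.

## Synthetic fields

`field_spec()` fields are deterministic sums of point-charge Coulomb
terms (k = 332.0637 kcal Å mol⁻¹ e⁻¹; distances below 0.1 Å clamped to
0.1 Å so fixture voxels stay finite — a region the detectors never
sample, since fixture scans start 0.5 Å from the centroid where the
metal charge sits) and Gaussian ESP features `A exp(−d²/2w²)`.
Model densities are Gaussians in e bohr⁻³; the 0.001 isosurface of a
unit Gaussian of width σ bohr is the sphere r = σ√(2 ln 1000), which
the marching-edge extractor recovers to within one voxel. V_s,max is
evaluated on this edge-crossing point set, not on raw voxels: voxel
masks move values by O(spacing).

The reference fixture (`axial_depletion_spec()`) places +2 e at the
origin, four −0.4 e at the donor positions, and one axial Gaussian
(A = 80 kcal/mol, w = 0.3 Å). A Gaussian *centered* at the target
height would peak below it once superposed on the decaying Coulomb
background, so the generator solves for the center (root finding on
the analytic axial derivative, near branch so the Gaussian curvature
dominates) that puts the analytic on-axis maximum exactly at the
requested height — 2.1 Å by default, the middle of the 1.8–2.4 Å band
where such holes live. The amplitude must exceed |V′_bg| · w · e^½
(≈ 41 kcal/mol here) for such a maximum to exist at all; the default
80 also makes it a strong, clearly curved maximum.

What these fields emulate: the smooth long-range shape, sign structure
and axial anisotropy of a cationic complex's ESP. What they do not:
short-range penetration effects, the true molecular density (and hence
realistic V_s,max magnitudes), and chemically meaningful sector
asymmetries from substituents. Passing tests therefore demonstrate the
*detector's* correctness (localization, relative-descriptor
arithmetic, invariances), not chemical predictions for real
complexes.

## Numerical choices

* **Units.** Å, kcal mol⁻¹ e⁻¹ and e bohr⁻³ internally; cube files
  convert with 0.52917721 Å/bohr and 627.5095 kcal mol⁻¹/hartree on
  read/write. Cube values are assumed hartree (the common
  Multiwfn/ORCA convention) with a flag to override.
* **Interpolation.** Trilinear; exact at voxel corners and on linear
  fields, second-order on smooth ones (the test suite checks the ~4×
  error reduction when spacing halves).
* **Axial scan.** `zmin = 0` by default (the path originates at the
  centroid); point-charge fixtures are scanned with `zmin = 0.5` Å
  because their nuclear sites are genuine singularities, unlike the
  bounded grids a QM code exports.
* **Sector sampling.** Deterministic stratified: m³ points per sector
  with m = ⌊(n + ½)^{1/3}⌋ (1000 → 10×10×10), uniform in r², θ, z over
  the full wedge (inner exclusion radius available, default 0). A
  seeded uniform-random sampler exists behind a flag for robustness
  checks. A 10⁶-sample Monte-Carlo oracle agrees with the stratified
  means to 0.5% on Coulomb backgrounds; sharp non-harmonic ESP
  features sitting inside the sector volume can push trilinear means a
  few tenths of a percent further.
* **Grid sensitivity.** Recomputing the fixture suite at 0.25 and
  0.20 bohr changes V_s,max and the three V_hole descriptors by well
  under 5%; ΔV_hole — a small difference of similar numbers (≈ 0.7
  kcal/mol on the near-symmetric fixture) — shows the largest relative
  grid dependence of the set, a property of the descriptor rather than
  of the resolution.
* **Equivariance.** Descriptors are invariant under rigid motion of
  molecule + field. The strict (10⁻³ kcal/mol) form of this check uses
  lattice-preserving motions (90° rotations plus whole-voxel
  translations), where regenerated grids are strictly comparable;
  generic rotations additionally re-sample the field and are covered
  by the grid-sensitivity bound instead.
* **Statuses.** "No candidate" (no axial maximum exists) and "failed
  validation" (a maximum exists but V_hole,mean ≤ Δ_thr) are distinct
  outcomes; multiple validated maxima in a hemisphere keep the largest
  V as primary, the rest in a secondary list.
* **Occurrence.** `cmd_report()` counts a complex as showing a hole if
  *any* hemisphere validates, and aggregates per (metal, conformer);
  over valid rows it reports mean ± sd of the hole height and of
  V_hole,mean, plus mean τ₄ and mean M–N distance.

## Problem sizes

The shipped suite runs the full 1296-structure enumeration with
deduplication, fixture grids of roughly 10⁵–10⁶ voxels (0.25 bohr
spacing, compact boxes for multi-spacing comparisons), a 1° × 360
dense replay of the clash scan, 1000 random quads for the plane-fit
oracle and 8 × 10⁶ Monte-Carlo points for the sector oracle — sizes
chosen so every oracle is meaningfully stronger than the path it
checks while the whole suite stays interactive.

## Known limitations

* No QM: ESP and density come from external cubes or the synthetic
  generators; the package never computes wave functions, and stub
  engine inputs are the only bridge to xTB/DFT codes.
* RMSD deduplication uses the canonical generated atom order; it is
  not a graph-isomorphism duplicate detector for structures from other
  sources.
* Scalar-field cubes only (negative atom counts — MO cubes — are
  rejected); rectilinear grids only.
* The axial search is a 1-D scan along n̂ with lateral confirmation; a
  hole displaced more than the candidate radius off-axis would be
  missed by design (σ-holes along bond axes are out of scope).
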