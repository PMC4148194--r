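---
title: "Volumetric analysis of binding-site electrostatics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric analysis of binding-site electrostatics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epsolid)
```

## The idea

Electrostatic comparison methods usually reduce a potential field to a
score. `epsolid` instead keeps the field's *shape*: the level set of the
potential at a threshold `k` (kT/e) bounds a closed three-dimensional solid,
and solids support exact boolean reasoning. Two proteins' fields can then be
compared region by region — the intersection of their isopotential solids is
where their electrostatics agree, the differences are where they disagree —
and every such region has a volume in ų that can be tracked across
perturbations. All objects (fields, occupancies, boundary meshes) live on
one regular cubic lattice in the coordinate frame of the input structures.

Sign convention: for positive `k` the solid is the region with potential
`>= k`, for negative `k` the region `<= k`; the complementary regions are
infinite in volume, so `k = 0` is rejected. Exact equality counts as inside,
making solids topologically closed.

## Isopotential extraction

`marching_cubes()` classifies every lattice point against the threshold and
places one boundary vertex on every lattice edge joining an inside point to
an outside point, at the linear-interpolation parameter
`t = (k − φ₁)/(φ₂ − φ₁)`. Per-cube triangle layouts come from a 256-entry
case table.

The table is *generated*, not transcribed: on each cube face (corners in
counter-clockwise order viewed from outside the cube) every maximal run of
inside corners contributes one directed segment from its entering crossing
to its leaving crossing. This rule is face-local, so the two cubes sharing a
face always agree on the segment pairing — including on ambiguous
("saddle") faces, where it amounts to the fixed convention that inside
corners are separated. Segments chain into closed loops over the cube's
crossing edges; each loop is fanned into triangles whose right-hand normals
point outward. No asymptotic decider is used; at the ≤ 0.5 Å resolutions
the package targets, all downstream quantities are volumes and the fixed
convention is sufficient.

Consequences worth knowing:

* **Closedness.** The surface is watertight by construction in the 2-cycle
  sense: every directed edge is balanced by a reverse copy. At non-manifold
  voxel junctions (two solids touching along a lattice edge, as arise in
  arbitrary boolean combinations) an undirected edge may be shared by four
  triangles instead of two; the enclosed volume remains well defined, and
  `mesh_is_closed()` tests exactly this zero-boundary condition.
* **Clipping.** A solid that reaches the lattice border is capped with
  faces on the border plane (a warning is emitted): volumes are always
  finite and well defined, but a clipped solid is a truncation of the true
  one — enlarge the lattice if the warning appears in an analysis that
  depends on absolute volumes.
* **Volumes** are computed by the Surveyor's (divergence-theorem) formula
  `|Σ det[v₁ v₂ v₃]|/6` over the boundary triangles and cached; an
  independent voxel-count oracle (`voxel_volume()`, spacing³ × inside
  points) is used throughout the tests.

## CSG on the lattice

`csg()` realizes intersection, union and difference on the point occupancy
(pointwise AND / OR / AND-NOT — exact, so idempotence, annihilation and
partition identities hold bit for bit) and re-extracts the boundary from the
combined interpolation field (`min`/`max` of the operands' fields). Where a
crossing comes from a single operand its interpolated position is inherited
unchanged — a no-op CSG keeps the boundary bit-identical — and where the
operands disagree with the combined occupancy the edge midpoint is used.

Mesh-level volume identities (e.g. `V(A−B) + V(A∩B) = V(A)`) hold to a
tolerance that is dominated by cubes straddling the *rim* where the two
operand surfaces intersect; this error shrinks roughly linearly with the
spacing. The test suite therefore checks such 1 %-level identities at the
fine end (0.25 Å) of the resolution range, and excludes features thinner
than the lattice itself (slivers of a few voxels), which no lattice-CSG
method can measure meaningfully. Practical analyses at 0.5 Å are calibrated
for volumes of tens to hundreds of ų, the scale at which cavity and
interface fields live.

## Potential models

The canonical charge source is a PQR file. Three field models are provided
(`electrostatic_model()`); both built-in models are *linear-response*
stand-ins for a full nonlinear Poisson–Boltzmann solve, chosen because the
package's contribution is the field→solid→CSG analysis, and any external
grid can be injected where nonlinear PB fidelity matters:

* `debye_huckel` (default): screened Coulomb superposition
  `φ(p) = Σᵢ ℓ·qᵢ·exp(−κdᵢ)/(ε_solvent·dᵢ)`, with
  `ℓ = e²/(4πε₀k_BT)` ≈ 560.5 Å at 298.15 K so that potentials are in
  kT/e. Distances are clamped at half a lattice spacing (configurable), so
  grids stay finite at atom centers; values inside that clamp radius are
  not meaningful.
* `fd_lpb`: finite-difference linearized PB,
  `∇·(ε∇φ) − ε_s κ²φ = −4πℓρ`, 7-point stencil with harmonic-mean face
  permittivities, `ε_solute` (default 4) inside the union of atom balls and
  `ε_solvent` (default 80) outside, κ² active in solvent only, trilinear
  charge spreading, Debye–Hückel Dirichlet boundaries, solved by SOR
  (ω = 1.8) until the largest Gauss–Seidel update falls below 1e-5 kT/e.
  The discrete point-charge solution deviates from 1/r at one-to-two cells
  from a source (an intrinsic property of the stencil); beyond two cells it
  tracks the closed form to a few percent, and the Born-ion exterior matches
  the Debye–Hückel form to better than the 8 % the tests require.
* `external_grid`: an OpenDX scalar grid, matched exactly or resampled
  trilinearly.

Nullification (`nullify_residue()`) zeroes one residue's charges and touches
nothing else: under `fd_lpb` the residue's atoms still shape the dielectric
mask, so the electrostatic focusing caused by its uncharged volume is
preserved (the tests assert mask invariance). Both models are linear in the
charges, so nullification equals subtracting the residue's own field.

For interface fields, each partner's field is computed from its own charges
*alone* but at complex coordinates; under `fd_lpb` the partner's atoms are
retained (uncharged) in the dielectric mask by default
(`partner_dielectric = TRUE`) — the bound-geometry, single-side-charged
convention. This dielectric treatment is genuinely open in a linear-response
setting; it is exposed as a flag rather than hidden.

## Surfaces, regions, cavities

The molecular (solvent-excluded) surface is a morphological closing of the
union of atom balls by the probe radius (default 1.4 Å, water; the probe is
a free parameter since the underlying rolling-probe literature it imitates
does not pin it). The erosion step is computed as a power-distance
transform against probe centers: every lattice point whose probe ball
clears the protein covers a complement ball whose radius is known
*analytically* (clearance + probe), which makes the boundary placement
second-order accurate in the spacing instead of first-order; only a thin
shell of centers just above the clearance threshold is needed (any covering
center can be slid toward the covered point until its clearance enters the
shell), which also keeps the field's gradients symmetric across the boundary
for edge interpolation. The SES occupancy always contains the union of
balls.

Interface residues are those with any atom within 5 Å of the partner (all
atoms count, hydrogens included if present; no solvent-exposure filtering,
since buried hot spots matter). The interface region is the union of 5 Å
balls around every atom of those residues. Binding cavities are *inputs* —
sphere-union tables or closed OFF/PLY meshes — because cavity detection is
a separate problem.

## Scans and thresholds

The cavity scan compares a test protein against a reference cavity field
inside `I = C_test ∩ C_ref`, nullifying one residue at a time and measuring
`v_r = V((E_test,r ∩ I) − (E_ref ∩ I))`. The difference is directed —
nullified test field minus reference — matching the question "which residue
of the test protein creates field the reference lacks"; a `symmetric` flag
adds the reverse direction. The prediction threshold is reconstructed from
the half-reduction principle: `T = (v₀ + min_r v_r)/2`, i.e. a residue is
predicted when nullifying it brings the fields at least half as close as
the best single nullification can. The interface scan measures
`D_r = EC(variant) − EC(reference)` with thresholds `T_u = max_r D_r/2` and
`T_l = min_r D_r/2`, each applied only when fewer than 10 % of scanned
residues cross it — a change most residues produce is not exceptional. Both
threshold formulas are verbal reconstructions of their sources and are
flagged as such in the scan output notes. "Significance" is operationalized
by the thresholds alone (no auxiliary statistics), predictions are
categorical, and relative magnitudes of two predicted residues are
deliberately not ranked.

All residues of the scanned structure are visited, not just interfacial
ones: long-range influence is part of the phenomenon. Salt bridges are
flagged by a distance rule (basic N of Arg/Lys/His within 4 Å of acidic O
of Asp/Glu); a predicted bridge member is labeled `salt_bridge_stability`,
since mutating it would perturb stability as well as the field.

Multi-threshold drivers (`scan_cavity_auto`, `scan_interface_auto`) run the
scan over a ladder (−2.5, −5, −7.5, −10 kT/e for cavities; 1, 3, 5, 7,
9 kT/e for interfaces) and keep the level where the per-residue statistics
spread the most — the calibration surrogate used when no principled `k` is
known for a system. A partner already calibrated on the same complex should
reuse its `k` directly.

Degenerate cases are explicit: a zero baseline (`v₀ = 0`) warns and
predicts nothing; a zero reference EC is an error ("no complementarity at
this k"); nullifying a chargeless residue reproduces the baseline exactly.

## Clustering

`pairwise_jaccard()` builds the distance matrix `1 − V(∩)/V(∪)` (a pair of
empty fields gets distance 0 with a warning — identical emptiness, though
the ratio is 0/0). `upgma()` is a from-scratch UPGMA: merge the closest
pair at height `d/2`, update by size-weighted arithmetic mean, ties broken
by the smallest pair of original label positions — deterministic by
construction. The `d/2` cophenetic convention matches Phylip's `neighbor`
in UPGMA mode; the test suite cross-checks topology and heights against R's
independent `hclust(..., method = "average")` to 1e-9. `to_newick()`
serializes with branch lengths as height differences.

## The synthetic fixtures, and what a green test does not establish

`planted_cavity_pair(seed)` emulates a protease-specificity setup: a 4 Å
spherical cavity ringed by eight neutral residues, identical in test and
reference, with the test protein carrying one extra −1 e residue just below
the cavity base — the planted ground truth — plus ten decoys 20–28 Å out.
The decoys carry partial charges of ±0.5 e (typical polar-atom magnitudes)
or none: far enough that no single decoy can halve the cavity-field
difference, but live enough that the scan faces realistic long-range
competition. `opposing_complex(seed)` places two pseudo-proteins across the
x = 0 midplane: neutral contact residues 2.2 Å off-plane (so the 5 Å rule
fires), a +1 e residue on one side facing −1 e on the other at 6–8 Å
separation, and ten neutral decoys per side (eleven-plus residues per side,
so a single genuine prediction stays under the 10 % suppression rule).

These fixtures emulate the *geometry* of the recognition problems — a
buried charge at a pocket base, an opposing pair across an interface — not
real proteins: point charges instead of distributed partial charges, no
backbone, no conformational response, screened-Coulomb fields instead of
nonlinear PB. A passing recovery test establishes that the volume algebra,
the thresholds and the scan logic do what they claim on systems where the
answer is known by construction; it does not certify accuracy on real
structures, which additionally depends on the quality of the injected
potential grids, protonation and alignment.

## Known limitations

* Nonlinear PB is not solved; absolute volumes from the built-in models
  will not reproduce analyses that used a nonlinear solver's grids. Inject
  DX grids for fidelity.
* Structures must be pre-aligned by the caller; no structural alignment is
  performed.
* Lattice CSG cannot resolve features thinner than the spacing; choose the
  resolution for the smallest feature that matters.
* Meshes may be non-manifold (though always closed) at voxel-contact
  junctions; downstream consumers needing 2-manifolds should resample.
* The formal-charge PDB fallback is a labeled approximation — side-chain
  termini only, fixed van der Waals radii — and is no substitute for a real
  charge assignment.
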