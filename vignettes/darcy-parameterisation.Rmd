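---
title: "From vascular networks to multi-compartment Darcy parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From vascular networks to multi-compartment Darcy parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darcypar)
```

`darcypar` turns a one-dimensional vascular network into the parameter
fields of a multi-compartment Darcy perfusion model and measures how well
the continuum pressures reproduce the spatially averaged network solution.
This vignette explains the model, the averaging machinery, the numerical
choices, and what the package's synthetic test networks do and do not tell
you about real anatomical data.

## The discrete model

Vessels are straight segments between nodes carrying position (mm) and
radius (mm); a vessel's radius is the mean of its endpoint nodal radii and
its flow obeys Poiseuille's law, `Q = C Δp` with conductance
`C = πr⁴/(8µl)` and blood viscosity µ = 0.0035 Pa s throughout. Mass
conservation at junctions gives a weighted graph-Laplacian system in the
nodal pressures, which `solve_network_flow()` solves sparsely
(`Matrix`/CHOLMOD) after eliminating Dirichlet nodes; terminals without a
pressure are natural zero-flux boundaries. The solver enforces a relative
junction mass residual below 10⁻¹⁰ and inherits a discrete maximum
principle from the SPD structure.

## Compartments via the hierarchic parameter

Radius alone cannot partition real networks (distal vessels can be as wide
as proximal ones), so vessels are ordered by the *hierarchic parameter* ζ:
at a node, the summed length of all distal vessels divided by the total
network length — 1 at the inlet, 0 at distal terminals, non-increasing
along every root-to-leaf path. A vessel's ζ̄ is the arithmetic mean of its
endpoint values (the natural choice when nodal fields are interpolated
linearly; a length-weighted alternative would differ only for curved
multi-segment vessels, which the data model does not represent). Looped
networks are rejected — a pressure-based ζ would be needed there, which is
out of scope.

An `N`-compartment partition is a strictly decreasing vector
`Z = (1, …, 0)` of length `N+1`; compartment `i` collects vessels with
ζ̄ ∈ [Z[i+1], Z[i]), half-open at the top with ζ̄ = 1 assigned to
compartment 1. `optimise_partition()` fits the interior entries of `Z` to
target mean radii by minimising the rms deviation of the compartment radius
means, using a deterministic coarse combination search over the observed ζ̄
values followed by coordinate-wise refinement (ties resolve toward larger
thresholds). Because candidate thresholds are data values the search is
exact up to the data resolution and fully reproducible.

For networks that span the arteriolar-to-capillary radius range, targets of
30, 6 and 3 µm are the natural three-compartment choice. The package's
synthetic trees (below) span a narrower range, so by default targets are
derived from the network itself (`derive_partition_targets()`): vessels are
split proximal-to-distal into 4 % / 46 % / 50 % groups — the compartment
proportions typical of a three-compartment arterial partition — and the
group radius means become the targets. The resulting `Z` vectors have the
same structure as the hand-picked ones (interior entries of order 10⁻² and
10⁻³ for a deep tree).

## Synthetic study networks

Two seeded generators supply test data.

**Volume-filling tree.** `generate_volume_filling_tree()` bisects the box
domain (default [-1, 1]³ mm) along alternating axes; every subdomain
receives one branch point at its jittered centroid (jitter: uniform, a
fraction — default 0.3 — of the subdomain half-width), recursively to the
requested depth, giving `2^L` terminals distributed through the domain.
Terminal vessels carry unit flux (1 mm³ s⁻¹), parents the sum of their
daughters, and radii follow `r = (q/α₁)^{1/α₂}·α₃` with defaults
(1, 3, 0.001) — so a terminal vessel has r = 1 µm and a 10-level root
~10 µm. Flux conservation is exact in integer arithmetic and radii are
non-increasing from root to leaves.

**Capillary lattices.** `generate_aligned_lattice()` emulates the
directional preference of imaged capillary beds: near-parallel chains along
one axis (endpoints exactly on the two opposing faces, so those faces carry
the pressure boundary conditions), sparse transverse cross-links, radii
from a truncated normal with mean 5.3 µm and SD 2.3 µm. Defaults are set so
that at least 80 % of the total vessel length lies within ~25° of the fibre
axis while the network stays connected (connectivity is guaranteed by
union-find plus deterministic re-links). `generate_isotropic_lattice()` is
the matching negative control with vessels along all three axes.

What these emulate — and what they do not: the tree reproduces the
*topology* (bifurcating, volume-filling, no loops, no compartment-1↔3
contacts) and the flux-radius coupling of an idealised arterial bed, but
its radii span only ~1–13 µm, its vessel lengths are comparatively
homogeneous within a compartment, and its layout is inherently isotropic.
Anatomical networks have right-skewed length distributions, radius
contrasts of 30× and directional structure. Consequently, passing the
package's tree-based checks shows the pipeline is *consistent* (fields
derived and solved correctly, trends in RVE radius and boundary conditions
as expected); it does not show that the three permeability methods would
rank identically on real data — that comparison is exercised on the
anisotropic lattices, where directional structure exists by construction.

## RVE averaging

All continuum fields are averages over a spherical RVE centred at the
evaluation point and clipped to the domain box. Averaged pressure weights
each vessel's mean endpoint pressure by lumen volume; porosity is lumen
volume over clipped ball volume; the inter-compartment flux sums `C Δp`
over *connector* vessels (compartment-k vessels sharing a node with a
compartment-i vessel). Three numerical choices matter:

* **Partial overlap.** Vessels crossing the ball boundary are weighted by
  the fraction of their centreline length inside (exact segment–sphere
  intersection). The alternative — counting a vessel in or out by its
  midpoint — makes every field discontinuous in the radius and was
  rejected.
* **Clipped volumes.** A ball entirely inside the box uses `4/3 πR³`
  exactly; clipped balls are integrated by seeded Monte Carlo (10⁵ samples
  in the ball), cached per clipping geometry — on a regular grid the
  distances to the nearest faces take only a handful of distinct values,
  so the cost is a few dozen Monte Carlo runs, not one per point.
* **Empty RVEs.** A compartment with no vessel inside the ball yields a
  missing value; fields are completed from the nearest valid grid point,
  with a warning carrying the count. The proximal compartment of a tree
  has few vessels, so at the reference radius an appreciable fraction of
  its averaged-pressure field is filled — this is the practical meaning of
  the coverage lower bound on admissible RVE radii.

The coupling field is `β_ik = |Q_ik| / |p̄_i − p̄_k|`, zero where the
averaged pressures coincide, symmetric in (i, k); the magnitude convention
keeps β ≥ 0 (mass conservation requires the symmetric form) while the sign
of the transfer is carried by the pressure difference in the Darcy system.
The flux's Δp is signed proximal-minus-distal; only its magnitude reaches
β.

## Permeability methods

All three constructions give symmetric positive (semi-)definite tensors in
mm² Pa⁻¹ s⁻¹ at every grid node; `regularize_spd()` floors eigenvalues at
10⁻⁶ × trace so degenerate vessel sets (e.g. all collinear) stay invertible
without switching methods:

1. **Porosity-scaled isotropic**: `K = φ(x) I`. Cheap, direction-blind;
   the baseline any anisotropy-aware method must beat.
2. **Huyghe–Van Campen**: `K_ij = π/(128 vol_RVE δx₀ µ) Σ d⁴Δx_iΔx_j/l`
   over the compartment's vessels in the RVE (fraction-weighted; the
   full-chord and clipped-chord formulations coincide under that
   weighting). `δx₀` is taken as the ζ-width of the compartment's partition
   interval; since every K field is subsequently rescaled by an optimal
   constant, δx₀ only shifts the pre-scale magnitude and is exposed as a
   parameter.
3. **Projected PCA**: each vessel contributes a datum — unit direction
   (signed away from the node nearest the RVE centre) times its
   conductance; the set is reflected through the origin (zero-mean), its
   covariance (population normaliser — immaterial to the eigenvectors)
   eigendecomposed, and each vessel's conductance distributed over the
   eigendirections in proportion to the absolute projections of its
   direction, normalised per vessel. The trace therefore equals the summed
   conductances exactly, a property the tests exploit.

Both anisotropic constructions are rotation-equivariant
(`K → R K Rᵀ`), checked against random rotations at 10⁻⁸ relative.

## The Darcy solve and the test protocol

`build_grid()` meshes the box with trilinear hexahedra (default 16³
elements — grid spacing 0.125 mm on the standard domain; the comparison
metrics are insensitive to refinement beyond this). Assembly uses full
2×2×2 Gauss quadrature with nodal fields interpolated trilinearly to the
quadrature points; the element loop is vectorised over elements, so
assembly is a few hundred vector operations regardless of mesh size.
RVE-level β (mm³ Pa⁻¹ s⁻¹) is divided by the clipped RVE volume on entry to
the weak form — the coupling term must carry units of ∇·w — and the global
factor this introduces is absorbed by the K rescaling.

The test protocol solves compartment 2 only, with zero-flux outer
boundaries; compartments 1 and 3 enter through the coupling terms as
Dirichlet-imposed averaged-pressure fields. The resulting system is
symmetric positive definite whenever β > 0 somewhere, solved by sparse
Cholesky at a relative residual below 10⁻¹⁰. A manufactured cosine solution
confirms second-order L² convergence; a constant equilibrium is reproduced
to solver precision; the solution respects the bounds of the imposed fields
and is equivariant under constant pressure shifts. For single-compartment
lattice studies the mesh faces normal to the fibre axis carry Dirichlet
pressures (2 and 1 kPa) and the four remaining faces zero flux, mirroring
the discrete boundary conditions; in that pure-Dirichlet, uncoupled setting
the pressure is invariant to a global K scale, so no rescaling is needed.

## Comparison metrics and the scale search

`rms_error()` min-max-normalises the reference field (the averaged discrete
pressure) to [0, 1], applies the *same* affine map to the comparison field,
and returns the rms difference — removing the dependence on absolute
boundary pressures. `smoothness_psi()` sums the absolute responses of the
5-point discrete-Laplacian kernel over the three axis-aligned slice
families of the grid (the natural 3D extension of the 2D kernel; it
reproduces the 2D definition on any single slice and vanishes for constant
and axis-linear fields).

None of the permeability constructions lands on the optimal magnitude, so
each field is rescaled by the constant minimising the rms error
(`optimise_k_scale()`): a deterministic 21-point scan over ±4 decades
brackets the minimum, golden-section search polishes it to 10⁻³ relative,
and the assembled system is reused across evaluations (only the stiffness
block scales). If the profile were non-unimodal the scan minimum still
bounds the answer; the scan-vs-optimiser comparison is itself a test.

## Experiment drivers

* `run_rve_sweep()`: increasing RVE radius smooths the averaged fields —
  the Darcy-vs-averaged rms falls (towards a plateau) while the
  averaged-vs-nodal Poiseuille rms rises, which is the trade-off governing
  RVE choice; 0.2667 mm (~13 % of the domain length) is the reference
  radius. The sweep records both errors, the smoothness of both fields and
  the optimal scales.
* `run_density_sweep()`: thins compartment 2 by moving its vessels below a
  radius threshold into compartment 3, re-deriving everything; vessel
  counts grow monotonically as the threshold drops and compartments 1/3
  never couple directly (the tree generator cannot connect them).
* `run_bc_independence_sweep()`: β is flux *per unit pressure difference*,
  so it should survive boundary-condition changes. The driver freezes all
  derived parameters at an 8 kPa outlet parameterisation, then varies the
  outlet pressure of the terminals inside S = [0, 1]³ mm over 7–9 kPa,
  updating only the discrete flow and the imposed pressure fields. The rms
  does not increase towards 9 kPa; it decreases away from 8 kPa because
  the widened pressure spread enters the normalisation.
* `run_anisotropy_comparison()`: the single-compartment protocol on
  aligned and isotropic lattices. On aligned networks the direction-aware
  methods clearly beat the isotropic assumption (HvC < PCA < φI across
  seeds); on the isotropic control PCA and φI agree (mean rms within
  ~11 %), confirming that PCA's advantage comes from real directional
  structure, not from extra degrees of freedom.

## Problem sizes and determinism

The reference study uses 10-level trees (2047 vessels), the 16³ mesh and
five seeds — deep enough for three well-populated compartments and stable
trends while keeping a full five-seed sweep within minutes. Every source of
randomness (generators, Monte Carlo volumes, comparison-node sampling) is
seeded explicitly and drawn under a locally restored RNG state, so all
sweep tables are bitwise reproducible.

## Known limitations

* On the deterministic bisection tree the three permeability methods are
  nearly indistinguishable after optimal rescaling (within ~1 %): its
  volume-filling layout is inherently isotropic and its within-compartment
  vessel lengths nearly homogeneous, so even a spatially constant
  isotropic K reaches the same error floor, which is set by the roughness
  of the averaged discrete pressure rather than by K. Method ranking on
  this fixture is therefore noise-dominated; the lattice studies are the
  discriminating comparison.
* The proximal compartment cannot cover the domain at practical RVE radii;
  its fields rely on nearest-neighbour completion.
* Loops, non-Newtonian rheology, vessel compliance, tissue deformation and
  source fields `s` are out of scope; the data model is single straight
  segments between nodes.
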