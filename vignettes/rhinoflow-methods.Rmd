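---
title: "Models and numerical methods in rhinoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in rhinoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rhinoflow implements a complete, desk-scale version of a physics-based
diagnostic chain for rhinology: objective resistance measurement
(4-phase rhinomanometry), machine-learning segmentation of CT-like
volumes, surface and volume mesh generation, a thermal lattice-Boltzmann
flow solver, and flow post-processing into clinically interpretable
quantities. This vignette records the models, the parameters that
matter, the numerical choices made where the design was open, and what
the synthetic phantoms do and do not demonstrate.

```{r setup}
library(rhinoflow)
```

## Four-phase rhinomanometry

A 4-PR recording samples the differential pressure Δp between
nasopharynx and mask (Pa) together with the volume flux V̇ (cm³/s,
positive at inspiration) over a full respiration cycle of duration T.
The central diagnostic quantity is the effective resistance, defined as
the ratio of the effective (RMS) pressure to the effective flux,

R_eff = Δp_eff / V̇_eff.

The literature also circulates an integral form,
sqrt((1/T)∫(Δp/V̇)dt). The two only coincide when R_eff = 1: for a
proportional waveform Δp = c·V̇ the RMS ratio gives `c` while the
integral form gives `sqrt(c)`. Both are implemented;
`effective_resistance()` defaults to the RMS ratio (the defining
equality) and exposes the integral form as `printed_integral`, where
samples with |V̇| below 1% of the cycle maximum are excluded from the
integrand to avoid the division blow-up at flow reversal, and the mean
is taken over the retained time. Quadrature is trapezoidal in both
cases.

```{r fourphase}
wf <- make_4pr_waveform(r_true = 0.45, cycle_s = 4, peak_flux = 400,
                        noise = 0.05, seed = 1)
analyze_4pr(left = wf$cycle)
```

The obstruction classification operates on the logarithmic scale
`LR_eff^1 = log10(10 R_eff)`; two sides combine like parallel electric
resistors before the logarithm (`combined_log_resistance()`).
Logarithms are base 10 — the class bounds (0.755, 0.960, 1.135, 1.365
for one side) only make sense on that scale. The published class table
contains a gap (0.755–0.760), an overlap (0.910–0.960) and an
internally non-monotone two-sided column; `classify_resistance()`
therefore treats the upper bounds as an ordered threshold list (the
two-sided bounds are sorted ascending first) and assigns the *lowest*
class whose bound is not exceeded. This makes the classification total
and monotone, and values in the printed overlap resolve to the lower
class. The thresholds are data (`resistance_class_bounds()`), not code.

The vertex resistance is Δp/V̇ at the sample of maximum |V̇| within a
phase. `overlay_data()` assembles the flux-over-pressure table on which
steady simulation operating points (Strouhal number 0, i.e. zero
respiration frequency) are overlaid on the measured loops.

## CNN segmentation

Axial CT slices, intensity-scaled to [0, 1], are segmented by small
convolutional networks: 1–4 blocks of [3×3 convolution → ReLU → 2×2 max
pooling (stride 2, zero padding) → a specialized 3×3 convolution →
ReLU], each pooled branch resized back to the ROI by bilinear
interpolation (no corner alignment) and concatenated into a feature
volume; per-class 1×1 linear combinations form the prediction stack
(sigmoid head for the binary air/non-air model, softmax along the class
dimension for the 9-class anatomical model). All layers are
convolutional, so the parameter count is independent of the ROI size.
Weights are initialized from a truncated normal (mean 0, sd 0.1,
truncated at ±2 sd); training uses Adam at a fixed learning rate of
0.01 with batch size 1.

Two cost functions address the severe class imbalance of head CT:

* the class-balanced cross entropy for binary segmentation, with the
  per-image multiplier β = |Y⁻|/|Y| weighting the two label sets
  complementarily, and
* the balanced focal loss for 9 classes,
  `-Σ_s Σ_{j∈Y_s} β_s (1-P)^γ log P`, with per-image class weights
  β_s = exp(-|X_s|/|X|) and the modulating factor (1-P)^γ that
  suppresses the contribution of confidently correct pixels (a pixel at
  P = 0.99 with γ = 2 contributes 10⁻⁴ of its γ = 0 contribution).

Natural logarithms are used throughout (the references are silent;
this is the standard convention), probabilities are clamped at
1e-7 before logs, and argmax ties at prediction time break to the
lowest class id. Convergence is declared when the *residual* — the
absolute change of the window-5 smoothed training cost — stays below
1e-5 for 30 consecutive iterations; with stochastic single-slice
updates this fires mainly for degenerate settings (tiny datasets, zero
learning rate), so `train_cnn()` also takes an iteration cap.

A third balancing device oversamples slices: `balance_training_set()`
repeatedly finds the least-dominant sinus segment, picks a slice
containing it and appends a horizontally flipped copy (exchanging the
left/right sinus labels under the bilateral-symmetry assumption) or a
randomly translated copy (shifts up to 10% of the ROI, zero-filled
images, shifted-in label pixels taking a configurable background
class). A strictly greedy stop — halt as soon as one append fails to
reduce the mean absolute pairwise difference of the sinus pixel counts
— stalls in an obvious local optimum (appending to one pair of sinuses
temporarily widens the gap to the others), so the implementation keeps
appending toward the minimum-count class with a patience window
(default 25 appends without a new best) and returns the prefix with the
smallest imbalance, capped at 10× the original dataset size. On the
labeled-head phantom this takes the five sinus classes from pixel
counts of roughly (150, 150, 364, 121, 121) to within a few pixels of
each other.

## Label-volume post-processing

Predicted label volumes pass through three steps mirroring clinical
practice: `split_maxillary()` separates the combined maxillary class
into left/right by component centroid relative to the mid-sagittal
plane (the volume x-midplane unless supplied);
`dissolve_small_components()` reassigns every voxel of a connected
component smaller than 10 voxels (strict) to the mode label of its 3³
neighborhood, own label excluded, ties to the smallest id, all targets
computed from a snapshot; `enforce_plausibility()` — only for
geometries deemed healthy, where each cavity is a single component —
keeps the largest component per sinus class and recolors strays that
fall inside another cavity's bounding region (axis-aligned box of its
main component, inflated by one voxel) to that cavity's class.
Connectivity is 26 in 3-D and 8 in 2-D throughout.

Segmentation quality is summarized by voxel accuracy, the mean Jaccard
index (per slice and class, classes absent from both volumes counting
100%, averaged over classes then slices), the segment match (per-slice
agreement of class presence), and the connected-component match. The
last is defined verbally in the literature; rhinoflow maps the
per-slice, per-class absolute component-count difference dC to
100/(1+dC) — any monotone map with dC = 0 ↦ 100% would do, and the
choice is documented here precisely because it is a convention.

`extract_surface()` produces simulation-ready watertight surfaces from
label masks at iso-level 0.5. The extraction is the tetrahedral variant
of marching cubes: each sample cube is split into the six Kuhn
tetrahedra sharing the main diagonal, which is face-consistent across
neighboring cubes and therefore yields closed, manifold, consistently
outward-oriented triangle meshes with no ambiguous configurations — at
the price of more (and less isotropic) triangles than the classic
256-case cube table. Optional Laplacian smoothing (λ = 0.5) relaxes the
staircase at a small volume shrink; the sphere-mask volume test keeps
smoothing off.

## Octree mesh generation

`generate_mesh()` builds the hierarchical Cartesian mesh the flow
solver runs on. The root cube is the geometry's bounding box inflated
by 5% and cubified; every level subdivides cells into 8 children, and
children located outside the geometry are deleted. A child of a cut
(surface-intersecting) parent is classified by exact triangle/box
overlap tests against the parent's local triangle list; a non-cut child
is kept iff its center passes a parity (ray-casting) inside test.
Children of interior cells are interior without any test, which keeps
the generation near-linear in the surface size. After the uniform level
`l_uniform`, only cells cut by the boundary and/or inside refinement
patches are subdivided further to `l_final`, and a 2:1 level balance is
maintained. Cut leaves store, for each of the 26 lattice directions,
the fraction q ∈ (0, 1] of the link length to the first surface hit —
the input of the interpolated bounce-back — plus the boundary patch of
the nearest triangle.

For the solver, `mesh_to_grid()` flattens a uniformly refined mesh to a
dense grid and re-derives the boundary data link-wise from the inside:
cut cells whose *center* lies outside the geometry are excluded from
the lattice (keeping them produces wall-enclosed cell chains with
invalid links that destabilize the collision step), and each remaining
cell with missing neighbors gets fresh ray-cast wall distances and an
open-boundary label when its closest axis-direction hit lies on a cap
patch (`pharynx`, `nostril_left`, `nostril_right`).

## Thermal lattice-Boltzmann solver

The flow solver is a D3Q27 BGK lattice-Boltzmann method with a second
set of total-energy distribution functions (TEDF) for the temperature
field. Particle distributions relax toward the second-order Maxwell
equilibrium with collision frequency ω = 1/(3ν_lat + ½); the TEDF
relax toward the total-energy equilibrium (total energy
E = (D/2)RT + v²/2, D = 3) with ω_t set from the thermal diffusivity
α = ν/Pr at Pr = 0.72 for air, plus the (ω_t − ω_f) coupling term in
the non-equilibrium momentum flux. The standard D3Q27 weights (8/27,
2/27, 1/54, 1/216) and c_s² = 1/3 are used; pressure follows the ideal
gas law p = ρc_s². The lattice gas constant is fixed by R_lat·T_avg =
c_s² at the average temperature 303.15 K, so temperatures stay in
kelvin. The unit bridge is diffusive: the time step follows from
matching the lattice viscosity to ν = 1.63·10⁻⁵ m²/s of air (the
dimensionally consistent reading of the printed value).

Boundary conditions:

* **Walls** — Bouzidi linear interpolated bounce-back for the particle
  distributions, with the two branches q < ½ (using the upstream fluid
  neighbor) and q ≥ ½, falling back to halfway bounce-back when the
  upstream neighbor is unavailable. The isothermal wall at body
  temperature T_B = 309.15 K is realized for the TEDF by an
  anti-bounce-back against the wall-temperature total-energy
  equilibrium, the package's realization of a Dirichlet thermal wall;
  it is exact for plane walls at q = ½ (the conduction benchmark is
  linear to machine precision) and first-order accurate for general
  offsets.
* **Pharynx** — either a fixed pressure offset, or a prescribed volume
  flux: the target Reynolds number Re_P = (V̇_P/A_P)·d_P/ν is computed
  from the prescribed flux, the boundary area A_P = H_P·δx² and the
  hydraulic diameter d_P = sqrt(4A_P/π); each step the current Re is
  measured from velocities extrapolated from the interior and the
  boundary pressure is adapted by gain·(Re_target − Re_current)
  (integral action; the adaptation law is not specified in the
  literature beyond "adapted at each time step"). The default gain of
  1e-6 lattice-pressure units per unit Re error is configurable; the
  phantom studies below use 2e-7–5e-7.
* **Nostrils** — the modified Saint-Venant/Wantzel relation
  ρ = (1 − (γ−1)/(2γ)·(3/ρ²)·(ρv)²)^(γ/(γ−1)) with γ = 1.4, evaluated
  in lattice units with ambient density 1 (the factor 3 is 1/c_s²),
  momentum extrapolated from the interior, temperature fixed at the
  ambient T_N = 293.15 K.

Open boundary cells rebuild all 27 populations by non-equilibrium
extrapolation from their interior neighbor (equilibrium at the
boundary density and extrapolated velocity plus the neighbor's
non-equilibrium part). This is robust but first-order at the boundary
cell itself: in the duct benchmark the cross-sectional mass flux is
constant to better than 10⁻³ in the developed interior while the first
one or two layers at an opening carry an entrance artifact of a few
percent; boundary-cell averages are therefore most trustworthy one
diffusion length away from strong gradients, and conservation checks
should use interior cross sections.

Validation included in the test suite: exact conservation and
equilibrium invariance in periodic boxes; shear-wave decay at the
analytic viscous rate within 1% at 32-cell wavelength; plane Poiseuille
flow driven by a pressure difference with L2 profile error 0.2% at 32
cells width and an observed convergence order of 2.0 between 16 and 32
cells under diffusive scaling (velocity halved with the grid, keeping
the compressibility error O(δx²) too); steady conduction between
plates at T_B and T_N linear within 1%; controller convergence to the
target Reynolds number within 1% in a straight duct. Simulations are
bitwise deterministic.

## Flow post-processing

`boundary_summary()` reduces a run to the clinically reported numbers:
per nasal side, the dynamic pressure (1/H)Σ½ρv² and static pressure
(1/H)Σρc_s² averaged over the boundary cells of the pharynx minus the
same average over the nostril, their sum (the total pressure loss —
additive by construction), the mean pharynx temperature relative to
T_B, and mass fluxes Σ(ρ₀v_n) per open surface (positive into the
domain, ρ₀ the constant reference density as printed, which makes the
in/out balance exact only to O(Ma²)). Averages are unweighted cell
means — no area weighting of cut cells — matching the 1/H prefactors
of the definitions.

Centerline diagnostics place equidistant stations along a supplied
centerline (phantoms carry analytic axes; clinical centerlines come
from external tools and are read as CSV polylines). At each station
`cross_section_cells()` grows a region from the cell containing the
station point through 26-neighbors whose centers satisfy the slab test
|(x − C_cl)·n_cl| < (√3/2)δx — the two half-space inequalities of the
cuboid of thickness √3δx. Growing instead of slicing is what separates
the two nasal sides and keeps sinus cells that merely intersect the
plane out of the average. `section_average()` is the arithmetic mean
over member cells; profiles report arclength as percent of the
centerline length. The temporal `moving_average()` uses a centered
window of Δt+1 samples (Δt even), truncated and renormalized at the
series edges rather than dropped — so the smoothed series keeps its
length, at the price of higher variance in the first and last Δt/2
samples.

`naive_centerline()` supplies phantom axes exactly and, for voxel
masks, a distance-transform ridge path: a minimum-cost 26-neighbor path
between two endpoints where steps are penalized by the inverse squared
wall distance.

## Synthetic phantoms and what they show

All generators are deterministic given their seed.

* `make_duct()` — a box duct with labeled caps and the laminar
  rectangular-duct series solution attached (profile and
  flux–gradient relation), the reference for solver and
  post-processing checks.
* `make_two_passage_airway()` — two passages merging into a common
  outlet, extracted from an implicit function (hence watertight), with
  analytic per-side centerlines, cap patches, optional sinus pockets
  with narrow ostia, and an asymmetry factor scaling the left
  passage's cross-section area. It reproduces the topology and the
  diagnostic question (which side is obstructed?) of a nasal cavity,
  not its anatomy.
* `make_labeled_head()` — a CT-like intensity volume with 9-class
  ground truth: an ellipsoidal head of tissue in a bone shell, a
  central nasal/oral column and six sinus pockets laid out so that
  different axial ranges contain different sinus combinations (frontal
  superior, maxillary mid, sphenoid inferior) — the property that
  makes per-slice oversampling able to balance classes. Intensities
  are nominal Hounsfield values (air −1000, tissue +40, bone +700,
  configurable noise) rescaled to [0, 1]; the sinus classes together
  stay below 5% of the pixels.
* `make_4pr_waveform()` — sinusoidal respiration cycles with known
  resistance under either resistance convention, plus seeded noise.

Study conditions of the phantom experiments: the end-to-end
obstruction study meshes the airway at uniform level 6 (δx ≈ 0.6 mm,
roughly 8–11·10³ lattice cells), fixes the flux at 4 ml/s (lattice
viscosity 0.02, Re ≈ 35–40 at the pharynx — a scaled-down operating
point chosen so the flow is cleanly laminar and diffusively converged
within 4,500 steps) and compares the per-side total pressure loss
across asymmetry factors 1.0, 0.75, 0.5; the loss on the narrowed side
increases strictly (0.041, 0.048, 0.055 Pa in the packaged run). The
CNN study trains the binary model (2 layers, 8 filters) on 12 slices
of a 64² head phantom at noise 30 HU and validates on 4 held-out
slices, exceeding 95% pixel accuracy within 600 iterations. These
sizes are the package's chosen desk-scale study conditions; clinical
resolutions (512² slices, ~10⁸-cell meshes, 300,000-iteration runs
averaged over another 300,000) are reachable with the same code paths
but not part of the test suite.

Passing these tests demonstrates internal correctness — the losses,
the balancer, the solver physics, the boundary conditions and the
post-processing behave as specified on geometry where ground truth is
known. It does not demonstrate clinical accuracy: real CT noise,
anatomy, mucosa state and turbulence transition at higher fluxes are
outside what the phantoms emulate.

## Known limitations

* The solver runs on the finest uniform octree level; multi-level
  streaming across refinement interfaces is not implemented (production
  meshes in this regime are uniformly refined anyway).
* Open-boundary extrapolation is first order; boundary-cell sums carry
  entrance artifacts of a few percent (see above).
* The thermal wall scheme is first-order for wall offsets q ≠ ½.
* The integral ("printed") resistance form is dimensionally
  inconsistent with the RMS definition; it is provided for
  completeness, with the RMS ratio as the operational default.
* `enforce_plausibility()` encodes the "healthy geometry" assumption
  with bounding-region tests; pathological anatomies must skip it.
* Unsteady, 4-PR-driven respiration cycles are not simulated; steady
  operating points are placed on the measured loops instead.
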