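---
title: "Models and methods behind ecogfwd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ecogfwd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ecogfwd` implements a patient-specific pipeline for solving the
electrocorticography (ECoG) forward problem in a brain deformed by the
implantation of a subdural electrode grid. The pipeline has three
computational cores:

1. a **meshless total Lagrangian explicit dynamics (MTLED)** solver that
   predicts the brain shift from the displacements of the implanted
   electrodes,
2. **image warping** machinery that carries scalar MRI and diffusion tensor
   images (DTI) into the deformed configuration, including
   preservation-of-principal-direction (PPD) tensor reorientation, and
3. a **voxel-hexahedral finite element** solver for the electrostatic forward
   problem with a **full-subtraction** dipole source, fed by DTI-based tissue
   classification and conductivity tensor construction.

Because the patient data the workflow was designed around cannot be shipped,
the package contains a first-class synthetic-phantom module: concentric-sphere
head label maps, synthetic tensor images, and synthetic electrode grids with a
known implantation shift, together with analytic multilayer-sphere dipole
solutions that act as independent oracles for the forward solver.

# The biomechanical model

## Kinematics and shape functions

The brain is represented as a cloud of nodes with a tetrahedral background
grid used only for integration (4-point, degree-2 Gauss rule per tetrahedron:
barycentric permutations of $(0.5854102, 0.1381966, 0.1381966, 0.1381966)$,
each weighted $V/4$). Displacements are approximated with moving least squares
(MLS) shape functions with a linear basis $p = (1, x, y, z)$ and a quartic
spline weight $w(q) = 1 - 6q^2 + 8q^3 - 3q^4$ on the normalized distance
$q = \lVert x - x_a\rVert / r_a$. The support radius defaults to
$r_a = 1.8\,\bar h_a$, with $\bar h_a$ the mean length of background-grid
edges incident on node $a$; this is a common meshfree choice that keeps the
moment matrix well conditioned on mildly irregular clouds. Shape-function
gradients are computed analytically via the shifted-and-scaled basis.

MLS shape functions form a partition of unity and reproduce affine fields
exactly, but they do not interpolate. At nodes carrying essential boundary
conditions the weight is switched to the near-singular form
$w(q)/(q^2 + \varepsilon^2)$ with $\varepsilon = 10^{-4}$, which makes the
approximation interpolate there to within $O(\varepsilon^2)$, so prescribed
displacements are imposed directly on the nodal parameters.

## Integration consistency

Gauss integration of rational MLS shape functions is inexact, and the test
functions of interior nodes do not vanish on the essential boundary. Left
uncorrected, both effects make the classic affine patch test fail at the
$10^{-3}$ level. The package therefore applies a first-order variational
consistency correction to the *test-function* gradients: for every free node
the quadrature-integrated gradient $\sum_{ip} w\,\nabla\phi_a$ is constrained
to zero (the value it would have if the test function vanished on the
boundary), and for every prescribed node to its boundary integral
$\oint \phi_a n\, d\Gamma$ (evaluated with a 3-point rule on the boundary
triangles of the background grid), with the correction distributed over the
integration points proportionally to $\phi_a$. Trial gradients are left
untouched, so affine fields still produce exactly affine strain. This
restores the affine patch test to solver precision and makes reactions at
prescribed nodes consistent surface-traction integrals. On irregular grids
the correction is capped at three times the median gradient magnitude per
node to preserve the stability of explicit stepping; the regular benchmark
grids are unaffected by the cap. The uncorrected Bubnov-Galerkin operator
remains available (`internal_forces(..., corrected = FALSE)`) and is the
exact gradient of the stored energy, which is what the energy-consistency
tests verify.

## Constitutive model and solver

The tissue is compressible neo-Hookean with decoupled volumetric response,
$$S = \mu J^{-2/3}\!\left(I - \tfrac{\operatorname{tr}C}{3}C^{-1}\right)
  + K J (J-1) C^{-1},$$
with $\mu = E/2(1+\nu)$ and $K = E/3(1-2\nu)$. Defaults are $E = 3000$ Pa and
$\nu = 0.49$, standard soft-tissue values for nearly incompressible brain
parenchyma; both are configurable per integration point, and
`assign_materials()` can blend per-class moduli using fuzzy C-means
memberships of the image intensity.

The static solution is obtained by explicit central differences with adaptive
dynamic relaxation. Nodal masses are scaled so the unit pseudo-time step is
stable (a Gerschgorin-style diagonal stiffness estimate times a safety factor
of 2); mass-proportional damping is adapted each step from a Rayleigh-quotient
estimate of the lowest mode built from successive force and displacement
increments, capped at 90% of critical. Prescribed displacements follow a
smooth 3-4-5 polynomial ramp (default 500 steps); convergence is declared
when the largest nodal displacement increment stays below $10^{-5}$ mm for
100 consecutive steps. Divergence (a non-positive deformation Jacobian)
aborts with advice to increase damping or mass scaling.

# Image warping

The solved displacement field is evaluated at voxel centres with the same MLS
machinery (forward transform), inverted by damped fixed-point iteration
$v_{k+1}(x) = -u(x + v_k(x))$ (defaults: tolerance 0.05 mm, 50 iterations),
and applied by trilinear pull-back. Samples during inversion are clamped to
the image domain so border voxels whose preimage leaves the grid by a
fraction of a voxel do not oscillate against the background. Physically the
brain slides under a static skull, so the *composite* head displacement field
is discontinuous at the brain surface; in the pipeline the field is evaluated
on a slightly dilated brain mask and tapered smoothly to zero outside, and
the inversion accepts a configurable small fraction of interface voxels above
tolerance (reported in a warning) rather than failing outright.

Tensor images are resampled component-wise (linear interpolation, matching
common practice) and reoriented by PPD: the local forward Jacobian — obtained
from the backward field by central differences and $3\times3$ inversion —
rotates the principal eigenvector to $Fe_1/\lVert Fe_1\rVert$ and the second
eigenvector to the Gram-Schmidt projection of $Fe_2$; eigenvalues are
preserved exactly by construction. Isotropic tensors and singular-Jacobian
voxels get the identity reorientation.

# Tissue classification and conductivity

Brain voxels are classified from diffusion invariants in two fuzzy C-means
stages with fuzziness $m = 2$: mean diffusivity separates CSF (the high-MD
cluster) from parenchyma, then fractional anisotropy separates WM (high FA)
from GM. Centres are initialized deterministically at feature quantiles with
one seeded random restart if they collapse; cluster-to-tissue mapping is by
centre ordering, and hard labels are taken by maximum membership. Skull and
scalp are built by offsetting the brain mask with a Euclidean metric dilation
(default shell 4.4 mm, i.e. 4 voxels at 1.1 mm spacing); the voxelized
electrode-sheet surface overrides underlying classes.

Conductivities (S/m) follow the standard EEG/ECoG literature values: scalp
0.33, skull 0.012, CSF 1.79, GM 0.33, electrode-sheet substrate $10^{-6}$.
White matter is anisotropic, sharing the eigenvectors of the local diffusion
tensor. Two eigenvalue mappings are implemented, because the "fractional"
scaling family appears in two forms in the modelling literature: the default
volume-normalized mode $\sigma_i = \sigma_{\mathrm{ref}}\, d_i/(d_1 d_2
d_3)^{1/3}$, which fixes $\det\sigma = \sigma_{\mathrm{ref}}^3$ per voxel
(default $\sigma_{\mathrm{ref}} = 0.14$ S/m, a common WM reference), and a
linear mode $\sigma_i = k\,d_i$. Eigenvalues are floored at $10^{-9}$ S/m to
guarantee positive definiteness.

# The electrostatic forward problem

The head label map is meshed with one trilinear hexahedron per voxel
(vertices at voxel corners, shared vertices merged), and the stiffness
operator $K_{ab} = \sum_e \int_e \nabla N_a \cdot \sigma_e \nabla N_b$ is
assembled directly into compressed sparse rows with a $2\times2\times2$ Gauss
rule (exact for these integrands). $K$ is symmetric with the constants as
null space (pure Neumann).

The dipole source uses the full-subtraction split $\phi = \phi_\infty +
\phi_c$, where
$$\phi_\infty(r) = \frac{1}{4\pi\sqrt{\det\Sigma_0}}
  \frac{m\cdot\Sigma_0^{-1}(r - r_0)}
       {\left[(r-r_0)^\top\Sigma_0^{-1}(r-r_0)\right]^{3/2}}$$
is the singularity potential of the homogeneous medium $\Sigma_0$, and the
correction satisfies
$$b_a = -\int_\Omega \nabla N_a\cdot(\sigma - \Sigma_0)\nabla\phi_\infty
       \;-\; \oint_{\partial\Omega} N_a\,(\Sigma_0\nabla\phi_\infty\cdot n).$$
$\Sigma_0$ defaults to the tensor of the element containing the dipole, and
the conductivity must be homogeneous within a configurable radius (default 3
voxels) around the dipole, otherwise the split is invalid and the solver
refuses with advice to reposition. The boundary term is integrated on the
exterior voxel faces of the masked region; the electrode sheet is handled as
a volume conductivity, not a boundary condition.

The singular system is solved by Jacobi-preconditioned conjugate gradients
with the constant null space projected from the right-hand side and the
preconditioned residuals; the gauge of the reported potential is mean-zero
over the mesh nodes. Any SPD preconditioner satisfies the solver contract;
Jacobi is the default because the voxel Laplacian at head-model sizes
(~270k elements at 2 mm) converges in a few hundred iterations, and algebraic
multigrid was deliberately left out of scope.

## Validation oracles

`analytic_dipole_sphere()` evaluates the classical Legendre-series solution
for a dipole in a concentric multilayer sphere with insulating exterior. Per
degree $n$ the interface conditions are solved as a small dense system with
per-layer radius scaling (basis $(r/R_l^{out})^n$, $(R_l^{in}/r)^{n+1}$),
which stays well conditioned to high degree; the singular part is evaluated
in closed form inside the source layer, so the expansion is valid at radii
below the dipole eccentricity too. Truncation defaults to 80 terms with an
early stop when the last term falls below $10^{-12}$ of the running maximum;
for a dipole at half the outer radius the series is converged to machine
precision well before 60 terms.

Forward-solver accuracy is reported as RDM (relative difference measure,
$\lVert u/\lVert u\rVert - v/\lVert v\rVert\rVert_2$) and MAG
($\lVert u\rVert / \lVert v\rVert$) against the series, both computed after
removing the mean over the sample points (both solutions are only defined up
to a constant). Samples are taken on a sphere two voxels below the outer
surface, away from the staircase boundary of the voxelized geometry.

# The synthetic phantom study

The phantom emulates the structure of the patient dataset: a five-layer
concentric-sphere head (defaults, outer to inner: scalp 80, skull 75.6, CSF
71.2, GM 67, WM 55 mm at 2 mm voxels — head-scale radii with shells a few
voxels thick), a synthetic DTI with literature-style eigenvalue triples (WM
$(1.7, 0.3, 0.2)\times10^{-3}$ mm²/s with tangential fibres, GM
$(0.85, 0.75, 0.7)\times10^{-3}$, CSF $\approx 3\times10^{-3}$) and seeded
Gaussian component noise of $4\times10^{-5}$ mm²/s, and an 8×8 electrode grid
at 10 mm pitch whose post-implantation positions are displaced 3 mm inward
along the local surface normal. Electrode lattice offsets are pre-warped
gnomonically (using the surface's estimated curvature radius) so the
projected grid keeps its pitch — without this, closest-point projection
compresses the outer electrodes together, which is also why a flexible real
grid drapes rather than projects. The synthetic CT renders 2 mm-FWHM Gaussian
blobs at the electrode positions.

What the phantom does *not* emulate: cortical folding (the surface is
convex), realistic MRI intensity distributions (only two-class Gaussian
mixtures are used for threshold tests), partial-volume effects at tissue
interfaces, spatially correlated DTI noise, and CSF-mediated sliding contact
of the brain. Passing the phantom suite therefore demonstrates the
correctness of the numerics (geometry processing, solvers, transforms,
classification logic) — not clinical accuracy on real heads.

Isosurfaces are extracted by marching tetrahedra on the Kuhn 6-tet
decomposition of each cell (a standard variant of marching cubes that is
watertight by construction); binary masks are box-smoothed (3 passes of a
6-neighbour kernel) first, as segmentation-to-model pipelines usually smooth,
which keeps the sphere-surface area within 3% and enclosed volume within 2%
of the analytic values at 1 mm resolution.

# Numerical choices and degenerate inputs

* Voxel labelling is by voxel-centre membership (no partial volumes), which
  matches the one-element-per-voxel forward mesh exactly.
* Component labelling is deterministic (raster order of the first voxel), as
  are FCM initialization and all generators given a seed.
* The dipole of the sphere studies is placed at an element centre (odd grid
  dimensions); a dipole exactly on a mesh node makes $\phi_\infty$ singular
  there and is rejected.
* Tangential/radial fibre fields fall back to the x axis at the sphere
  centre; PPD falls back to identity reorientation for isotropic tensors and
  singular Jacobians; conductivity mapping falls back to the isotropic WM
  value for degenerate diffusion tensors (warning).
* MLS evaluation fails loudly (naming the point) when a support holds fewer
  than four nodes or the moment matrix is singular.
* The electrode-displacement interpolation thickens the quasi-planar
  electrode cloud along its fitted normal (duplicating values), because a 3D
  linear-basis MLS moment matrix is near-singular on a plane; this enforces a
  zero out-of-plane gradient and removes extrapolation overshoot.

# Problem sizes used in the shipped studies

The validation studies run at the sizes a single desktop core handles
comfortably: the homogeneous-sphere benchmark uses a radius of 80 mm at 2 mm
voxels (~268k hexahedra; convergence is checked against 2.5 mm and 1.5 mm
meshes), the four-layer benchmark the same grid with scalp/skull/CSF/brain
conductivities 0.33/0.012/1.79/0.33 S/m, the MTLED benchmarks a 5³-node cube
cloud (40 mm side), and the classification phantom a three-shell sphere at
2 mm voxels over five seeds. The end-to-end pipeline demo in the test suite
uses a reduced 40 mm head so the whole chain (phantom through metrics) stays
fast; `pipeline_config()` defaults reproduce the full-size study.

# Known limitations

* The meshless solver has no contact mechanics or gravity; brain-skull
  interaction is represented only through the prescribed electrode
  displacements.
* Displacement-field inversion is pointwise fixed-point iteration; it has no
  diffeomorphic guarantee and degrades at sliding interfaces (reported, not
  silently ignored).
* The forward mesh is voxel-aligned; geometric staircase error is the
  dominant error term at coarse resolutions, which is exactly what the
  convergence check quantifies.
* The full-subtraction source requires local homogeneity around the dipole;
  sources near tissue interfaces need repositioning or an explicit
  $\Sigma_0$.
* Real Slicer `.seg.nrrd` segment metadata, DICOM, and HDF5 transform files
  are out of scope; the supported formats are plain NRRD, STL, fcsv,
  Abaqus-style `.inp`, and legacy VTK output.
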