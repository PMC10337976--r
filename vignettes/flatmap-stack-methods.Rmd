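---
title: "Methods: cortical flatmap stacks and the mesoscale tracer pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortical flatmap stacks and the mesoscale tracer pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`cortexstack` re-implements the bespoke computational stages of a serial
two-photon tomography (STPT) post-processing pipeline for mesoscale tracer
mapping: microscope tile shading correction and stitching, injection-site
localization, tracer density and normalized-intensity maps, cell density
rasterization with laminar labels, a 3D *flatmap stack* coordinate system
for the cortex, symmetric spherical gradient design and interpolation for
HARDI population averaging, streamline selection with track-density
imaging, and the validation statistics used to assess all of the above.
Everything is exercised on synthetic phantoms with analytic ground truth;
no real marmoset data, trained networks, or external registration tools are
required or included. Learned tracer/cell segmentation is replaced by a
pluggable probability-map interface with classical intensity-threshold
stand-ins, and nonrigid registration is treated as an external backend:
only its averaging rule and validation metrics are in scope here.

# The flatmap stack

A cortical flatmap maps the mid-surface of one hemisphere to the unit
square through a triangulated mesh with per-vertex 2D coordinates
`flat_uv`. The flatmap *stack* extends this to a 3D image: voxel `(u, v, d)`
of a `U x V x D` stack (default `500 x 500 x 50`) refers to the point at
flatmap position `(u, v)` and relative cortical depth `d`, with `d = 0` on
the white-matter (inner) boundary and `d = 1` on the pial (outer) boundary.
The default depth axis therefore divides the cortex into 50 equidistant
layers.

Construction proceeds in three stages.

## 1. Direction field (`compute_direction_field`)

Directional information seeded at the two cortex boundaries — normals
pointing *into* the cortex on the inner boundary and *away* from it on the
outer boundary — is diffused through the cortical thickness by heat
propagation and normalized. Two discretizations are implemented:

* **`method = "potential"` (default).** Heat propagation of a scalar
  potential held at 0 on the inner and 1 on the outer boundary; at
  equilibrium this is the discrete Laplace problem, solved by red-black SOR
  (relaxation factor `2 / (1 + sin(pi / max(dim)))`, convergence when the
  largest per-sweep update falls below `tol = 1e-6`). The field is the
  normalized gradient of the potential (central differences inside the
  domain, one-sided at its edges, per-axis spacing-corrected). At the
  boundaries the equilibrium gradient *is* the surface normal direction, so
  the seeding semantics are preserved. Lateral cuts of the cortex mask
  (e.g. the border of a flatmap patch) receive the natural zero-flux
  condition, which makes the field run parallel to the cut — the behavior a
  through-cortex trajectory should have there.
* **`method = "vector"`.** The literal componentwise reading: boundary
  voxels are seeded with explicit unit normals (estimated by local PCA
  plane fits on the one-voxel boundary sheets, oriented by the smoothed
  mask gradient) and diffused by Jacobi neighborhood averaging with the
  seeds held fixed, renormalizing after every sweep, until the maximum
  angular change drops below `tol = 0.02` degrees.

Both fields are finished with a masked-normalized Gaussian smoothing
(`smooth_sigma = 1.5` voxels) and renormalization, which suppresses
voxelization noise without moving the field away from the analytic solution
on smooth geometry. The potential method is the default because the free
border condition is exact for it: on the spherical-shell phantom the
componentwise vector diffusion develops a systematic tangential bias in a
halo around the patch border (its converged solution satisfies a zero
normal-derivative condition on the *vectors*, which is not satisfied by the
radial truth), while the scalar equilibrium keeps the field radial up to
discretization noise. On a flat slab both methods are exact by symmetry.

## 2. Trajectories (`trace_trajectory`, `build_flatstack`)

Trajectories start at inner-boundary voxels and follow the trilinearly
interpolated field with fixed Euler steps (default half a voxel, 25 um at
50 um spacing) until they enter the outer boundary mask. Longer steps are
refused; trajectories exceeding `5 x` the estimated cortical thickness or
leaving the cortex sideways are *failed*: they are excluded and counted,
never silently filled, and the build aborts if more than `max_fail = 20%`
fail. `build_flatstack` supersamples `seed_supersample = 2` seeds per axis
within each inner-boundary voxel (8 per voxel); one seed per voxel leaves
the bundle too sparse for the in-plane accuracy the 500-voxel grid asks
for, and the voxel-center seeding is a subset of the supersampled one.

Each successful trajectory inherits the flatmap coordinate of its
mid-surface crossing: the candidate sample nearest the mesh is located via
a coarse spatial hash plus chunked nearest-vertex search; if the crossing
lies within one voxel of a mesh vertex it takes that vertex's `flat_uv`
(refined barycentrically when an incident triangle contains the point), and
otherwise barycentric interpolation on the best incident triangle is used,
falling back to the vertex coordinate when the crossing is outside every
incident triangle by more than a 0.25 barycentric slack. Depth along a
trajectory is *relative arc length*, not sample index.

## 3. The two coordinate maps

`from_world` (cortex voxel to `(u, v, d)`) rasterizes every trajectory
sample into its cortex voxel and averages where several land. Holes (cortex
voxels no trajectory visited) are filled by iterated neighborhood averaging
restricted to the cortex, and the in-plane channels are then de-noised with
a small masked Gaussian (`uv_smooth = 1` voxel): `u` and `v` are constant
along trajectories and smooth across them, so this removes per-trajectory
jitter; the depth channel, which has a strong radial gradient, is left
untouched to avoid boundary bias.

`to_world` (stack voxel to world) resamples each trajectory at the `D`
depth levels and scatters the world positions into each `U x V` layer at
the trajectory's `(u, v)` bin, with a truncated-Gaussian kernel
(`sigma_px = max(1.2, 0.8 * sqrt(U V / n_traj))`, Nadaraya-Watson
normalized). Stack voxels outside the kernel support of every trajectory
are undefined (`NA`) and excluded from any later mapping — the stack is
only defined where the cortex actually maps.

`map_to_stack` is pull-back resampling through `to_world`;
`map_points_from_stack` and `stack_coords_of_world` are the point-wise
inverses. Round trips agree within about one stack voxel on the shell
phantom.

## Isotropy validation

`isotropy_validate` places seeds equidistantly in chosen stack layers
(default layers 5, 25 and 45 of 50), maps them to world space, samples an
isotropic sphere surface around each (a Fibonacci lattice rotated by a
seeded random rotation; deterministic coverage with no pole clustering),
maps the samples back to stack coordinates and computes the eigenvalues
`l1 >= l2 >= l3` of their covariance. The isotropy score is
`sqrt(l3 / l1)`, which is 1 for an isometry and exactly 0.5 under a 2x
uniaxial stretch; only the score's 0-1 range is fixed by convention, so the
formula is documented here and configurable in the report. Spheres leaving
the mapped cortex are skipped and counted.

# Phantoms and what they do (not) show

`make_shell_cortex` builds a spherical-shell sector (defaults:
`r_inner = 1` mm, `r_outer = 2` mm, 50 um voxels, a 120 x 120 degree patch
facing `+x`, poles excluded) whose depth
(`(r - r_inner)/(r_outer - r_inner)`) and flatmap (equirectangular
longitude/latitude rescaled to the unit square) have closed forms — the
oracle for every flatmap-stack accuracy statement. `make_slab_cortex` is
the degenerate flat case where symmetry forces exact answers.
`make_stpt_phantom` emulates the three acquisition channels:
autofluorescent background (plus 10% tracer bleed-through), tracer with
bright fiber polylines and a *saturated* injection blob, and an
injection-detail channel that is near zero outside the injection with
Gaussian cell-body spots planted at known voxel centers. Noise is
multiplicative Gaussian clipped at zero (2% by default), approximating the
signal-dependence of fluorescence shot noise without committing to a
Poisson model. `make_tileset`, `make_hardi_phantom` (single-tensor signal
`S0 exp(-b n' D n)`) and `make_tractogram_phantom` (with exact per-
streamline voxel oracles) cover the remaining stages. All generators are
pure functions of their parameters and seed.

What passing on these phantoms does *not* show: real cortex is gyrified
and of variable thickness, so direction fields and isotropy will degrade
near high curvature (the isotropy report exists precisely to quantify
that); real tracer signal has structured background, vessels and
section-to-section variation that the intensity-threshold segmentation
stand-in does not face; tile offsets are taken as exact, as the microscope
reports them. The phantom results bound discretization error, not
biological variability.

## Problem sizes

Module tests run a 600-1200 um shell at 60 um voxels with a 120 x 120
stack; the acceptance checks run the full 1-2 mm shell at 50 um with the
default 500 x 500 x 50 stack (about 9,400 seed voxels and 68,000 scored
cortex voxels), the 64-direction scheme, a 1,000-replicate permutation
calibration at 999 permutations each, and 200-streamline selection
oracles. These sizes were chosen so the full suite completes in minutes on
one core while keeping every estimate comfortably inside its tolerance.

# Symmetric direction design

A left-right symmetric HARDI template needs a gradient scheme closed under
both antipodal equivalence (`S(x, n) = S(x, -n)`) and the x-mirror
coupling (`S(-x, y, z, -nx, ny, nz) = S(x, y, z, nx, ny, nz)`), read here
as: the set of direction representatives must map to itself (up to
antipodes) under `(nx, ny, nz) -> (-nx, ny, nz)`. Exactly equal pairwise
distances are impossible for general n, so "charged particles that repel
until equilibrium" is implemented as minimization of the Coulomb energy
`sum 1/d` over the antipodally expanded point set by projected gradient
descent with backtracking (energy never increases). Closure is enforced
*by construction*, not by penalty: representatives come either in free
mirror pairs `{x, m(x)}` or as self-symmetric classes (on the mirror plane
`nx = 0`, parameterized by one angle, or the `x` axis itself). For `n <= 6`
every split between paired and self-symmetric classes is optimized and the
lowest-energy one kept — necessary because the n = 3 optimum (the
octahedron, minimum pairwise angle 90 degrees) consists entirely of
self-symmetric classes. For larger n, `n/2` mirror pairs (plus one
on-plane class when n is odd) are used; with `n = 64` and seed 0 this
reaches a minimum pairwise angle of about 16 degrees with exact closure.
Per-split restarts (default 3) guard against poor random starts; the
energy trace and final gradient norm are returned in the provenance.

`spherical_interpolate` resamples a HARDI signal onto new directions per
b-shell with inverse-angular-distance weights over the `k = 8` nearest
sources under the antipodally symmetrized angle `min(ang, pi - ang)`. The
squared-distance exponent (`power = 2`) was fixed against the single-tensor
closed form (128 to 64 directions: about 1.8% relative RMSE, vs 2.6% for
`power = 1`); weights are normalized, so constant shells are reproduced
exactly and a coincident direction is copied verbatim. Whether to
interpolate raw signal or a spherical-harmonic fit is genuinely open; raw
kernel interpolation is implemented because it makes no band-limit
assumption and its error is directly measurable on the tensor phantom.

`symmetrize_population` implements the template averaging rule
`sum(w_i I_i) / sum(w_i)` with inverse-tracer weights to stop bright tracer
from biasing the template, exclusion of zero-weight (missing-tissue)
voxels with an unweighted-mean fallback (logged), and optional mirroring
that adds each input's x-reflection (with direction volumes permuted to
their mirrored counterparts for HARDI), making the result exactly
mirror-invariant and the operation a projection.

# Tracer stages: conventions and tie-breaks

* **Stitching.** Offsets are trusted verbatim. Tiles are cropped
  (default 50 px) and fused with a separable linear ramp rising over the
  residual overlap, normalized to a partition of unity; the weight is kept
  strictly positive half a pixel inside the cropped border so single-tile
  zones are exact and the fused image is a convex combination everywhere.
  The canvas border inside the crop margin is trimmed; any remaining
  interior gap is an error that reports its bounding box. With the
  acquisition defaults (720 px tiles, ~80 px overlap) a 50 px crop on both
  sides of an abutment exceeds the stated overlap, so crop and overlap are
  validated together rather than assumed compatible. Shading is estimated
  per channel as the normalized pixelwise mean (or median) over many
  tiles; the injection-detail channel is typically excluded (too few tiles
  with content), which the per-channel interface makes natural.
* **Injection site.** Gaussian smoothing (default 2 voxels at 50 um — the
  scale is a free choice; only "smoothing" is prescribed), half-maximum
  threshold, largest 26-connected component. 26-connectivity is the most
  permissive standard choice and is used for components and local maxima
  throughout. The output is invariant to uniform intensity rescaling.
* **Peaks.** Strict local maxima over the 26/8-neighborhood at probability
  `>= 0.5`; equal-probability plateaus resolve to their centroid voxel
  (deterministic); optional non-maximum suppression by descending
  probability.
* **Tracer maps.** Density counts positive pixel centers per 50 x 50 um
  in-plane bin, one slice per section (counts are conserved across binning
  resolutions); normalized intensity is `max(ch2 - ch1, 0)` divided by its
  maximum outside the injection site dilated by 2 voxels (the margin is
  unstated upstream; 2 voxels is the documented default), unclamped inside
  the injection. Multi-injection composites take the voxelwise maximum of
  normalized maps.
* **Laminar labels.** Depth `>= 0.5` is supragranular by default; 0.5 is an
  explicit surrogate for histological layer IV, which a synthetic pipeline
  cannot see, and is configurable.

# Statistics

NCC is the masked zero-mean, unit-variance Pearson correlation (global,
over an explicit mask defaulting to the union of nonzero support; a
windowed variant would change the question being asked and is not the
default). Permutation tests are two-sided with the add-one correction
`p = (1 + #{|r*| >= |r|}) / (1 + n_reps)`, so p is never zero and is
super-uniform under the null; at one million repetitions a maximal
statistic reports below 1e-6. Dice is `2|A n B| / (|A| + |B|)` with the
both-empty case defined as 1 (logged). Landmark reports compare
expert-vs-expert and automation-vs-expert median displacements per
landmark and subject; ties count as manual wins (the conservative
reading).

# Known limitations

* The flatmap patch border keeps a residual in-plane bias of a few stack
  voxels in a narrow halo (trajectory failures concentrate there too);
  real closed-surface cortices do not have this artificial border, but
  gyral crowns will show the analogous curvature effect that the isotropy
  report quantifies.
* Heat propagation is solved on the voxel lattice; no sub-voxel boundary
  representation is used, so all boundary placement is accurate only to
  half a voxel, which also bounds the depth accuracy at the boundaries.
* The intensity-threshold tracer segmentation is a stand-in for a learned
  probability map and inherits none of its robustness; it exists so the
  downstream density/intensity machinery is fully testable.
* Only axis-aligned NIfTI affines are accepted, and world units are
  micrometers everywhere.
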