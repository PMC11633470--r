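---
title: "Methods: 3D traction force microscopy in cylindrical microwells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D traction force microscopy in cylindrical microwells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

A single cell sits inside a cylindrical well (radius ~5-8 µm, depth ~11-12
µm) molded into the top of a soft polyacrylamide gel (~15 kPa, ~100 µm
thick) whose free surfaces carry 200 nm fluorescent beads. Confocal stacks
of the beads are acquired with the cell in place (deformed state) and after
the cell relaxes or is removed (reference state). The task is to turn that
image pair into the three-dimensional traction vector field the cell exerted
on the well wall and floor, and into summary quantities (unfolded traction
maps, circumference-averaged profiles, mean wall traction, net forces).

wellTFM implements the whole chain: surface localization, volumetric PIV,
optical axial correction, an inverse finite-element reconstruction, and the
cylindrical unfolding/statistics, plus a synthetic bead-stack generator so
every stage can be validated without a microscope.

## Model and procedure

### Gel mechanics

The gel is modeled as an isotropic, homogeneous, linearly elastic solid
(polyacrylamide is close to linear in this strain regime). The computational
domain is a square prism of gel with the filleted cylindrical cavity sunk in
its top face (bottom edge fillet 0.5 µm, top rim fillet 1 µm, matching the
molded wells). The base is bonded to glass (fully fixed); the lateral faces
and the gel top are traction-free; unknown tractions act only on the well
wall and floor.

Units are µm, Pa, pN throughout (1 Pa µm² = 1 pN), which keeps all matrices
well scaled.

Defaults: Young's modulus E = 15000 Pa (the gel formulation used for the
wells); Poisson ratio nu = 0.45. The gel is nearly incompressible, but
linear tetrahedra lock as nu approaches 0.5, so 0.45 is the practical
compromise; nu is configurable. A compressible Neo-Hookean law is available
(`material_model(law = "neo_hookean")`, solved by a modified Newton
iteration with the elastic stiffness as preconditioner) for checking that
geometric/material nonlinearity is negligible at the measured strains — at
the ~1% strains of these experiments it agrees with the linear law to <1%.

### Meshing

`build_mesh()` builds a conforming tetrahedral mesh by structured extrusion:
one 2D cross-section layout (a polar disk under the cavity joined to a
circle-to-square blended ring around it) is triangulated once, instantiated
at a set of z-levels that follow the cavity profile (straight wall, fillet
arcs subdivided by arc length), and each triangular prism between levels is
split into three tetrahedra using the lowest-global-index face-diagonal
rule, which guarantees matching diagonals on shared faces. Element size is
~`target_edge_length` near the cavity and grows geometrically toward the
remote base and lateral boundaries. For the default geometries the meshed
cavity volume and all boundary-group areas agree with the closed-form
filleted-solid values within 0.5-1%.

### Volumetric PIV

`piv3d()` discretizes the stack pair into interrogation boxes (default
32 x 32 x 8 voxels, 50% overlap) and cross-correlates each box pair with
zero-mean, zero-padded (linear) correlation, normalized by the overlap
volume of each shift so the peak shape is unbiased. Displacement is
estimated in two passes: an integer peak first, then a discrete window
offset (the deformed window is re-cropped at the integer shift) so that the
residual correlation is symmetric and the three-point Gaussian subpixel fit
is unbiased; integer translations are therefore recovered exactly on boxes
whose offset window stays inside the stack. Vector validation uses the
universal normalized-median test against grid neighbors; outliers are
replaced by the neighborhood median and flagged.

Known behavior: axial (z) errors exceed lateral ones because the axial
point-spread function is ~3x elongated and the axial box extent (8 planes)
truncates every blob — the same anisotropy the imaging itself has. Lateral
subpixel accuracy on well-seeded boxes is ~0.03 px (median).

Small wells put steep displacement gradients within one default box, which
low-passes the measured wall displacement by ~10%. For well-size analyses
the pipeline configuration therefore uses 16 x 16 x 8 boxes: at the typical
surface seeding (~12 particles per 32 x 32 x 8 box, i.e. ~2 beads/µm² on
the surface) the smaller boxes still hold 4-5 particles, the minimum the
PIV literature recommends.

### Optical corrections

The nominal z-step Δs overstates the true focal step inside the sample when
the immersion and sample refractive indices differ. `apply_visser()`
rescales all axial coordinates by Δf/Δs with
Δf = tan(asin(NA/n1)) / tan(asin(NA/n2)) · Δs *before* any surface
localization or PIV, so everything downstream operates in physical µm. Note
the direction: Δf grows with the sample index n2 and shrinks with the
immersion index n1 (paraxial limit Δf → (n2/n1)Δs).

Cell-induced lensing (apparent displacements from refraction through the
cell body) is handled as a displacement-space subtraction of a calibration
field (`lensing_correction()`), supplied from control experiments or a
model; the package deliberately treats the calibration as an input contract
rather than predicting it from cell optics.

### Surface localization

The gel top is the peak of the plane-mean intensity profile (beads
concentrate at the free surfaces), refined to sub-plane precision by a
three-point parabolic fit. The well bottom is placed at a fixed offset
(the model depth) below the top — intensity-based bottom detection is too
unreliable. The well axis is found in a mid-depth plane by maximizing a
ring-contrast score (mean intensity in the annulus just outside the
expected radius minus the interior-disk mean) over candidate centers,
coarse-to-fine; the radius is then set to the half-rise point of the
azimuthal-mean radial intensity profile, which is unbiased for a blurred
edge (a gradient-maximum criterion is biased outward here because the bright
bead layer sits just outside the wall). A manual circle override is
available and is a first-class path, as in practice.

### Inverse traction reconstruction

The unknowns are nodal traction vectors on the well wall and floor. With
the linear forward operator `Forward(T)` (one sparse Cholesky factorization
reused for all sensitivity columns), `solve_inverse()` minimizes

    sum_i w_i || u_model_i - u_meas_i ||^2  +  lambda ||T||^2_w ,
    u_model = Forward(T)

over measured surface nodes i (gel top + wall + floor), with weights w =
lumped nodal areas so both terms approximate surface integrals. Mechanical
equilibrium is satisfied exactly because any reconstruction is a forward
solution. The gel top is traction-free *by construction* (its dofs are not
unknowns) while its displacement data still constrain the fit — this is
what distinguishes the method from imposing measured displacements as
boundary conditions. The direct-Dirichlet variant is kept
(`direct_dirichlet_solve()`) as a diagnostic: with noisy data it produces
spurious tractions on the gel top, which is exactly why the inverse
formulation exists.

Regularization: Tikhonov on the traction magnitude, with the unitless
`lambda` scaled internally against the data term so values ~1e-3 are a
sensible default across meshes. `choose_lambda_lcurve()` picks the corner
of the log-log misfit/penalty curve by the triangle (distance-to-chord)
method. With noiseless consistent data and lambda = 0 the reconstruction is
exact to solver precision.

### Unfolding and metrics

Wall tractions are decomposed into the local cylinder frame — T_n (outward
normal; negative = contractile), T_v (vertical), T_c (circumferential) —
and bottom tractions into T_n, T_r (radially outward), T_c. Maps are
resampled onto regular (theta, z) or disk grids by piecewise-linear
interpolation on a Delaunay triangulation of the scattered nodes (data
replicated across the 0/360 degree seam for periodicity); nodal values are
reproduced exactly. The top ~1 µm of the wall, where the rim fillet
concentrates discretization error, is excluded from maps and profiles.
Circumference averages yield mean ± sd profiles against z (wall) or r
(bottom); profiles from wells of different depths are aligned at their
lowest point and overhang samples are flagged out of group statistics.
Scalar metrics: measure-weighted mean T_n-wall (and the unweighted
profile-sample mean, since either convention may be wanted), coefficient of
variation (sample sd / mean, absolute value), SNR as the ratio of mean
absolute signal to mean absolute noise profiles, net force as
sum(traction x area) with sign/component filters, contact area and
cylinder-approximation cell volume with exact fillet corrections.

## The synthetic generator

`sample_beads()` + `render_stack()` + `warp_beads()` (bundled by
`simulate_well_experiment()`) emulate the imaging regime:

* calibration 0.104 µm lateral pixels, 0.2 µm z-steps; a rendered bead spans
  ~2.3 px FWHM (the PIV optimum, matching the 200 nm beads used);
* anisotropic Gaussian PSF, sigma_z/sigma_xy = 3, emulating confocal axial
  elongation;
* surface-biased seeding: a bulk density (default 0.05 beads/µm³) plus
  surface layers on the gel top, wall and floor (default 2 beads/µm²,
  consistent with the ~12 particles per interrogation volume typically found
  at the gel surface). Within the 0.6 µm layer the concentration peaks at
  the surface and decays exponentially inward (scale 0.2 µm): beads
  accumulate against the mold during polymerization, and a uniform layer
  would artificially bias the plane-mean surface-localization peak ~0.3 µm
  into the gel;
* deformation by warping bead positions with the forward FEM solution of a
  prescribed traction (the canonical case is an axisymmetric normal-traction
  ring on the wall, with raised-cosine axial edges — `ring_traction()`;
  band-limited edges make the prescription resolvable by a finite
  interrogation volume);
* additive Gaussian camera noise, all randomness seeded.

What the generator does *not* emulate: diffraction/Airyscan optics,
photobleaching, gel swelling drifts, cell autofluorescence, or refractive
lensing by the cell body. Passing the synthetic loop therefore validates
the computational chain (localization through inversion and unfolding) under
realistic sampling and noise — it does not certify the optical corrections
against real aberrations, which require the calibration experiments
described above.

## Numerical choices and degenerate inputs

* FFT correlation is zero-padded; search range is ±box/4 voxels by default;
  peaks on the search boundary are flagged invalid, never refined.
* The three-point Gaussian subpixel fit falls back to parabolic when a
  neighbor is non-positive.
* Flat interrogation boxes (no intensity variance), all-zero stacks, and
  featureless planes raise typed errors rather than producing vectors.
* Delaunay triangulation applies a deterministic ~1e-11 jitter to break the
  cocircular degeneracies of regular grids; interpolation queries outside
  the hull take nearest-sample values.
* Interpolation of PIV fields at surface nodes is trilinear on the sample
  grid; cells touching invalidated samples fall back to the nearest valid
  sample (renormalizing over remaining corners was tested and is more biased
  near the masked cavity).
* At the well axis (r = 0) the in-plane cylindrical components are
  undefined; such nodes get T_r = T_c = 0 and a degeneracy flag.
* The normal-equation solve adds `solver_tol` (default 1e-10) times the mean
  diagonal as ridge, purely for numerical conditioning.

## Problem sizes used in the shipped tests

Unit tests run on a small well (R = 5 µm, depth 8 µm, gel 25 µm) meshed at
1.6 µm (~2000 nodes). The forward-inverse oracle uses R = 7.5 µm,
depth 11.5 µm meshed at 1.5 µm (~5500 nodes, ~1500 traction dofs). The
end-to-end loop renders 198 x 198 x 84 voxel stacks (~1100-1300 beads) and
averages the recovered ring amplitude over independent bead realizations,
the same way experimental numbers average over cells. These sizes were
chosen so the full validation battery runs on a laptop-class machine;
accuracy at production sizes improves with finer meshes (the shipped
convergence test shows ~1% change under mesh halving at the sizes above).

## Known limitations

* Linear tetrahedra with nu = 0.45: mild volumetric locking; a mixed
  formulation would be the natural extension for nu -> 0.5.
* Single-pass PIV (with discrete window offset): no iterative window
  deformation; strong gradients within a box are low-passed, which
  systematically underestimates near-wall displacement by ~10% with default
  boxes on small wells (use smaller lateral boxes, as the pipeline config
  does).
* The top-surface estimate rides on the bead layer's intensity peak; any
  physical offset between that peak and the mechanical surface translates
  into a mesh alignment offset of the same size.
* Tikhonov regularization biases amplitudes toward zero as lambda grows;
  report amplitudes with the lambda used.
* The lensing correction is only as good as the supplied calibration field.
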