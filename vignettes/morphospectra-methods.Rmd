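---
title: "Spectral decomposition of whole-embryo surface morphogenesis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral decomposition of whole-embryo surface morphogenesis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Time-lapse recordings of a developing embryo yield one closed, genus-0
surface mesh per frame (for ascidian embryos, segmented whole-embryo
surfaces at minute-scale intervals; vertex counts and connectivity differ
arbitrarily between frames). `morphospectra` turns such a sequence into a
compact, standardized description of *where* and *when* the embryo
deforms:

1. a fixed-topology sphere mesh is deformed onto every frame, so its
   vertices become **Lagrangian markers** of the surface;
2. marker trajectories give a velocity field whose symmetric tangential
   gradient is the **surface strain-rate tensor** `D`; its eigenvalue norm
   `f = sqrt(l1^2 + l2^2 + l3^2)` is a scalar morphological-activity
   field;
3. `f(theta, phi, t)` is decomposed spatially into **spherical
   harmonics**, `f_lm(t) = sum_v f(v) conj(Y_lm(v)) w_v`;
4. each coefficient series is decomposed temporally into
   **Ricker-wavelet scalograms**, whose maxima localize morphogenetic
   events in time and duration.

# Lagrangian markers

## Reference sphere

The reference mesh is an icosahedron refined by interpolating butterfly
subdivision (8-point stencil, tension 1/16; the published
extraordinary-vertex rules at the twelve valence-5 vertices), with each
new vertex re-projected onto the unit sphere. Interpolating subdivision
keeps existing vertices fixed, so the parametrization is stable across
levels; re-projection keeps the sphere exact, which the spherical
quadrature below relies on. The default level is 4 (2,562 vertices,
5,120 faces): marker behavior is insensitive to the marker count well
before this density, while costs grow fourfold per level. The level is a
configuration knob (`subdivision_level`).

## Distance-descent fitting

`fit_surface()` moves every source vertex along the negative gradient of
its unsigned distance to the target surface — i.e. straight toward its
exact closest point on the target triangles (computed by a uniform-grid
accelerated point-triangle query in C++). Three numerical choices matter:

* **Step clamping.** The step is `min(0.3 * median target edge, d)`;
  clamping to the remaining distance `d` means a vertex within one step
  of the target lands exactly on it, never oscillates across it.
* **Tangential relaxation.** After each step, a Laplacian term (weight
  0.1) moves each vertex toward its ring-1 neighbor mean, projected onto
  the local tangent plane. This preserves mesh quality (prevents marker
  clustering in concavities) without pulling vertices off the surface.
* **Stopping and polish.** Iteration stops when the maximum residual
  falls below `tol = 0.5 * median target edge` — but the bare rule would
  strand vertices anywhere up to `tol` off the surface, a systematic
  radial lag that would corrupt marker tracking between frames. Two
  extra "polish" iterations after first reaching `tol` land vertices
  essentially on the target (residuals drop to ~1e-3 of an edge). If a
  fit starts within `0.05 * tol` of the target (a warm start on a static
  frame), it returns immediately, so static sequences give bitwise-static
  markers.

`propagate_markers()` fits frame 0 from a sphere enclosing the embryo
(1.1x its maximal radius about the centroid) and warm-starts each later
frame from the previous fit; a blend coefficient `alpha` mixes in the
recentred enclosing sphere for users who want to limit drift
accumulation (default 0: pure warm start). Because connectivity never
changes, the fitted sequence is a homeomorphic deformation of the sphere
at every frame.

**What this scheme can and cannot track.** Distance descent recovers the
*normal* component of inter-frame motion; purely tangential motion is
invisible (a translated sphere is the same point set). The junction
validation quantifies exactly this slippage. Consequently the package's
guarantees are stated for the small-deformation regime — inter-frame
displacements below one edge length (`evolving_surface()` warns
otherwise).

## Junction validation

On data with per-cell meshes, 3-cell junctions are detected as clusters
of mutually close triangle barycenters of three or more cells (contact
tolerance: 1.5x the pooled median cell edge), tracked across frames by
their member-cell set, and compared against the nearest marker: the
per-frame error is the mean absolute change of the junction-marker
distance, normalized by the mean apical edge length. On the synthetic
pulsation embryo (below) this error stays around 0.3%, far inside the
8% regime reported for real segmented data; the same statistic is the
package's acceptance gate.

# Strain-rate kinematics

Velocities are central differences of marker positions (one-sided at the
ends), in length units per hour. For each velocity component, per-triangle
linear-interpolation gradients are averaged onto vertices with area
weights, giving the intrinsic gradient matrix `G` whose rows are
tangential gradients of `v_x, v_y, v_z`. The tensor is the in-surface
part of its symmetrization:

    D = P sym(G) P,   P = I - n n^T  (vertex normal n).

The projection is deliberate. `sym(G)` alone retains an apparent
normal-direction shear for rigid rotations (a rotation about an in-plane
axis tilts the surface, which the 3x3 representation records as shear of
magnitude ~ omega/sqrt(2)); projecting both indices onto the tangent
plane cancels it identically while leaving genuine in-surface strain
untouched. The two analytic anchors are:

* uniform expansion `v = c x` on a sphere: eigenvalues `{c, c, 0}`,
  scalar `c sqrt(2)` (measured max deviation 0.1% at level 4);
* rigid rotation at matched speed: scalar below 0.02% of that reference.

Normal derivatives of the velocity field are unobservable from surface
data alone; no completion is attempted. Smoothing (a ring-distance
Gaussian over the 1- and 2-ring, sigma = 1 ring, truncated at ring 2, and
a discrete temporal Gaussian, sigma = 1 frame, reflected at the ends) is
applied to the *tensor* field, componentwise, before the scalar is
derived — smoothing after rectification would bias event amplitudes. The
scalar equals the Frobenius norm of `D`, so no eigendecomposition is
needed for it; eigenpairs (descending eigenvalues, sign-fixed
eigenvectors) are computed on demand by `strain_eigen()`.

# Spherical harmonics

The scalar field is a function of each marker's *original* sphere
coordinates `(theta, phi)`, so the forward transform is a quadrature over
the unit-sphere parametrization with the sphere mesh's barycentric vertex
areas as weights — not the deformed embryo's areas. This keeps the basis
orthonormal (discrete Gram deviation 1.6e-3 entrywise for `l <= 8` at
level 4) and makes coefficients comparable across frames; integrating
against the deformed-surface measure instead is available through the
`weights` argument of `harmonic_series()`. The basis is complex
orthonormal with the Condon-Shortley phase (built on `pracma::legendre`);
a real orthonormal basis drives the synthetic generator and is exported
for real-valued maps. `L_max` defaults to 12 — far above the `l <= 2`
modes usually displayed, for reconstruction quality — with an aliasing
guard when `(L_max + 1)^2` exceeds half the vertex count.

Variance ratios are per-frame coefficient-magnitude shares,
`vr_lm = |f_lm| / sum |f_l'm'|`, with the sum over *all* modes up to
`L_max` inclusive so shares sum to one exactly (reading the denominator's
strict bound as inclusive; otherwise ratios cannot normalize).

# Wavelet scalograms

Each series `f_lm(t)` is z-scored (population SD) over an analysis
window, then convolved with the Ricker wavelet

    psi_s(x) = 2 / (sqrt(3 s) pi^(1/4)) (1 - (x/s)^2) exp(-x^2 / (2 s^2)),

zero-padded at the window ends, over a geometric grid of 32 scales from 1
to N/4 frames, spanning impulse-like division events up to half-window
processes. Signed
coefficients are stored; magnitudes are displayed. A cone-of-influence
mask (`sqrt(2) s` from each end, the Gaussian e-folding width) marks
pad-contaminated cells; `find_events()` excludes them by default, then
extracts local maxima of `|C|` with non-maximum suppression in time and a
deterministic tie-break (earlier time, then smaller scale).

# The synthetic embryo

`deformation_script()` drives a radius field over the reference sphere,

    R(theta, phi, t) = R0 (1 + g(t) + sum a_lm(t) Yr_lm + pulses(t)),

realized by `make_deforming_sphere()` with exact trajectories and
analytic radial velocities as ground truth. Defaults emulate densely
sampled early-embryo recordings: `R0 = 60` length units, 60 frames 2
minutes apart. The canonical scripts, chosen once as the study
conditions:

* **pulsation** (`default_pulsation_script()`): 5% global radius
  amplitude, 1-hour period — inter-frame deformations ~1% of the radius,
  the small-deformation regime;
* **Y10 ramp**: `a_10(t) = 0.15 t` (reaching 0.3 at 2 h), the
  single-mode recovery condition;
* **two-phase invagination** (`make_invagination_embryo()`): a polar cap
  (half-angle pi/4) displaced inward with C1 rim blending,
  `B(s) = (1 - s^2)^2`, depth following two tanh ramps (10 + 10 units,
  centers 0.5 h and 1.5 h, width 0.1 h). The surface remains a radial
  graph, hence embedded, for any depth below `R0`.

`make_cell_tessellation()` adds a spherical centroidal Voronoi
tessellation (seeded directions, 30 Lloyd iterations on the area-weighted
vertex directions), extrudes each patch inward into a closed cell mesh,
and reports the true 3-cell junctions (mesh vertices whose incident faces
span 3+ cells, clustered by member set and adjacency). Optional isotropic
vertex jitter models segmentation noise (off in the acceptance
conditions).

**What the generator does not emulate:** tangential tissue flows
(radial-graph deformations have none — real gastrulation does, and its
slippage is only bounded, not resolved, by this scheme), cell
rearrangements and divisions (the tessellation is Lagrangian), varying
vertex density, segmentation topology errors, and anisotropic noise.
Green tests therefore certify the machinery (fitting accuracy, operator
convergence, spectral identities, event localization), not biological
fidelity on real data.

# A known negative result

A pure `Y10` radial drive does *not* make `vr(1,0)` the leading
non-constant mode of the scalar strain field, and cannot: the radial
velocity pattern `u ~ cos(theta)` changes sign between hemispheres while
the scalar field rectifies it (`f ~ |u|`), so `f` is even under
reflection and its `l = 1` content appears only through the `O(a)`
geometric asymmetry (measured end-to-end: `vr(2,0) = 12.3%`,
`vr(1,0) = 0.66%`). Dominant `l = 1` shares arise from
hemisphere-*localized* activity — as in invagination — not from a signed
`l = 1` velocity pattern. The corresponding acceptance test states the
single-mode expectation and fails with the measured shares; it is kept as
documentation of this property.

# Problem sizes and runtime

All shipped tests and the acceptance script run at the study conditions:
level-4 icosphere (2,562 markers), 60-frame sequences, 40-cell
tessellations, `l <= 12`, 32 scales. The full test suite completes in
about 3.5 minutes on one CPU; the acceptance script in about 2.

# Limitations

* Tangential motion is unobservable on featureless regions; marker
  trajectories are Lagrangian only in the small-deformation limit.
* The fit assumes genus-0, self-intersection-free targets;
  self-intersections after fitting are logged, not fixed.
* Quadrature-based harmonic transforms are exact only at the band limit
  the vertex density supports (the aliasing guard warns beyond it).
* No statistical significance is attached to scalogram events; the COI
  mask and non-maximum suppression are heuristics, not tests.
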