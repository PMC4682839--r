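---
title: "Methods: time-corrected thrombus reconstruction and Lagrangian shear analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-corrected thrombus reconstruction and Lagrangian shear analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A thrombus growing on the wall of a perfused microcapillary is imaged by
confocal microscopy as a z-stack: a sequence of optical sections acquired
bottom-up, one after the other. Scanning a typically sized thrombus
(about 75 x 12 x 30 um) takes 1.2 s, followed by 2.3 s of data transfer, so
consecutive stacks are 3.5 s apart and the slices *within* one stack span
1.2 s of real time. A thrombus at arterial shear grows appreciably on that
timescale, so a surface reconstructed directly from one stack is a time-skewed
composite: its lower portion was imaged before its upper portion, making the
bottom too small and the top too large relative to any single instant.

`thromboflow` implements the full chain needed to study what flowing platelets
experience before they adhere to such a growing surface:

1. **phantom** – synthetic growing thrombus-like geometries imaged by an
   emulated confocal microscope, providing exact ground truth;
2. **reconstruct** – segmentation, sub-pixel contour extraction and
   watertight triangulated surfaces from z-stacks, with ripple filtering;
3. **timecorrect** – level-set morphing of same-height contours between
   consecutive stacks, resampling an *instantaneous* stack at any timepoint;
4. **growth** – signed surface-to-surface distance maps by bidirectional
   normal-ray casting;
5. **flow** – steady incompressible Navier–Stokes in the rectangular
   microcapillary around the reconstructed surface (SIMPLE, staggered grid),
   plus the exact analytic duct solution;
6. **lagrangian** – backward pathline integration with an embedded adaptive
   Runge–Kutta 4(5) scheme and shear-rate histories prior to adhesion.

Units throughout: geometry and imaging in um, channel dimensions in mm in
configuration, time in s, shear rate in 1/s, viscosity in cP, velocity in m/s.

## The phantom: what it emulates, and what it does not

The synthetic data generator is first-class, tested code: every downstream
claim about time-correction accuracy is made against its exact instantaneous
volume and surface.

A phantom is a wall-attached half-ellipsoid
$x^2/a(t)^2 + y^2/b(t)^2 + z^2/c(t)^2 \le 1$, $z \ge 0$, with semi-axes
following linear, exponential or logistic growth laws. The lobed variant
perturbs the boundary radius by a seeded mixture of azimuthal cosine lobes
tapered with $\sin^2\theta$; because the relative amplitude is below 1 the
region stays star-shaped about the origin (single connected component), and
the exact volume is a cheap spherical quadrature. The default lobed preset
reproduces the typical thrombus bounding box of 75 x 12 x 30 um.

The emulated acquisition scans bottom-up with per-slice timestamps
$t = m(\mathrm{scan} + \mathrm{transfer}) + k\,\mathrm{scan}/n_\mathrm{slices}$
(defaults: 1.2 s scan, 2.3 s transfer, 0.5 um slices, 0.31 um/pixel, 12-bit
intensities in 16-bit TIFF containers, two blank guard slices below the wall,
emulating scanning from below the interface). Optional seeded Gaussian and
salt-and-pepper noise are off by default. The phantom emulates geometry and
timing only: it has no optical point-spread function, no spherical
aberration, and no red-blood-cell background. Passing tests therefore
demonstrate correctness of the *geometric* chain (segmentation through
time-correction and flow) under realistic sampling; they do not certify
robustness to optical artefacts of real confocal data.

For validation regimes we use linear growth with the rate set so the volume
grows by 12 % over one 3.5 s stack period
(`growth_rate_for_volume_increase(0.12, 3.5)`), and a gentler ~1 % volume
per second for the three-stack morphing studies.

## Reconstruction

Images are converted from their native bit depth to 8 bit by a fixed linear
scale with half-up rounding, then thresholded. No threshold value is imposed
by the protocol, so the default is Otsu's method on the pooled 8-bit
histogram of the whole stack — pooling keeps the threshold consistent along
z — overridable by a numeric value. Connected components smaller than the
area of a 2 um disk (the platelet scale) are discarded as specks.

Contours are traced as the 0.5 iso-level of each binary mask with sub-pixel
linear interpolation (`grDevices::contourLines`), one closed polygon per
connected component (holes traced clockwise), components touching the image
border closed along it and flagged.

Surfaces are iso-surfaces of the stacked mask volume, extracted by marching
tetrahedra on the Kuhn (six-tetrahedra) cube subdivision. This tessellation
is face-consistent across cells and the field is linear within each
tetrahedron, so orienting every triangle against the within-tet field
gradient yields watertight, consistently outward-oriented meshes by
construction — properties asserted (every edge shared by exactly two faces,
once per direction) rather than hoped for. The volume is zero-padded so the
surface closes, and the mesh is capped at the wall plane z = 0. Grid nodes
numerically on the iso-level are nudged off it by one part in 10^6 to avoid
degenerate triangles. Volumes come from the signed-tetrahedron (divergence
theorem) sum.

### Ripple filtering

Stacked reconstruction leaves oscillations between z-slices. Two filters are
provided under one generic:

* For segmented stacks (the standard path inside `build_surface()`), each
  slice's mask is converted to an exact polygon signed-distance field on the
  pixel lattice, the per-slice fields are smoothed along z with a narrow
  (1, c, 1)/(c+2) kernel (default c = 10, 8 passes, distances saturated at
  3 um so empty slices have bounded influence, edges replicated so the wall
  contact is not eroded), and the zero level is re-meshed. The inter-slice
  ripple is the highest z-frequency of this signal, so it is attenuated by
  about (c-2)/(c+2) per pass (~60x over 8 passes) while in-plane detail is
  untouched. A Taubin surface smoother was evaluated for this task and
  rejected: with umbrella weights the ripple projects onto mid-band mesh
  frequencies that a shrinkage-compensated lambda/mu pass attenuates far too
  slowly.
* For bare triangulated surfaces, a gentle Taubin lambda/mu pass
  (10 iterations, lambda = 0.5, mu = -0.53, z-biased edge weights, wall
  vertices pinned in z) is applied; analytically smooth inputs pass through
  within a small fraction of a slice thickness.

Both paths rescale the mesh uniformly about its (x, y) centroid and the wall
plane so the enclosed volume matches the unfiltered reconstruction — the
volume-drift contract (<= 1 %) is met at machine precision. Validation
fixtures: a cylinder with alternating per-slice radius (10 / 10.6 um) whose
radial standard deviation drops more than five-fold with the mean preserved,
and a right trapezoidal prism whose slanted face returns to planarity within
a tenth of a slice thickness.

## Time-correction

The correction morphs same-height contours between consecutive stacks and
resamples one frame per z-level at the requested timepoint $t^*$.

**Morph realisation.** The published description of this step is an active
contour/level-set evolution from the earlier contour toward the later one,
without stated parameters. We implement the evolution's fixed-point target
directly: contours are embedded as exact polygon signed-distance fields
(SDFs) on the slice pixel lattice, and the intermediate at morph parameter
$s$ is the zero level set of the linear blend $(1-s)\phi_1 + s\phi_2$. This
realisation is symmetric in its endpoints, handles topology changes
(splits/merges) without special cases, and has a dense analytic oracle for
testing: blending SDFs of concentric circles of radii 5 and 10 um yields a
circle of radius 7.5 um at mid-parameter to sub-pixel accuracy. Appearance
and disappearance are represented by giving the empty frame the SDF of a
collapse point (the other frame's area centroid), so growth from nothing
emerges as inflation. Multiple components in a slice are handled implicitly
by blending whole-slice fields rather than by explicit component pairing;
for thrombi further apart than the morph-grid margin the result is
identical, and merging/splitting fields remain well defined.

**Timing.** Intermediate k of n between acquired times $t_a < t_b$ is
stamped $t_a + k(t_b - t_a)/(n+1)$; n is chosen per bracket so the increment
is at most 60 ms (configurable) — the same order as the residual time band
reported for the original experiments. Acquired frames keep their metadata
times exactly. Sampling picks, per z-level, the frame nearest $t^*$, so the
realised band `delta_t_span` is bounded by twice the increment. Timepoints
before the end of the first stack's acquisition or after the start of the
last stack's cannot be corrected and raise an error naming the valid window.

The SDF grid is aligned to the image pixel lattice, and the instantaneous
mask is read directly off the blended field's sign at pixel centres; for a
static scene the resampled stack is therefore bit-identical to the acquired
one. Intermediate-frame SDFs are blended lazily at sampling time, so the
timeline stores only the acquired frames regardless of how fine the time
increment is.

**Validation.** On a semi-ellipsoid growing 12 % in volume per stack period,
the corrected surface volume is within 2 % of the phantom's exact
instantaneous volume (typically ~0.3 %), while the uncorrected stack shows
the expected skew: every slice acquired before $t^*$ is a strict pixel
subset of the instantaneous truth and every later slice a superset. On a
three-stack growing lobed phantom, the surface morphed from stacks 1 and 3
at stack 2's mid-acquisition time deviates from the directly reconstructed
stack 2 by well under 1.9 % in volume (typically ~0.02 %); `scripts/acceptance.R`
recomputes this end to end.

## Growth mapping

For every vertex of the earlier surface both vertex-normal rays (outward and
inward) are cast against the later surface (Möller–Trumbore, exact
distances). The signed distance is the nearest hit: positive outward
(adhesion), negative inward (consolidation/embolism); when both directions
hit, the smaller magnitude wins — this reports the nearest change and avoids
double counting on folded geometry, a case the source description leaves
open. Rays are capped at 20 um (the order of inter-thrombus spacing) so they
cannot hit unrelated thrombi; vertices with no hit are flagged invalid, never
zero-filled. Vertex normals are area-weighted face-normal averages. Multiple
components are paired greedily by centroid proximity and mapped pairwise;
unpaired reference components are flagged wholly embolized.

Classification uses a +-0.5 um neutral band (a quarter platelet diameter;
the source does not state its band). The net volume-change estimate
integrates signed distance against the trapezoid of the reference and
displaced per-vertex areas — the plain distance-times-area product
underestimates by d/R on curved surfaces (9 % for concentric spheres of 10
and 11 um, where the trapezoid form is exact to 0.04 %) — and the exact
watertight volume difference is always reported alongside.

## Flow

The microcapillary is a 2 x 0.2 mm rectangular duct perfused at 1.44 ml/min
with blood treated as incompressible and Newtonian at 2.8 cP. Derived
quantities: nominal wall shear rate $\gamma_w = 6Q/(wh^2) = 1800\,/s$,
hydraulic diameter $2wh/(w+h) = 0.36$ mm, aspect ratio $h/w = 0.1$. The
Reynolds number requires a density the protocol does not state; with
940 kg/m^3 (the pipeline default) Re = 7.3, matching the dynamic similarity
quoted for the original experiments. Note two convention points: the aspect
ratio is height over width (the printed "width/height = 0.1" formula is
inconsistent with its own value for this section), and the rate-of-strain
tensor is $D = \tfrac12(\nabla U + \nabla U^T)$ with
$\gamma = \sqrt{2\,D\!:\!D}$ — printed without the half, that definition
would return twice the imposed rate in simple shear and contradict
$\gamma_w = 1800\,/s$. Both choices are verified by construction tests
(simple shear returns the imposed rate exactly; rigid rotation returns 0).

The analytic fully developed duct profile is the standard odd-harmonic
Fourier series, normalised so its cross-sectional integral equals Q
(series truncated at a relative tail below 1e-9; hyperbolic ratios evaluated
in exponential form to avoid overflow at this aspect ratio).

The solver is SIMPLE pressure–velocity coupling on a staggered rectilinear
grid: first-order upwind convection (cell Peclet numbers are below one at
Re ~ 7, so upwind diffusion is negligible), central diffusion, Gauss–Seidel
momentum sweeps, SOR pressure correction (omega = 1.2; stronger
over-relaxation destabilises the singular Neumann pressure system on graded
grids), under-relaxation 0.7/0.3. The inlet carries the analytic developed
profile — rescaled so its *discrete* flux equals Q exactly, otherwise the
profile's quadrature error is an irreducible mass imbalance — which replaces
the long physical entrance region at identical end state. The outlet is a
zero-gradient outflow rescaled each outer iteration to conserve Q (bounded
during transients). Walls and obstacle are no-slip; the obstacle is the
watertight surface voxelized at cell centres (first-order immersed
boundary). Grids are graded toward the obstacle with a smooth density map
and a cell-expansion-ratio limit of 1.4; desk-scale runs use ~20k–40k cells
where the original study used ~17 million body-fitted elements. Residuals
are normalised by rho*Q (mass) and rho*Q*U_mean (momentum); the solver
default tolerance is 1e-8, and the package's desk-scale studies run at 1e-6
-- already far below every quantity compared here. Against the analytic duct
solution the empty-channel solve is within ~0.4 % at the centerline and ~2 %
in near-wall shear on a 24-cell-high grid, conserves the flux to rounding,
and its error decreases under refinement.

The local shear rate is computed from cell-centred velocities by central
differences, one-sided toward no-slip faces (walls, obstacle, inlet), as
$\gamma = \sqrt{2 D\!:\!D}$. With a 30 um phantom in the 200 um channel the
crown shear exceeds the nominal wall value several-fold, the expected
elevation over an obstruction.

## Lagrangian pathlines

Seeds are placed 1 um along the outward normal from every surface vertex
(half a platelet diameter, clearing the no-slip boundary); seeds falling
inside the obstacle or outside the domain are dropped and flagged. Pathlines
integrate $dX/dt = -U(X)$ with the Dormand–Prince embedded RK 4(5) pair;
velocities are interpolated trilinearly on the wall-padded cell-centre grid
(walls contribute exact zeros, the inlet its profile), the shear field is
sampled at every accepted step (edge-replicated at walls, where shear is
largest). The step controller keeps the per-step error estimate below an
absolute tolerance of 1e-8 um, which holds the *accumulated* spatial error
along a pathline below 0.001 um — verified, not assumed, by integrating
backward to the upstream plane and forward again for the same elapsed time:
the seed-to-return distance stays under 1e-4 um, and halving the maximum
step moves endpoints by less than the same bound. In the steady fields used
here pathlines coincide with streamlines, and platelets are massless tracers
(no finite-size or lift effects). Seeds caught in recirculation terminate by
stagnation (speed below 1e-9 m/s) or at a 30 s time cap; such paths are
reported with their termination reason, and are excluded from retrace
checks, where integrating through a near-zero-velocity region is ill-posed.

Each pathline is summarised over the last 3 s before (potential) adhesion —
the window is configurable, and truncated for shorter paths: the shear rate
at the seed (adhesion value), the window maximum (peak), and the
time-weighted trapezoidal mean. Whether the original analysis averaged over
time or arc length, and over the 3 s window or the thrombus interaction
region (TIR, 10 % of the thrombus length upstream — `thrombus_interaction_region()`),
is not stated; time-weighting over 3 s is the default here. Summaries are
mapped back onto the surface as per-vertex channels, joined with the growth
map by vertex index; untraced vertices are `NA`-flagged.

## Pipeline, problem sizes and determinism

`run_pipeline()` chains the six stages, writing every artifact (TIFF+JSON
stacks, PLY surfaces, VTK fields, CSV tables) plus a JSON manifest with
stage list, parameter echo and MD5 checksums; identical configuration and
seed give identical outputs. The `demo` preset studies a ~75 x 12 x 30 um
lobed phantom over three stacks with a 42 x 40 x 22 solver grid; `tiny` is a
plumbing smoke preset (a 0.4 mm-wide channel section at matched wall shear,
coarse grids) chosen so a full run completes in well under a minute. The
test-suite problem sizes follow the same philosophy: fixtures are as small
as still proves each property (e.g. spheres meshed at 0.7–0.8 um, one shared
desk-scale obstacle solve reused across flow, pathline and acceptance
checks).

## Known limitations

* No optics: segmentation robustness to PSF blur, spherical aberration or
  fluorescence noise beyond the simple noise model is untested.
* The immersed boundary is first-order (stair-step); shear *on* the surface
  is evaluated 1 um away, which also bounds sensitivity to reconstruction
  error, but sub-cell geometry is not resolved.
* Growth morphing interpolates shape, not motion: advection of a translating
  thrombus between stacks would be rendered as shrink-and-grow, as in the
  method this package implements.
* Correction uses the two bracketing stacks only (no higher-order temporal
  interpolation), and the correctable window excludes times before the first
  stack's end and after the last stack's start.
* Retrace closure — and hence the 0.001 um accuracy statement — applies to
  pathlines that reach a stop plane; trajectories ending in stagnation have
  no well-posed inverse.
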