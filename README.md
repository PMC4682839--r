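# thromboflow

Tools for quantifying the flow-induced shear history that platelets
experience before adhering to a growing thrombus, combining time-corrected
confocal reconstruction with desk-scale microchannel hemodynamics.

**Who it is for.** Researchers imaging wall-attached thrombi (or any growing
object) by confocal z-stacks who need instantaneous 3D geometry despite the
scan time, and who want the Lagrangian flow properties — in particular the
shear rate at, before and at peak prior to adhesion — on that geometry.

**The problem.** A confocal z-stack is acquired bottom-up over ~1.2 s, with
~2.3 s of transfer between stacks. A thrombus growing at arterial shear
changes measurably within one scan, so a surface built directly from a stack
is time-skewed: too small at the bottom (imaged early), too large at the top
(imaged late).

**The core method.** For each height z the segmented contours from
consecutive stacks are embedded as signed-distance fields φ₁, φ₂ on the
pixel grid; morphed intermediates are the zero level sets of
(1−s)·φ₁ + s·φ₂, each stamped with the time tₐ + s·(t_b − tₐ). Sampling the
frame nearest a requested time t\* at every z assembles an *instantaneous*
z-stack (residual time band ΔT ≤ twice the sampling increment), which is
reconstructed into a watertight triangulated surface (marching tetrahedra +
inter-slice ripple filtering). Signed growth between two surfaces is mapped
by casting both vertex-normal rays onto the later surface. Steady
incompressible flow (SIMPLE on a staggered grid; γ_w = 6Q/(wh²) = 1800 s⁻¹
for the 2 × 0.2 mm channel at 1.44 ml/min) is solved around the surface, and
platelet pathlines are integrated backward in time with an adaptive
Runge–Kutta 4(5) scheme, keeping the accumulated spatial error below
0.001 μm, to give per-vertex γ_adhesion, γ_peak and γ_mean (last 3 s).

A synthetic **phantom** module generates growing thrombus-like geometries
and emulates the confocal acquisition (time-skewed stacks with per-slice
z/t metadata), so every stage is validated against exact ground truth and no
external data are required.

## Worked example

A half-ellipsoid phantom (semi-axes 15 μm) grows 12 % in volume per 3.5 s
stack period while three stacks are acquired; the corrected surface at
stack 2's mid-acquisition time (t\* = 4.1 s) is compared with exact truth:

```r
library(thromboflow)

geom <- channel_geometry()   # 2 x 0.2 mm, 1.44 ml/min, 2.8 cP
geom
#> <channel_geometry> 2 x 0.2 x 100 mm, Q = 1.44 ml/min, mu = 2.8 cP
#>   gamma_w = 1800 1/s, D_h = 0.3636 mm, AR = 0.1

rate <- growth_rate_for_volume_increase(0.12, 3.5)
ph <- make_semi_ellipsoid_phantom(15, 15, 15, growth = growth_linear(rate))
sch <- acquisition_schedule(n_slices = 38, n_stacks = 3, width_px = 110,
                            height_px = 110, pixel_um = 0.62)
stacks <- acquire_zstacks(ph, sch)

t_star <- sch$period_s + sch$scan_s / 2
corrected <- time_corrected_surface(stacks, t_star)
corrected
#> <tri_surface> 28432 vertices, 56860 faces, watertight, t = 4.100 s
surface_metrics(corrected)
#> # A tibble: 1 × 4
#>   volume_um3 length_um width_um height_um
#>        <dbl>     <dbl>    <dbl>     <dbl>
#> 1      8050.      31.1     31.1      15.7
```

The corrected volume is within 0.23 % of the phantom's exact instantaneous
volume at t\* (8069 μm³), and the realised time band of the instantaneous
stack is 57.3 ms. From here `growth_map()` compares two corrected surfaces,
`solve_steady_flow()` + `compute_shear_field()` solve the channel flow
around one, and `seed_surface()` → `trace_pathlines()` →
`summarize_pathline()` → `map_summaries()` put the shear history onto the
surface. `run_pipeline(pipeline_config("demo"))` chains all six stages and
writes every artifact (TIFF+JSON stacks, PLY surfaces, VTK fields, CSV
tables) with a JSON manifest. A thin command-line front end is installed at
`inst/cli/thromboflow.R` (subcommands `phantom`, `reconstruct`,
`timecorrect`, `growth`, `flow`, `pipeline`).

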