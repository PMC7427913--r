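---
title: "Ray-based phase aberration correction for transcranial focused ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ray-based phase aberration correction for transcranial focused ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A hemispherical phased-array transducer focuses continuous-wave ultrasound
through the intact skull for thermal ablation or neuromodulation.  The skull
is both thicker and acoustically faster (roughly 2900 m/s in dense cortical
bone versus 1480 m/s in water) than the surrounding media, and its thickness
varies from element to element, so the per-element arrival phases at the
intended focus are scrambled; uncorrected, the focus is displaced and its
peak pressure reduced.  The fix is per-channel: drive element $n$ with an
excitation phase offset that restores a synchronous arrival at the target.

`skullray` computes those offsets from a CT volume of the skull by tracing
one geometric ray per element:

1. aim the ray at the commanded target, $\vec h_{w} = (t - s_0)/\|t - s_0\|$;
2. march along the ray in fixed steps, sampling the CT by trilinear
   interpolation, until the sampled value meets the bone threshold
   $\tau_{skull} = 700$ HU — the outer collision point $s_1$;
3. estimate the local surface normal with the three $3\times3\times3$
   Zucker–Hummel gradient operators, refract the ray by the vector form of
   Snell's law with the fixed water/bone speed pair, and march on through
   the bone to the inner threshold crossing $s_2$ (the skull exit);
4. refract again into the brain compartment and terminate the ray at its
   closest approach to the target;
5. convert the three segment lengths $d_w, d_s, d_b$ into a travel phase
   $$\phi_n = 2\pi f_0\left(\frac{d_{w}}{c_{w}} + \frac{d_{s}}{c_{s,n}} +
     \frac{d_{b}}{c_{b}}\right),$$
   and export the wrapped correction $\mathrm{wrap}(\phi_{ref,n} - \phi_n)$,
   where $\phi_{ref,n}$ is the homogeneous-water phase of the same element.

Elements whose incidence exceeds the critical angle
$\theta_c = \arcsin(c_w/c_s) \approx 30.7^\circ$ at the water–skull
interface have no transmitted longitudinal ray and are switched off, as in
clinical practice.

## Model choices and their rationale

**Aiming.**  Rays are aimed at the commanded target rather than the array's
geometric center.  For an electronically steered target the two differ, and
the path lengths are only meaningful along rays that actually approach the
target region.

**Sound speeds.**  Refraction at both interfaces uses the fixed pair
$c_w = 1480$, $c_s = 2900$ m/s: at the moment the first interface is hit
the tracer has no skull-specific speed estimate yet, so a representative
bone speed sets the refraction geometry.  The travel-time phase, by
contrast, uses a per-element skull speed $c_{s,n}$: the mean of the
HU-derived speed over the profile samples inside the two *cortical* regions
of the in-skull segment.  The cancellous dip between the two HU peaks of the
profile is excluded — its porous marrow would otherwise bias the average
with values that the linear HU-speed map does not represent well.  The
HU-to-speed map itself is a documented stand-in: a two-point linear ramp
anchored at (0 HU, 1480 m/s) and (1000 HU, 2900 m/s), clamped outside;
`speed_map()` makes it swappable.

**Brain compartment.**  $c_b = c_w$: the validation setting is an ex-vivo,
water-filled skull with no brain tissue, and the synthetic phantoms follow
it.

**Correction sign convention.**  The exported phase is
$\mathrm{wrap}(\phi_{ref} - \phi_n)$ on $[-\pi, \pi)$ with the boundary
mapped as $\pi \mapsto -\pi$.  This is the physically required convention
for refocusing — adding the correction to the skull-aberrated propagation
phase reproduces the homogeneous-water arrival — and the field module
verifies it end to end.  A clinical system may use a different internal
reference (e.g. a geometric delay table); only the pairwise differences
matter.

**Two-peak skull exit.**  The exit search must not stop at the first
below-threshold sample: in a two-table skull that sample may sit in the
cancellous layer.  The tracer therefore bridges below-threshold runs
shorter than `exit_gap_mm` (default 10 mm, comfortably above diploë
thickness) and exits at the first below-threshold sample after the last
cortical sample.  Both threshold comparisons are boundary-inclusive
(entry $\geq \tau$, exit $\leq \tau$); a profile that sits exactly at
$\tau$ everywhere is degenerate under this rule, but does not occur with
realistic HU contrasts.

**Element status semantics.**  Rays that never meet bone within the marching
budget keep a pure water path and stay *active* with zero correction — a ray
through a water window (craniotomy, or past the phantom's edge) is a
legitimate propagation path.  Rays whose in-skull march reaches the edge of
the scanned block while still in bone are `left_volume` and are deactivated:
the remaining bone thickness is unknowable.  Points sampled outside the
volume are treated as water precisely so that rays may legitimately start
outside the scanned block; consequently a first-collision march that finds
no bone is always `no_skull_hit`, never `left_volume`.  A flat-gradient
(degenerate-normal) neighborhood is mapped to `left_volume` as well:
per-element failures must deactivate, not throw.  The brain leg is clamped
at $d_b \geq 0$ (a target behind the skull exit contributes no negative
travel time; a warning is raised).

**Registration.**  Transducer and CT frames are aligned from corresponding
fiducial markers with the closed-form SVD solution of the orthogonal
Procrustes problem: center both sets, decompose the cross-covariance, and
correct the determinant so the estimate is always a proper rotation even
when noise favors a reflection.  This is the standard least-squares rigid
estimator for fiducial registration; abbreviated formulations that decompose
a single coordinate matrix do not minimize the correspondence error in
general.  Correspondence is by index; automatic matching is out of scope.
Fiducial detection binarizes above bone HU (default 2500), labels
26-connected components, and applies a granulometric size filter as an
equivalent-diameter band (nominal diameter ±50%) — equivalent to
morphological sieving for sphere-like markers and much simpler to test.

## The synthetic phantoms

No suitable public skull CT accompanies the validation protocol, so the
`phantoms` module generates parametric stand-ins with closed-form oracles:
flat and tilted bone slabs (optionally layered
cortical/cancellous/cortical), concentric spherical shells with and without
a cancellous core, and a fiducial frame of eight 2 mm high-HU spheres.
`analytic_path()` returns the exact Snell-refracted segment lengths and
travel phase in continuous space for slabs at arbitrary incidence and for
shells at radial incidence, entirely independent of the voxel ray tracer —
the dual-route check behind most of the test suite.

Two rendering choices matter and are deliberate:

* **Partial-volume edges.**  Each interface is rendered as a linear ramp of
  width `edge_width_mm` (default 1.0 mm) rather than a hard voxel step.
  Real CT has a finite acquisition point-spread function and bone
  boundaries always occupy intermediate HU in clinical scans.  This is not
  cosmetic: a $3\times3\times3$ gradient operator applied to a hard-edged
  binary volume aliases badly (normal errors of 5–20° in our measurements,
  quantized by which voxels happen to flip), while on a ramp wider than the
  kernel support it is nearly exact.  Setting `edge_width_mm = 0` restores
  hard edges for tests that need exact layer values at voxel centers.
* **Cortical HU of 1400.**  With a linear edge ramp from 0 to the cortical
  value, the $\tau = 700$ threshold crossing sits exactly at the edge
  half-maximum when cortical bone is 1400 HU — so threshold-based collision
  detection localizes the true geometric interface with no systematic bias,
  mirroring the standard full-width-at-half-maximum edge criterion.  1400 HU
  is a realistic dense cortical value.  Cancellous bone defaults to 300 HU
  (below threshold, giving the characteristic two-peak profile) and
  fiducials to 3000 HU (separable by thresholding above bone).

What the phantoms do *not* emulate: CT noise texture and beam hardening
(optional Gaussian HU noise is available but off by default), realistic
skull curvature and thickness variation, trabecular microstructure, and any
shear-mode conversion.  Tests passing on these phantoms therefore validate
the geometry, refraction and phase arithmetic of the implementation — not
clinical accuracy on real skulls.

## The forward field model

`simulate_field()` sums free-space monochromatic point sources,
$p(x) = \sum_n a_n r_n^{-1} e^{i(k_w r_n + \varphi_n)}$, over a sampling
plane (default 0.25 mm step, 10 mm × 10 mm, the usual hydrophone raster).
The skull enters as a per-element phase screen taken from the analytic
oracle; the ray-traced corrections are then applied on top, so the
round trip correction-versus-screen is a genuine cross-validation of the
tracer against the closed form.  Phase only: no transmission loss,
attenuation, or nonlinearity — matching a phase-only correction method.
Focal metrics are the peak-to-target distance per condition and the
corrected-to-uncorrected peak ratio, reported alongside the free-field
ceiling.  Lateral (XY) planes are used for the focal metrics: with a
narrow-cap array the axial depth of field exceeds the plane extent, and the
$1/r$ envelope, not the focus, would dominate an axial profile.

## Numerical choices and validation problem sizes

* Marching step 0.1 mm (default); collision localization error is bounded
  by one step plus the isosurface error of the interpolated volume.
  Halving the step never increases the localization error.
* Validation phantoms are rendered at 0.25 mm voxels with the 1 mm PSF
  ramp; at these settings ray-traced phases agree with the closed-form slab
  oracle to ≤ 0.55 rad at the 0.1 mm step and ≤ 0.1 rad at a 0.02 mm step
  for tilts up to 20°, which the test suite asserts.
* The concentric-shell suites use a scaled shell (radii 25/31 mm, 60 mm
  array radius) instead of a head-sized 70–80 mm shell: the symmetry and
  normal-accuracy properties are scale-free, and the volume stays at ~30M
  voxels.  The slab suites bound the rendered block laterally to the region
  the test rays traverse for the same reason.
* Arrays for the slab-oracle comparisons use a 5° cap half-angle so that
  total incidence stays within the ≤ 25° regime where the slab oracle's
  tolerances are stated; near the critical angle the refraction geometry
  amplifies any normal-estimation error without bound.
* Registration noise bounds (RMS ≤ 0.3 mm, rotation ≤ 0.5° at σ = 0.1 mm,
  K = 8) were computed from seeded Monte-Carlo runs before being frozen
  into the tests.

## Known limitations

One ray per element (no ray-bundle averaging); longitudinal propagation
only (no shear-mode conversion, the dominant simplification at high
incidence); no amplitude or apodization correction; no refraction at the
internal cortical/cancellous boundaries; the HU-speed map is a linear
surrogate; the field model is free-space summation, not full-wave
propagation.  The eccentric-shell geometry has no closed-form oracle here,
so end-to-end refocusing is validated on tilted slabs only.
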