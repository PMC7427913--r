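# skullray

Ray-based phase aberration correction for transcranial focused ultrasound
(tcFUS) treatment planning.

The skull defocuses a transcranial phased-array beam: its thickness and
sound speed (≈2900 m/s in dense cortical bone vs 1480 m/s in water) vary
from element to element, scrambling the per-channel arrival phases at the
target. `skullray` computes per-channel excitation phase offsets from a CT
volume by tracing one ray per element:

- **Collision detection** — march along the aimed ray in 0.1 mm steps,
  sampling the CT by trilinear interpolation, until the value meets the
  bone threshold τ\_skull = 700 HU (outer surface *s₁*), and again through
  the bone to the exit *s₂*, bridging the below-threshold cancellous dip
  between the two cortical HU peaks.
- **Surface normals** — the three 3×3×3 Zucker–Hummel gradient operators,
  ψᵢ(x,y,z) = x/√(x²+y²+z²) etc., applied to the HU neighborhood of the
  collision point.
- **Refraction** — vector-form Snell's law, sin θ\_T / sin θ\_I = c₂/c₁,
  with the fixed water/bone pair (1480, 2900) m/s at both interfaces;
  elements beyond the critical angle arcsin(1480/2900) ≈ 30.7° are switched
  off.
- **Aberrated phase** — φₙ = 2π f₀ (d\_w/c\_w + d\_s/c\_{s,n} + d\_b/c\_b)
  at f₀ = 650 kHz, where c\_{s,n} averages the HU-derived sound speed over
  the two cortical regions of the in-skull profile; the exported correction
  is wrap(φ\_ref − φₙ) in [−π, π).
- **Registration** — rigid alignment of transducer and CT frames from
  corresponding fiducial markers (SVD/orthogonal-Procrustes with
  determinant correction), with marker detection by thresholding,
  26-connected labeling and a granulometric size filter.
- **Phantoms and field model** — parametric skull phantoms (slabs, shells,
  fiducial frames) with closed-form path/phase oracles, and a monochromatic
  Rayleigh-summation field model to verify refocusing in silico.

## Worked example

Correct a 10°-tilted 6 mm bone slab for a 256-element, 150 mm array driven
at 650 kHz, and verify the refocusing with the forward field model:

```r
library(skullray)

spec <- phantom_spec("tilted_slab", tilt_deg = 10, spacing = 0.25,
                     bbox_lo = c(-14, -14, -45), bbox_hi = c(14, 14, -19))
vol  <- voxelize(spec)                       # synthetic CT, HU in [0, 1400]
arr  <- make_hemisphere_array(n = 256, radius = 150, cap_half_angle = 14)

pc <- build_correction(vol, arr, target = c(0, 0, 0))
pc
#> <phase_correction> 256/256 channels active, f0 = 650 kHz
#>   element status: ok=256

head(ray_table(pc$paths), 3)
#>   element status theta_I_ws_deg theta_T_ws_deg d_w_mm d_s_mm d_b_mm miss_distance_mm
#> 1       1     ok          9.383         18.630  115.1    6.3 28.682            1.012
#> 2       2     ok         10.812         21.566  115.0    6.4 28.712            1.194
#> 3       3     ok          9.974         19.838  115.1    6.3 28.693            1.079
```

Every ray crossed the slab (status `ok`); the incidence angles around 10°
refract to ≈19–22° inside the bone, the oblique bone path is 6.3–6.4 mm, and
the uncorrected rays miss the target by ≈1 mm. Applying the corrections on
top of the slab's analytic aberration screen:

```r
screen <- aberration_screen(spec, arr, target = c(0, 0, 0))
plane  <- field_plane(c(0, 0, 0), "xy")      # 10 x 10 mm, 0.25 mm raster
metrics <- focal_metrics(
  simulate_field(arr, screen + pc$phi_corr, plane),   # corrected
  simulate_field(arr, screen, plane),                 # uncorrected
  simulate_field(arr, rep(0, 256), plane),            # free field
  target = c(0, 0, 0))
str(metrics)
#> List of 5
#>  $ shift_corrected_mm       : num 0
#>  $ shift_uncorrected_mm     : num 1.25
#>  $ shift_free_mm            : num 0
#>  $ gain_percent             : num 102
#>  $ corrected_vs_free_percent: num 99.9
```

The uncorrected focus is displaced 1.25 mm by the tilted slab; the
ray-traced corrections return the peak to the target (shift 0 mm, within
one 0.25 mm grid step), raise the focal magnitude above the uncorrected
level (gain 102%), and recover 99.9% of the free-field ceiling.

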