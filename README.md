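# vesica

Bladder wall motion and voiding flow analysis from pre- and post-void
surface meshes.

## What it does, for whom

Multichannel urodynamics measures bladder pressure and urinary flow but says
little about *how* the bladder wall moves while it empties. Given a pre-void
and a post-void bladder surface (STL, millimetres) segmented from 3D
imaging, plus a real-time cross-sectional area curve acquired during
voiding, vesica reconstructs an approximate space-time model of the wall and
the urine flow it drives. It is aimed at researchers in lower-urinary-tract
biomechanics and image-based physiological modelling.

The core model is separable radial wall motion in a spherical frame anchored
at the post-void volume centroid:

    dr(θ, φ, t) = d₀(θ, φ) · α(t),   dθ = dφ = 0

* **d₀(θ, φ)** — total pre-to-post radial displacement, measured per
  direction by Möller–Trumbore ray casting against both surfaces.
* **α(t)** — dimensionless voiding time course, from the area curve via
  α(t) = √((A(t) − A(t₀)) / (A(t_end) − A(t₀))) (0 at the start of voiding,
  1 at the end), with a square-root-of-cosine parametric form
  α = √((1 − cos πτ)/2) for subjects without real-time imaging.

On top of this the package computes regional five-number summaries
(anterior/posterior, dome/base, left/right), the left-right asymmetry ratio
100·|med_L − med_R| / ((med_L + med_R)/2), displacement probability
densities, volume and flow-rate curves, and a simplified 2D moving-boundary
incompressible flow simulation of voiding (staggered-grid projection method,
immersed moving wall, rigid urethra channel at atmospheric outlet) yielding
mean |vorticity|, dimensionless vorticity ω·D/Ū, and a recirculation
fraction. A seeded synthetic generator produces icosphere-based fixtures
with analytically known displacement fields and sigmoidal area curves.

## Worked example

```r
library(vesica)

# healthy-like fixture: dome-weighted contraction, 40 mm pre-void radius
sc   <- voiding_scenario("dome_weighted", r_pre = 40, shrink_fraction = 1/3,
                         dome_gain = 2, mesh_subdivisions = 4)
pair <- make_voiding_pair(sc)
field <- compute_displacement_field(pair$pre, pair$post)
glance(field)
#>   n_samples n_failed sampling     median_d0_mm asymmetry_pct max_tangential_mm
#> 1      2562        0 pre_vertices         13.5       0.00322                 0

regional_stats(field)
#>   region        n   min    q1 median    q3   max
#> 1 anterior   1313  13.3  13.5   13.5  19.2  26.7
#> 2 posterior  1249  13.3  13.5   13.5  19.1  26.6
#> 3 dome       1463  13.5  14.3   18.1  22.1  26.7
#> 4 base       1099  13.3  13.4   13.5  13.5  13.5
#> 5 left       1313  13.3  13.5   13.5  19.2  26.7
#> 6 right      1249  13.3  13.5   13.5  19.0  26.6

curve <- make_area_curve(10, 40, 4000, 400, n_samples = 64)  # sigmoidal RTI curve
kin <- volume_and_flow(pair$pre, field, alpha_curve = alpha_from_area(curve),
                       keep_meshes = TRUE)
glance(kin)
#>   v_pre_ml v_post_ml voided_ml q_max_ml_s q_mean_ml_s duration_s
#> 1     268.      58.1      209.       55.3        8.30       25.2

dom <- build_domain(kin, urethra = c(D = 5, L = 20))
sol <- solve_voiding_flow(dom, grid_h = 5/8)
glance(sol)
#>   mean_vorticity_per_s dimensionless_vorticity peak_recirc_fraction q_mean_mm2_s
#> 1                0.101                  0.0189                0.156         133.
```

Reading the output: the wall moves a median 13.5 mm, most at the dome
(median 18.1 mm) and least at the base — the dome-dominant healthy pattern —
with essentially zero left-right asymmetry (0.003%). The tangential
components are exactly zero: that is the radial-model contract, not an
estimate. The fixture voids 209 mL in ~25 s. In the flow simulation the
mid-plane mean |vorticity| is ~0.10 s⁻¹, the dimensionless vorticity 0.019,
and at most 15.6% of the bladder cross-section flows away from the outlet.
`autoplot()` methods exist for fields, regional statistics, α curves,
kinematics and flow solutions.

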