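---
title: "Bladder wall motion and voiding flow: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bladder wall motion and voiding flow: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesica)
```

## The problem

During voiding the bladder wall contracts from a full (pre-void) to a
near-empty (post-void) shape. Pre- and post-void surface meshes segmented
from 3D imaging, together with a real-time 2D cross-sectional area curve
acquired during voiding, contain enough information to reconstruct an
approximate time course of the whole wall and to drive a flow simulation of
the emptying bladder. vesica implements that post-processing chain: wall
displacement estimation, regional and asymmetry statistics, the voiding time
course, volume/flow kinematics, and a simplified two-dimensional
moving-boundary flow simulation with vorticity and recirculation metrics.
Healthy voiding is characterized by large, dome-dominant, left-right
symmetric wall motion; impaired voiding (e.g. with bladder outlet
obstruction) by smaller, lateralized motion, larger recirculation regions
and lower bladder vorticity at comparable geometry.

## The separable radial motion model

In a spherical frame anchored at the volume centroid of the *post-void*
bladder (axes: +x subject-left, +y anterior, +z dome), wall displacement is
in general a 3-vector field over the sphere and time. The model makes two
simplifying assumptions, both borrowed from cardiac chamber motion
estimation:

1. **Radial-only motion**: the tangential components are identically zero.
   A `displacement_field` therefore stores `dtheta_mm = dphi_mm = 0` by
   construction — this is a model contract, not an estimate.
2. **Separability**: `dr(theta, phi, t) = d0(theta, phi) * alpha(t)`, where
   `d0` is the total pre-to-post displacement along each ray and `alpha(t)`
   rises from 0 (start of voiding) to 1 (end).

`d0` is measured by casting rays from the origin through each pre-void
vertex (or through a near-uniform Fibonacci direction set) and differencing
the two surface distances, using the Möller–Trumbore ray-triangle
intersection test. The model is valid for surfaces that are star-shaped
about the origin; multiple ray crossings are flagged per sample, and more
than 5% failed rays is an error rather than a silently wrong field.

The time dependence comes from the area curve via
`alpha(t) = sqrt((A(t) - A(t0)) / (A(tend) - A(t0)))`, i.e. the radial scale
of a shrinking cross-section tracks the square root of its area. Observed
emptying curves are sigmoidal, so the package also provides the parametric
form `alpha(t) = sqrt((1 - cos(pi * tau)) / 2)`, `tau = (t - t0)/(tend - t0)`
(equivalently `sin(pi * tau / 2)`), whose induced area curve is a raised
cosine. The exact functional form is a package choice: it is the simplest
"square root of a cosine" satisfying both endpoint conditions, and the
area-ratio square root inverts it exactly (a property the tests assert at
1e-12). When only one subject has real-time imaging, the same fitted
`alpha(t)` can be applied to other subjects via `alpha_source = "canonical"`.

A consequence worth stating explicitly: with this `alpha`, the *area* shrink
rate is bell-shaped (slowest at the beginning and end of voiding), but the
*volume* flow rate `Q = -dV/dt` of the radial model is maximal at onset and
decreases monotonically, because `d(alpha)/dt` is largest at `tau = 0`. The
two statements are consistent — they describe different derivatives — and
the test suite pins down both behaviours.

## Regional statistics

The wall is partitioned three ways by coordinate sign in the bladder frame
(anterior/posterior, dome/base, left/right), with boundary samples assigned
to the positive side deterministically. Each region gets a five-number
summary of `d0` (quartiles by linear interpolation, R's default type 7). The
left-right asymmetry ratio is

```
100 * |median_left - median_right| / ((median_left + median_right) / 2)
```

The denominator — the mean of the two medians — is a package choice among
the normalizations compatible with "based on the difference between the
median displacements": it admits values above 100% for severely lateralized
motion (up to 200% in the limit), which matches the range reported for
obstructed voiding. Displacement probability densities use a Gaussian KDE
with Silverman's rule-of-thumb bandwidth.

## Voiding window detection

`detect_void_window()` works on a 5-sample moving-average smoothed curve,
estimates plateau levels as medians of the top/bottom sample deciles, and
takes threshold crossings (1% of the total change) that persist for three
consecutive samples. Because a sigmoidal curve leaves its plateau
tangentially, any threshold detector lags the true onset by a few percent of
the voiding duration (about 2 s on a 30 s event at the 1% threshold); the
tests assert that achievable accuracy rather than an idealized one.
Smoothing is engaged only when the residual-vs-moving-average is serially
anti-correlated (the signature of noise); smoothing an already clean curve
would only bias the square root near `t0`.

## The synthetic generator

No bladder meshes are distributed with the package, so `voiding_scenario()`
plus `make_voiding_pair()` generate icosphere-based pre/post pairs with an
*analytically known* displacement field, in three patterns:

* `uniform` — `d0 = shrink_fraction * r_pre` everywhere (concentric spheres);
* `dome_weighted` — scaled by `1 + (dome_gain - 1) * max(0, cos theta_dome)`,
  emulating the dome-dominant healthy pattern;
* `asymmetric` — left hemisphere scaled by `asym_gain`, blended smoothly over
  a 10 degree band at the midplane (a hard seam would be unphysical and
  ill-posed for ray-casting recovery). With `asym_gain = 1.5` on a uniform
  base the implied asymmetry ratio is exactly 40%.

Default scales (pre-void radius 30–50 mm, shrink fractions 0.1–1/3,
voiding 20–40 s, areas of a few thousand mm²) are plausible adult bladder
scales chosen once; they are conventions of the fixtures, not measured
values. Area curves get i.i.d. Gaussian noise under a fixed seed. What the
generator deliberately does **not** emulate: segmentation error, non-radial
wall motion, partial-volume effects, or non-star-shaped anatomies. Passing
the recovery tests therefore shows the estimator inverts its own model
class exactly and stably — not that real bladders move radially.

One geometric subtlety: pre and post icospheres share vertex directions, so
sampling along pre-void vertices hits post-void vertices exactly and
recovery is machine-precision accurate. Convergence tests that need a real
discretization error rotate the post sphere so rays land in triangle
interiors; the chordal error then decays quadratically with subdivision.

## The flow simulation

The flow stage is a deliberately simplified stand-in for a full 3D
moving-boundary CFD study: a single mid-plane cut (sagittal by default;
coronal available, and used when the left-right asymmetric pattern must be
in-plane), incompressible Navier–Stokes on a uniform staggered (MAC)
Cartesian grid, fractional-step pressure projection with a direct sparse
solve, explicit first-order upwind advection, and a direct-forcing immersed
boundary: faces between fluid and wall cells carry the prescribed wall
velocity obtained from the level-set rate of the moving contour. A straight
rigid urethra channel (diameter `D`, length `L`, no-slip walls) is grafted
at the inferior contour point; its outlet is zero gauge pressure with
zero-gradient velocity. Fluid defaults are water-like urine at body
temperature (density 1000 kg/m³, viscosity 0.7 mPa·s).

Numerical choices:

* **Explicit diffusion.** With urine-like kinematic viscosity
  (0.7 mm²/s) and grid spacings of D/8–D/16, the viscous stability bound
  (`0.2 h²/nu`) is far looser than the advective CFL bound, so an implicit
  viscous solve would add a second sparse system per step for no gain. The
  adaptive time step honours both bounds plus `cfl * h / umax`.
* **Mass compatibility.** Staircase wall faces under-resolve the smooth
  contour, so raw prescribed face velocities are rescaled each step by a
  single factor making total wall influx equal the polygon-area shrink rate.
  The outlet flux then balances the contour shrink rate to solver precision
  — the per-step diagnostics record both sides, and the conservation test
  compares the *solved* outlet flux against the contour rate.
* **Pressure solve.** One sparse SPD system per step (the fluid mask moves),
  solved directly; post-projection divergence is checked each step and stays
  at rounding level (< 1e-6 of the velocity scale by contract, ~1e-13 in
  practice). The solver contains no randomness: identical inputs give
  bitwise-identical metrics.
* **Validation.** The same discretization (reflected-ghost no-slip,
  projection) solves pressure-driven channel flow; at 16 cells across the
  width the Poiseuille profile is reproduced to well under 2%, with a clean
  second-order error decay across 8/16/32 cells.

Metrics over the bladder region (channel excluded): mean |vorticity| per
snapshot and time-averaged (central differences on cell-centred velocity;
the unsigned mean is used because a recirculating flow's signed average can
cancel to zero, which would make between-group comparisons meaningless);
dimensionless vorticity `omega * D / Ubar` with `Ubar = Q/D` in the 2D
per-unit-depth sense (a pseudo-3D `Q/(pi D^2/4)` mode is provided); and the
recirculation fraction — the fraction of bladder cells whose velocity makes
an angle over 90 degrees with the direction to the outlet, among cells
moving faster than 1% of the snapshot maximum. The speed floor keeps
near-stagnant numerical noise out of the fraction; the angle criterion turns
"larger recirculation regions" into a number.

All flow comparisons are internal and ordinal: a control-like scenario
(large, dome-weighted, symmetric motion) is checked to produce larger median
displacement, lower asymmetry, higher mean vorticity and a lower peak
recirculation fraction than a BPH-like scenario (small, asymmetric motion,
same geometry), and nondimensionalization is checked to shrink the
between-scenario vorticity gap. No numeric agreement with any 3D simulation
is claimed.

## Problem sizes and tolerances

The shipped tests and the acceptance script run on desk-scale problems
chosen to finish in minutes on one CPU: icosphere subdivisions 2–4 (up to
2562 sample directions), 33–64 time samples, flow grids of ~3000–6000 cells
(8 cells across the urethra; a 15 mm bladder radius), a few hundred solver
steps per run. Key tolerances: ray-oracle agreement 1e-9 relative;
concentric-sphere recovery 2% at subdivision 4; asymmetry recovery 5%
relative; volume conservation 0.5%; Poiseuille 2%; outlet-vs-contour mass
balance 2%; post-projection divergence 1e-6.

## Known limitations

* Real anatomies that are not star-shaped about the post-void centroid
  violate the model; the package flags and fails rather than repairs.
* The 2D flow plane cannot represent out-of-plane swirl; vorticity and
  recirculation values are not comparable to 3D magnitudes.
* First-order upwind advection is diffusive; at the low Reynolds numbers of
  voiding (Re ~ 100) this smooths but does not suppress the recirculation
  patterns the ordinal comparisons rely on.
* STL carries no units or anatomical orientation: millimetres are a
  documented convention (`--scale` in the CLI) and frame axes for real data
  are a required input.

## A worked example

```{r example, eval = FALSE}
sc <- voiding_scenario("dome_weighted", r_pre = 40, shrink_fraction = 1/3,
                       mesh_subdivisions = 4)
pair <- make_voiding_pair(sc)
field <- compute_displacement_field(pair$pre, pair$post)
glance(field)
stats <- regional_stats(field)
autoplot(stats)

curve <- make_area_curve(10, 40, 4000, 400, n_samples = 64)
ac <- alpha_from_area(curve)
kin <- volume_and_flow(pair$pre, field, alpha_curve = ac, keep_meshes = TRUE)
glance(kin)

dom <- build_domain(kin, urethra = c(D = 5, L = 20))
sol <- solve_voiding_flow(dom, grid_h = 5 / 8)
glance(sol)
```
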