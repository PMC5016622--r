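---
title: "Methods: from plant architecture to whole-plant photosynthesis"
author: "canopyray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from plant architecture to whole-plant photosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyray)
```

# The problem

Canopy photosynthesis models classically assume that light decays
exponentially with depth (Beer–Lambert) and that photosynthetic capacity
tracks that decay. In a real greenhouse canopy, light interception is
strongly heterogeneous — sun direction, diffuse fraction, leaf angles,
and shading by neighbour plants all matter — and for a V-trellised sweet
pepper (*Capsicum annuum*) the vertical profiles of capacity turn out to
be closer to linear than exponential. `canopyray` implements the
alternative estimation chain end to end:

1. **Architecture** — rebuild the plant as a triangle mesh from a
   per-layer structural table (leaf area, petiole length, droop angle,
   internode length, stem radius);
2. **Light transport** — Monte Carlo ray tracing of the direct beam plus
   an isotropic diffuse sky through the (optionally replicated) canopy,
   with leaf reflectance and transmittance;
3. **Leaf physiology** — the Farquhar–von Caemmerer–Berry (FvCB) model,
   parameterised per canopy layer from light-response and A/Ci
   gas-exchange curves using partitioned fitting windows;
4. **Integration** — area-weighted layer irradiances drive per-layer FvCB
   rates that sum to a whole-plant rate on a half-hourly weather series;
5. **Validation** — inversion of a sealed-chamber CO2 drawdown log to
   measured whole-plant rates.

Every input has a synthetic generator with known ground truth, so the
whole chain is testable as a closed loop without any instrument data.

# Leaf model

At a fixed leaf temperature of 25 °C (no temperature response functions
anywhere in the package), net assimilation is

$$A_l = \min(A_v, A_j) - R_l$$

with the Rubisco-limited rate $A_v = V_l (c_i - \Gamma^*)/(c_i + K')$,
the effective Michaelis constant $K' = K_c (1 + O/K_o)$, and the
RuBP-regeneration-limited rate
$A_j = J (c_i - \Gamma^*) / (4 (c_i + 2\Gamma^*))$. Electron transport
$J$ is the smaller root of
$\theta_l J^2 - (I_{le} + J_m) J + I_{le} J_m = 0$ driven by the PSII
effective irradiance $I_{le} = I_l (1 - f)/2$, where $I_l$ is the PPFD
absorbed per unit leaf area (supplied by the ray tracer). Light-response
curves use the non-rectangular hyperbola with parameters
$(A_{max}, \phi, \theta, R_d)$.

Constants (`fvcb_constants()`): $K_c = 40.4$ Pa, $K_o = 24.8\times10^3$
Pa, $O = 20.5\times10^3$ Pa, $\Gamma = 4.4$ Pa, $\Gamma^* = 3.69$ Pa,
$f = 0.15$.

**Respiration.** The source constants state two slightly inconsistent
rules: a fixed coefficient $R_l = 0.0089\,V_l$ and the compensation-point
ratio $R_l/V_l = (\Gamma - \Gamma^*)/(\Gamma + K')$, which evaluates to
$0.00908\,V_l$ at the constants above. Both are implemented
(`leaf_respiration(rule = "table3" | "eqA7")`); the coefficient rule is
the default because it is stated explicitly as a value, and the ratio
rule is the one that pins the net CO2 compensation point at exactly
$\Gamma$ when Rubisco limits — the package's root-finding checks use
each rule for the property it guarantees.

```{r}
p15 <- fvcb_params(vl = 88.62, jm = 175.42, theta = 0.75,
                   resp_rule = "eqA7")
compensation_point(which = "gross")              # Gamma* = 3.69 Pa
compensation_point(p15, il = 1000, which = "net",
                   interval = c(3.7, 30))        # Gamma = 4.4 Pa
```

# Fitting gas-exchange curves

The measurement protocol is a 20-point A/Ci curve (external CO2 0–120 Pa
at PPFD 1000 µmol m⁻² s⁻¹) and a 20-point light curve (PPFD 50–1000 at
100 Pa external CO2) per canopy layer.

* `fit_light_curve()` fits the non-rectangular hyperbola by bounded
  Levenberg–Marquardt least squares ($A_{max} > 0$, $\phi \in (0,
  0.125]$, $\theta \in (0,1)$, $R_d \ge 0$) with three deterministic
  starts; non-convergence is flagged on the result, not thrown.
* `fit_vl()` uses only points with $\Gamma^* < c_i < 30$ Pa, where
  Rubisco limitation can be assumed, and fits
  $A_{net} = V_l[(c_i-\Gamma^*)/(c_i+K') - r]$. Respiration is coupled
  to $V_l$ through the active rule's coefficient $r$ because the
  measured quantity is net assimilation; since the model is linear in
  $V_l$, the least-squares solution is computed exactly by linear
  regression (a fixed-$R_l$ mode is also provided — the measurement
  protocol does not record which convention an instrument operator would
  use, so both are labelled).
* `fit_jm()` uses points with $c_i > 40$ Pa. Because the defining
  relations are algebraic, each point is inverted exactly:
  $A_j = A_{net} + R_l$, then
  $J = 4A_j(c_i + 2\Gamma^*)/(c_i - \Gamma^*)$, then
  $J_m = J(I_{le} - \theta_l J)/(I_{le} - J)$. The estimate is the mean
  of the per-point $J_m$ and the SE their standard error; points with
  $J \ge I_{le}$ are impossible under the quadratic and are dropped with
  a warning. A joint NLS would pool the windows; the per-point inversion
  matches the algebraic form of the defining equations and makes the
  noiseless round trip exact. $\theta_l$ defaults to the same layer's
  light-curve estimate, falling back to 0.75, the midpoint of the
  observed 0.68–0.83 range.

**Window caveat.** For layers with a small $J_m/V_l$ ratio the full
min-rule model can remain Rubisco-limited well above 40 Pa, in which
case the high-window inversion estimates the wrong branch. The
synthetic generator therefore supports forcing a single limitation
(`gen_aci_curve(limitation = "rubp")`) to emulate curves in which the
assumed partition holds, and the round-trip tests use it for exactly
those parameter sets.

# Plant architecture

The structural table (`read_layer_spec()`) records odd node positions
1, 3, …, 15; even nodes are linearly interpolated
(`expand_layer_spec()`). Interpretation of the tabulated leaf count `n`
(per layer, per plant): an odd layer $k$ spans nodes $\{k, k+1\}$ on
both stems, so `n = 4` is one leaf per node per stem; the terminal layer
15 is a single node pair carrying `n = 6`, i.e. three leaves per stem —
34 leaves in total, matching the tabulated counts.

Geometry choices the data do not constrain, fixed once:

* **Blade outline** — a flat ovate-cordate polygon fan (24 triangles)
  scaled anisotropically to the tabulated area (aspect ratio 1.5).
  Interception at this scale is governed by area and angle, not outline
  detail.
* **Phyllotaxis** — azimuths alternate 180° per node with a seeded
  ±10° jitter; the second stem's base azimuth is offset 90°.
* **Trellis** — the two stems lean ±30° from vertical in the row plane
  (the "V" training system); droop is applied as a pitch of the blade
  below horizontal at the petiole tip, and the petiole displaces the
  blade horizontally by its tabulated length.
* **Units and frame** — meters internally (cm/mm converted at the
  boundary); right-handed, z up, ground at z = 0, rows along x, y
  toward compass north unless a north offset is given.

`build_canopy()` replicates the plant on a rows × cols grid (0.8 m
default spacing); detectors (the surfaces whose irradiance feeds the
physiology) belong to the centre plant of an odd × odd array, with
neighbours acting as shading geometry.

# Light transport

`trace_scene()` performs forward Monte Carlo ray tracing. Emitters are
built from the global horizontal PPFD and the diffuse fraction $d$: a
parallel beam along the solar vector carrying $(1-d)\,I_0$ per unit
horizontal area, and an isotropic diffuse sky carrying $d\,I_0$, both
emitted from a horizontal source plane sized to over-cover the scene
(including the beam's lateral drift at low sun). The sky is isotropic
because no sky radiance model is implied by a single diffuse fraction.

At each surface hit the absorbed fraction $1-\rho-\tau$ of the ray's
energy is scored to that surface; the ray continues with the remaining
$\rho+\tau$, choosing reflection vs transmission with probability
$\rho : \tau$ and a Lambertian direction about the local normal
(incident side vs far side). Rays terminate on escape or after
`max_impacts` (default 10) interactions, the remainder being booked as
truncated, so

$$\text{absorbed} + \text{escaped} + \text{truncated} = \text{emitted}$$

holds to floating-point accumulation error (Kahan-compensated totals;
the test suite checks 1e-10 relative). Scoring the absorbed fraction
deterministically rather than by absorb-or-survive roulette keeps the
bookkeeping exact and lowers variance at identical cost. Leaf optics
default to $\rho = 0.1$, $\tau = 0.07$ on both sides (integrating-sphere
values for this crop); stems are opaque black.

Implementation: triangles in a bounding-volume hierarchy (median split,
built in C++); every ray owns a counter-based RNG stream derived from
(seed, ray index), so a fixed seed reproduces the interception map bit
for bit regardless of traversal details, and scenes sharing a bounding
box sample identical ray streams (which is what makes the deterministic
shadowing-monotonicity test exact rather than statistical). Per-leaf
Monte Carlo standard errors come from the per-ray deposit variance.

The desk-scale default is $10^6$ rays — enough to resolve per-leaf
irradiance of a single plant to a few percent and each of this
vignette's checks in seconds. The estimator is unchanged at any budget;
results converge toward the multi-giga-ray regime simply by raising
`n_rays`.

Solar geometry (`solar_position()`) uses Spencer's Fourier series for
declination and the equation of time — accurate to a few hundredths of
a degree, and cross-checked in the tests against an independent
ecliptic-coordinate implementation at 0.5°.

# Whole-plant integration and chamber validation

`assign_layers()` orders leaves acropetally and groups them in fours
(the remainder joins the top layer), reproducing the eight physiological
layers used for the parameter profile; labels are the odd node indices
so they align with the per-layer tables. `plant_rate()` evaluates the
FvCB model per layer at the area-weighted mean absorbed irradiance and
sums $A_l \times$ area over layers. `simulate_day()` runs that chain per
30-minute weather step.

**Internal CO2 during validation.** The chamber protocol holds external
CO2 between 80 and 200 Pa (above saturation) but does not measure
$c_i$; the default rule is the conventional constant ratio
$c_i = 0.7\,c_a$ with $c_a$ the chamber setpoint (140 Pa default), and a
fixed-$c_i$ mode is available. This is the weakest link in the chain and
is deliberately prominent in the configuration.

`chamber_slope_to_rate()` inverts a 10-s CO2 log of a sealed 1 × 1 × 2 m
chamber at 25 °C: CO2 injections appear as rises above 2 Pa per sample
and are masked together with the refill ramp until decline resumes;
within each 30-min window the drawdown slope is estimated with a common
slope but a separate intercept per declining segment (an injection
shifts the level, not the slope), and converted through the ideal-gas
chamber content $n = PV/RT$ to µmol s⁻¹. Chamber leakage (0.2–0.3
µmol s⁻¹ under elevated CO2) can optionally be subtracted; the default
reports the raw drawdown rate, since whether leakage was removed from
the measured series is not recorded in the protocol.

# Synthetic data: what it does and does not emulate

The generators reproduce the measurement *protocols*: 20-point curves on
the printed grids, a half-sine 09:00–18:00 weather day (peak 1000
µmol m⁻² s⁻¹, diffuse fraction 0.3 by default), and the sawtooth chamber
log (trigger 100 Pa, refill toward 200 Pa with a 60-s first-order ramp
so that jump detection is actually exercised; injections are also
reported at ~80 Pa elsewhere in the protocol description — the 100 Pa
figure from the validation day is used). Measurement noise is Gaussian
on assimilation with σ = 0.5 µmol m⁻² s⁻¹, chosen to produce
replicate-level standard errors of the same order as the measured
profile's; chamber sensor noise is off by default.

They do **not** emulate: instrument drift or autocorrelated noise,
stomatal dynamics (no $c_i$ feedback — $c_i/c_a$ is fixed at 0.7),
leaf-age or nitrogen effects, imperfect chamber mixing, or real sky
radiance distributions. A passing closed loop therefore demonstrates
the internal consistency of the estimation chain — generation model,
ray tracer, fitting windows and integration agree — not field accuracy.
The chain's published field agreement (measured vs estimated R² 0.85,
RMSE 0.47 µmol s⁻¹) is not reproducible from tabulated data alone, since
the raw chamber and weather logs exist only as figures; the package
replaces that comparison with the property-based closed loop (truth vs
re-estimated R² ≥ 0.95 on a full synthetic day at 10⁶ rays per step),
and `goodness_of_fit()` itself is unit-tested on hand-computable
vectors.

# Numerical choices

* Quadratic roots (electron transport, NRH) use the
  $2c/(b+\sqrt{b^2-4ac})$ form to avoid cancellation at low irradiance;
  negative rounding noise under the radical is clamped to zero (the
  discriminant is analytically non-negative for $\theta \le 1$).
* Compensation points by bisection (`uniroot`) at 1e-9 Pa tolerance.
* Degenerate triangles are dropped at BVH build with a count reported on
  the interception map.
* Ray-surface intersection uses Möller–Trumbore with an epsilon scaled
  to the scene diagonal; re-emission offsets the origin along the
  outgoing side's normal.
* The light-curve optimizer reports `converged = FALSE` (never an
  exception) for degenerate data such as a constant curve.
* All randomness flows through explicit integer seeds: R-side draws use
  an isolated RNG stream that leaves the session RNG untouched, and the
  tracer's C++ streams are derived per ray.

# Problem sizes

The test suite and the reproduction script run at desk scale by design:
$10^6$ rays per trace for tracer physics and the end-to-end day
(19 half-hour steps, single plant), $2\times10^5$ rays for bookkeeping
and shadowing checks, 100 replicates for estimator-calibration checks,
and 9-hour 10-s chamber logs. These sizes resolve every tested quantity
well inside its tolerance; all of them are parameters, not limits.

# Known limitations

* No stomatal-conductance coupling; $c_i$ is prescribed, not solved.
* Fixed 25 °C; applying the chain across temperatures requires adding
  the standard Arrhenius/peaked response functions.
* No triose-phosphate-utilisation limitation (not part of this model
  variant).
* The diffuse sky is isotropic; overcast/clear-sky radiance models are
  out of scope.
* Greenhouse structural shading and chamber-wall optics are not
  modelled (chamber and glasshouse surfaces are treated as fully
  transparent).
* Leaf outlines, phyllotactic jitter and the stem lean angle are
  plausible defaults, not measurements; per-leaf interception detail
  beyond area and angle is outside what the structural table supports.
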