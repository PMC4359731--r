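---
title: "The lampswim model: mechanics, muscle, fluid and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The lampswim model: mechanics, muscle, fluid and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lampswim` simulates steady anguilliform swimming of a lamprey-like animal
and reproduces the experimental logic built on such simulators: sweep
tail-beat frequency and muscle activation strength, locate the
speed-maximizing combinations, fit the resulting speed maps, and close the
loop so that a single desired swimming speed drives the whole model.  This
vignette documents the model equations, the meaning and default of every
tunable parameter, the numerical choices, and what the calibration does
and does not pin down.

## The body

The body is a planar, inextensible, unshearable, viscoelastic rod of
length 0.21 m and mass 0.015 kg, of uniform density and neutral buoyancy,
discretized into `n_segments` (default 50) rigid links of equal length.
The height is a constant 0.0073 m with an elliptical cross-section; the
width profile rises smoothly from a rounded snout to its maximum of
0.0073 m in the gill region (arc position 0.1 body lengths by default) and
tapers to 0.0005 m at the tail tip.  The published outline the profile
imitates is not available as data, so the taper is parametric — a
`(1 - u^2)^p` law — and its one free exponent `p` is calibrated once, at
construction, so that the resting centre of mass falls in segment 18 of
50, the only printed geometric consequence of the true outline.  The
anterior `head_fraction` (default 0.12 BL, read off the extent of the
head-and-gills region in the source anatomy, and configurable) carries no
swimming muscle.

Generalized coordinates are the head endpoint and the 50 link angles, so
the inextensibility constraints hold exactly by construction and the
contour length is conserved to rounding.  The equations of motion are the
Euler-Lagrange equations of the chain; the hand-derived mass matrix and
Coriolis terms are verified in the test suite against an independent
numeric Euler-Lagrange oracle (complex-step velocities, Richardson finite
differences) on small chains.

Each joint carries a linear viscoelastic moment
`-k_b * dphi - c_b * d(dphi)/dt`.  A continuum bending stiffness EI maps
to `k_b = EI / segment_length`.  The defaults are the package's one-time
behavioural calibration (see below).

## The muscle

Each joint behind the head region bears two antagonist hemisegments that
span the neighbouring cross-bars.  With `wbar` the mean cross-bar
half-width at the joint, the muscle lengths are
`L = segment_length -/+ wbar * dphi`, which makes the moment arm and the
length kinematics mutually consistent (a virtual-work identity exercised
by the tests through the Euler-Lagrange oracle).

Force generation follows a Hill-type model driven by two-state calcium
kinetics with work-dependent deactivation (WDD):

* `dc/dt = k_on stim (1 - c) - k_off c - gamma c max(0, F_active v)` with
  `c` the bound-calcium (activation) level, confined to [0, 1] by the
  structure of the equation;
* `F_active = P0 c FL(L) FV(v)` with a Gaussian force-length curve
  (width `fl_width` in strain units) and a Hill force-velocity curve:
  hyperbolic from 1 at `v = 0` to 0 at `v_max` for shortening, and a
  C1-continuous saturating branch rising to `ecc_plateau` for
  lengthening;
* a parallel elastic component adds
  `F_pec = pec_gain P0 max(0, strain - pec_slack)^2` on a stretched
  hemisegment.  At the working strains of steady swimming (a few percent)
  it is slack; it engages at large bends and prevents the body from
  locking into high-curvature shapes where the force-length curve would
  leave both antagonists too weak to straighten the body.

`P0` scales with the local cross-section (`sigma_max * muscle_fraction *
width * height`), i.e. uniform muscle stress along the tapered body.

"Activation strength A%" is defined operationally: the stimulus amplitude
is the one at which sustained isometric stimulation would plateau at
`c = A/100`, hence at A% of the maximum tetanic isometric force.  From
the kinetics this gives `stim = (A/100) k_off / (k_on (1 - A/100))`, so
the percentage scale is exact by construction, not approximate.

The exact published equation set this muscle model abstracts (including
its constants) is in sources unavailable here, so all parameters are
configuration with documented defaults, chosen in calibration:
`sigma_max = 4e5 Pa` with `muscle_fraction = 0.4`, `k_on = 120 /s`,
`k_off = 60 /s` (burst-scale rise and relaxation fast enough to support
2-6 cycles/s), `v_max = 10 optimal lengths/s`, `a/P0 = 0.25`, eccentric
plateau 1.5, `fl_width = 0.45`, `gamma_wdd = 1e4 /J`, `pec_gain = 4`,
`pec_slack = 0.1`.  The WDD gain is set so that deactivation by
shortening work visibly accelerates the force fall in 4 Hz work loops
(see `work_loop()`), and the calcium rates keep that behaviour while
allowing force to develop within a 36%-duty burst at 6 cycles/s.  With
much slower kinetics (relaxation times of order 50 ms) the simulated
speed decreases monotonically with frequency at every activation level —
no speed-maximizing frequency exists in the swimming range — so the
kinetics are pinned by the requirement that the frequency-speed response
have an interior maximum, which is the central phenomenon the package
studies.

## The activation wave

The central pattern generator output is a square wave of stimulation per
hemisegment: duty fraction 0.36 of each cycle, alternating sides in exact
antiphase, travelling head-to-tail at one body length per cycle at every
frequency (the phase of a segment is `f t - s` with `s` its arc position
in body lengths).  The whole pattern is multiplied by a `tanh` ramp that
reaches 99% of maximum at 3 s, which suppresses the start-up transient
that otherwise excites slow lateral sloshing of the centre of mass at
higher frequencies.  The square-wave edges are smoothed over 0.5% of a
cycle (`edge` parameter): muscle depolarisation is not instantaneous, and
ideal discontinuities force the stiff integrator to restart at every
hemisegment switching time (about 170 per cycle) for no physical gain.
The duty measured at half maximum is exactly 0.36.

## The fluid

Resistive (Taylor) forces: each link feels a force density decomposed in
its own frame, a quadratic normal pressure drag
`-1/2 rho C_N h v_N |v_N|` on the projected span `h` (the constant body
height) and a tangential skin friction `-1/2 rho C_T P(s) v_T |v|` on the
local cross-section perimeter `P(s)`.  The density is integrated along
each link with 3-point Gauss quadrature, which both reduces the
discretization error of the resultant and supplies the spin torque of a
rotating link.  Defaults: `rho = 1000 kg/m^3`, `C_N = 1.0`, `C_T = 0.01`.
There is no ambient flow, no added mass, and no vortex shedding; these
are known limitations of the resistive approximation, which is accurate
for slender bodies in the planar motions simulated here.

## Integration and numerical choices

The coupled system (head position and velocity, 50 link angles and
angular velocities, 2 x 43 calcium states) is stiff: joint
viscoelasticity and fast muscle kinetics coexist with the slow swimming
dynamics.  It is integrated with the adaptive implicit BDF method of
`deSolve::vode` (`mf = 22`, internally generated full Jacobian), with the
right-hand side compiled in C++ and resolved by `deSolve` natively, and
tolerances `rtol = 1e-7`, `atol = 1e-9` by default.  Halving the
tolerances changes the steady speed by far less than the 0.05% contract
used in the tests.  Runs are bitwise reproducible for a fixed
configuration.

The simulation starts from rest: straight body along +x, still water,
fully relaxed muscle.  The steady-state analysis window is the final two
full cycles of the (default) 8-s run, which never begins before 5 s so
the ramp (99% at 3 s) has effectively finished.  A run is flagged
non-converged when the mean speed of the last two cycles differs by more
than 0.5% from the two before; sweep rows keep the flag rather than being
dropped.

Kinematic estimators:

* forward speed: centre-of-mass displacement along the mean heading over
  the steady window, divided by its duration (the exact time average of
  the projected COM velocity), in BL/s;
* tail-beat amplitude: half the per-cycle peak-to-peak lateral excursion
  of the tail tip about the mean path, averaged over steady cycles;
* curvature wave speed: joint curvature `kappa = dphi / segment_length`;
  upward zero crossings located by linear interpolation, chained
  head-to-tail into wave events, and crossing time regressed on arc
  position over the mid-body band `s` in [0.25, 0.9] (ends excluded as
  noisy; the band is configurable and reported).  `V_c = 1/slope`,
  averaged over events; the regression R^2 is the quality metric and
  values below 0.95 raise a "non-uniform wave" warning.  A standing wave
  has no single speed and is reported as such.
* per-segment work: the cycle integral of force times shortening rate,
  summed over the two hemisegments of each joint (the parallel elastic
  contribution is included: the attachments feel the total tension).

All estimators are validated on synthetically constructed travelling-wave
trajectories (`synthetic_wave_trajectory()`) where the true speed,
amplitude and wave speed are known exactly; they recover the construction
parameters to 1% at the default 200 samples per cycle.

## Calibration: what was fitted, and to what

The elastic and damping parameters of the body tissues are the only model
constants with no published value; the source tradition states only that
values in a wide range produce lamprey-like swimming.  `lampswim`
therefore fixes them by a one-time behavioural calibration
(`calibrate_passive()`), whose targets are the observed properties of
swimming lampreys, evaluated at the model's speed-maximizing operating
points (the closed-loop suite):

* mean curvature/activation wave-speed ratio within [0.65, 0.79]
  (the observed lamprey range is 0.72 +/- 0.07);
* tail-beat amplitude within [0.08, 0.18] BL;
* a stable backward-travelling curvature wave at every probed point
  (regression R^2 >= 0.95).

The calibrated defaults shipped in the package are
`k_b = 1.4e-3 N m/rad`, `c_b = 7e-6 N m s/rad`, `C_N = 1.0`, together
with the muscle defaults listed above.  With them the model swims at
0.6-1.8 BL/s across the exercised activation range, with a wave-speed
ratio near 0.75 and a tail-beat amplitude near 0.14 BL at the
speed-maximizing operating points of the mid and upper frequency range —
emergent consequences of the calibrated primitives, not fitted targets.
Two behaviours depart from the ideal: at the slowest frequencies the
speed-maximizing gait carries a somewhat larger amplitude and a higher
wave-speed ratio than at higher frequencies, and far above the
speed-maximizing activation (several-fold overdrive) at 2-3 cycles/s the
body enters a large-amplitude, nearly non-propulsive oscillation rather
than a gentle decline.  Both are discussed in the limitations below.

What passing the behavioural suite does *not* show: the model's absolute
force and stiffness scales are not validated against isolated-muscle or
tissue measurements (those data are not available here); the fluid model
omits vortex wake effects, so absolute speeds carry the systematic
uncertainty of resistive theory; and the calibration pins a ridge of
behaviour, not a unique parameter point — other (k_b, c_b, C_N)
combinations inside the search box may behave comparably.

## Experiment pipeline and problem sizes

`sweep_experiments()` runs the frequency x activation grid (default
frequencies 2-6 /s; activations log-spaced 0.1-20%).  At each activation
level with at least 4 swept frequencies, `optimal_frequency()` fits
`U = a f^2 + b f + c` and reports the interior maximum (refusing fits with
no interior maximum); `fit_speed_maps()` then fits the linear
`f*(U) = alpha U + beta` map and the log-quadratic activation map
`A(U) = exp(q2 U^2 + q1 U + q0)`, which is re-fitted from the package's
own sweep rather than carrying any published coefficients — the scheme,
not the numbers, is the contribution.  `closed_loop()` takes only a
desired speed, evaluates both maps and runs the full simulation at the
resulting operating point.

The shipped acceptance runs use 5 frequencies x 6 activation levels
(0.3, 0.68, 1.3, 2.6, 5.2 and 18%, spanning the exercised range with
extra density at the low end where the speed-maximizing ridge begins)
and a 5-speed closed-loop suite (0.6-1.8 BL/s), all at 100 output
samples per cycle; these sizes keep a full pipeline run near a quarter
hour on one CPU while leaving the quadratic fits over-determined.

## Known limitations

* Resistive fluid forces only; no wake, no added mass.  The wave-speed
  ratio is the quantity most plausibly sensitive to this simplification.
* Deep overdrive (activation many times the speed-maximizing level) at
  low frequency excites a large-amplitude flailing mode with near-unity
  wave-speed ratio and almost no net propulsion, where a gentler decline
  of speed with activation would be expected.  The parallel elastic
  component bounds the muscle strains in this regime but not the
  whole-body excursion; quadratic speed-frequency fits that include such
  points lose quality (R^2 around 0.9 instead of above 0.99), and maxima
  whose fitted vertex falls far outside the swept frequency range are
  excluded from the speed-map fits.
* The speed-maximizing ridge is compressed at its slow end: at 2 cycles/s
  the optimal gait swims near 1.1 BL/s, so the fitted speed maps do not
  extend down to 0.6 BL/s and closed-loop requests below about 1 BL/s
  extrapolate beyond the fitted range (they are refused unless
  explicitly permitted, and their speed error is reported as measured).
* Planar motion, constant height, no fins.
* The muscle model is a deliberately small abstraction (two-state
  kinetics, separable FL/FV, work-rate WDD, quadratic-toe parallel
  elasticity); it does not represent cross-bridge distortion, fatigue, or
  series (tendon) elasticity.
* The CPG is a fixed kinematic pattern; no reflex feedback modulates
  timing or intensity, consistent with the evidence that intersegmental
  timing needs no feedback.
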