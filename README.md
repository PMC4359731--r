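# lampswim

Neuro-musculo-mechanical simulation of lamprey swimming in R.

Anguilliform swimmers propel themselves with a wave of muscle activation
that travels head-to-tail faster than the resulting wave of body
curvature.  `lampswim` implements a self-propelled model of this system —
a planar, inextensible, viscoelastic multilink rod driven by Hill-type
muscle with calcium-kinetics activation and work-dependent deactivation,
stimulated by a central-pattern-generator square wave (36% duty,
alternating sides, one body length per cycle), and immersed in resistive
(Taylor) fluid forces — and the experimental programme built on it:

* simulate steady swimming at a prescribed tail-beat frequency `f`
  (2–6 s⁻¹) and muscle activation strength `A` (0.1–20% of maximum
  tetanic isometric force);
* measure forward speed `U` (BL/s), tail-beat amplitude, the
  curvature-wave speed `V_c`, the wave-speed ratio `R = V_c / V_a`
  (the activation wave travels at exactly `f` BL/s), and per-segment
  muscle work;
* sweep `f × A`, fit `U = a f² + b f + c` at each activation level, and
  extract each speed-maximizing pair `(f*, U*)`;
* fit the speed maps `f*(U) = α U + β` and `A*(U) = exp(q₂U² + q₁U + q₀)`;
* close the loop: a single desired speed is mapped to `(f, A)` and the
  full simulation runs at that operating point.  Along the
  speed-maximizing ridge the emergent wave-speed ratio sits in the
  0.7–0.8 neighbourhood of the value observed in swimming lampreys
  (0.72 ± 0.07), with a tail-beat amplitude near 0.14 BL over the mid
  and upper speed range; the slow end of the ridge is compressed
  relative to the animal (see the methods vignette's limitations).

The body is 21 cm, 15 g, of uniform density and neutral buoyancy, in 50
sections of constant 0.73 cm height, with a smooth width profile (maximum
0.73 cm at the gills, 0.05 cm at the tail) calibrated so the resting
centre of mass lies in segment 18.  The equations of motion are derived
in generalized coordinates (head position + link angles), compiled in
C++, and integrated with the adaptive implicit BDF solver of `deSolve`.

## A worked example

```r
library(lampswim)

cfg <- simulation_config(
  activation = activation_wave(frequency = 3, strength = 1))  # 3 s^-1, 1%
traj <- run_simulation(cfg)          # 8 simulated seconds from rest
summarize_kinematics(traj)
#> U = 1.379 BL/s, amplitude = 0.144 BL, wave ratio = 0.782 (R^2 0.961)
```

The animal accelerates from rest under the tanh-ramped activation
(99% of full drive at 3 s) and settles into steady swimming at about
1.4 body lengths per second.  Its forward velocity oscillates twice per
tail-beat cycle and its lateral velocity once, the tail tip sweeps about
0.14 BL to each side of the mean path, and the wave of lateral curvature
travels backward at 78% of the speed of the activation wave — the
hallmark mismatch of anguilliform swimming.

Per-segment work over one steady cycle (`segment_work()`) shows the
anguilliform division of labour; at 4 s⁻¹ and 0.6% activation the tail
region (arc position beyond 0.8 BL) does net negative work (-2.8e-7 J
per cycle: active muscle there is stretched and brakes the tail) while
the body total stays positive (+2.6e-4 J per cycle).

Closed-loop control from a fitted sweep:

```r
bm <- build_speed_maps(base_config = cfg)     # sweep + quadratic maxima
cl <- closed_loop(c(0.6, 1.2, 1.8), bm$maps, cfg)
cl[, c("U_desired", "frequency", "activation", "U_achieved")]
```

A command-line interface wrapping these functions is installed at
`inst/exec/lampswim` (subcommands `simulate`, `analyze`, `sweep`,
`fit-maps`, `closed-loop`, `calibrate`, `muscle-workloop`,
`export-csv`), reading YAML configurations (`load_config()`) and writing
CSV/JSON.

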