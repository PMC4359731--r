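#' Passive viscoelastic joint properties
#'
#' The rod obeys a linear constitutive relation at joint level: each joint
#' resists bending with moment `-k_b * dphi - c_b * d(dphi)/dt`.  A continuum
#' bending stiffness EI maps to `k_b = EI / segment_length`; the values
#' here are per joint of the reference 50-section discretization, and the
#' simulator holds the continuum EI fixed when the body is discretized
#' more finely, so the swimming kinematics are discretization-invariant.
#' The defaults
#' are the package's one-time calibration (see the methods vignette): they
#' were chosen so that closed-loop swimming shows a backward-travelling
#' curvature wave with speed ratio near 0.75 and tail-beat amplitude near
#' 0.13 BL, the behaviour observed in swimming lampreys.
#'
#' @param k_b Joint bending stiffness, N m per radian.
#' @param c_b Joint bending damping, N m s per radian.
#' @return An object of class `passive_properties`.
#' @export
passive_properties <- function(k_b = 1.4e-3, c_b = 7e-6) {
  stopifnot(k_b > 0, c_b >= 0)
  structure(list(k_b = k_b, c_b = c_b), class = "passive_properties")
}

#' Muscle model parameters
#'
#' Hill-type hemisegmental muscle: two-state calcium kinetics drive an
#' activation level `c` in \[0, 1\]; force is `P0 * c * FL(L) * FV(v)` with a
#' Gaussian force-length curve and a Hill force-velocity curve (hyperbolic
#' for shortening, saturating above 1 for lengthening).  Work-dependent
#' deactivation removes activation at a rate proportional to positive
#' shortening power, accelerating relaxation after the muscle has done work.
#'
#' @param sigma_max Maximum isometric tetanic muscle stress, Pa; per-joint
#'   `P0` is `sigma_max * muscle_fraction * width * height` at the joint.
#' @param muscle_fraction Fraction of the local cross-section that is
#'   swimming muscle (the remainder is notochord and skin).
#' @param k_on Calcium binding rate constant, 1/s.
#' @param k_off Calcium unbinding rate constant, 1/s.
#' @param fl_width Width (strain units) of the Gaussian force-length curve.
#' @param a_p0 Hill constant a/P0 of the shortening hyperbola.
#' @param v_max Maximum shortening velocity, optimal lengths per second.
#' @param ecc_plateau Saturating force factor for lengthening muscle
#'   (eccentric force enhancement), >= 1.
#' @param gamma_wdd Work-dependent deactivation gain, 1/J: extra
#'   deactivation rate per watt of positive shortening power.
#' @param pec_gain Parallel elastic component gain (dimensionless, in units
#'   of P0): passive tension of a stretched hemisegment is
#'   `pec_gain * P0 * (strain - pec_slack)^2` beyond the slack strain.
#' @param pec_slack Slack (toe) strain below which the parallel elastic
#'   component carries no tension.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(sigma_max = 4e5, muscle_fraction = 0.4,
                          k_on = 120, k_off = 60, fl_width = 0.45,
                          a_p0 = 0.25, v_max = 10, ecc_plateau = 1.5,
                          gamma_wdd = 1e4, pec_gain = 4,
                          pec_slack = 0.1) {
  stopifnot(sigma_max > 0, muscle_fraction > 0, muscle_fraction <= 1,
            k_on > 0, k_off > 0, fl_width > 0,
            a_p0 > 0, a_p0 < 1, v_max > 0, ecc_plateau >= 1,
            gamma_wdd >= 0, pec_gain >= 0, pec_slack >= 0)
  structure(list(sigma_max = sigma_max, muscle_fraction = muscle_fraction,
                 k_on = k_on, k_off = k_off, fl_width = fl_width,
                 a_p0 = a_p0, v_max = v_max, ecc_plateau = ecc_plateau,
                 gamma_wdd = gamma_wdd, pec_gain = pec_gain,
                 pec_slack = pec_slack),
            class = "muscle_params")
}

#' Central-pattern-generator activation wave
#'
#' Alternating left/right square waves of muscle stimulation travelling
#' head-to-tail at one body length per cycle at every frequency, occupying
#' 36% of each cycle on each side, multiplied by a tanh start-up ramp that
#' reaches 99% of maximum at 3 s.  `strength` is expressed as a percentage
#' of the maximum tetanic isometric force: the stimulus amplitude is scaled
#' so that sustained isometric stimulation would plateau at that percentage
#' of P0 (see [stim_amplitude()]).
#'
#' @param frequency Tail-beat / activation cycle frequency, cycles per
#'   second (the range exercised experimentally is 2-6).
#' @param strength Muscle activation strength, % of maximum tetanic
#'   isometric force (0.1-20 exercised).
#' @param duty Fraction of the cycle each hemisegment is stimulated.
#'   Must be < 0.5 so left and right bursts never overlap.
#' @param ramp_time Time (s) at which the start-up ramp reaches
#'   `ramp_level` of its maximum.
#' @param ramp_level Ramp value at `ramp_time` (fraction of maximum).
#' @param edge Smoothing width of the square-wave edges, as a fraction of a
#'   cycle (0 gives ideal discontinuous edges; the small default keeps the
#'   stiff integrator from restarting at every burst edge).
#' @param mirror Swap left and right stimulation patterns (for symmetry
#'   checks).
#' @return An object of class `activation_wave`.
#' @export
activation_wave <- function(frequency = 3, strength = 1, duty = 0.36,
                            ramp_time = 3, ramp_level = 0.99,
                            edge = 0.005, mirror = FALSE) {
  stopifnot(frequency > 0, strength >= 0, ramp_time > 0,
            ramp_level > 0, ramp_level < 1, edge >= 0, edge < 0.05)
  if (duty <= 0 || duty >= 0.5) {
    stop("duty must lie in (0, 0.5): left and right bursts of one ",
         "hemisegment must never overlap", call. = FALSE)
  }
  structure(list(frequency = frequency, strength = strength, duty = duty,
                 ramp_time = ramp_time, ramp_level = ramp_level,
                 edge = edge, mirror = mirror),
            class = "activation_wave")
}

#' Start-up ramp of the activation wave
#'
#' `ramp(t) = tanh(r t)` with `r` set so that `ramp(ramp_time) =
#' ramp_level` (by default 99% at 3 s).
#'
#' @param t Time(s), seconds.
#' @param wave An [activation_wave()].
#' @return Ramp value(s) in \[0, 1).
#' @export
activation_ramp <- function(t, wave = activation_wave()) {
  tanh(t * atanh(wave$ramp_level) / wave$ramp_time)
}

#' Stimulus amplitude for a given activation strength
#'
#' "Activation strength A%" means: sustained isometric stimulation at this
#' amplitude makes the bound-calcium level plateau at `c = A/100`, so the
#' isometric force at optimal length plateaus at A% of P0.  From the
#' two-state kinetics the plateau is `s k_on / (s k_on + k_off)`, giving
#' `s = (A/100) k_off / (k_on (1 - A/100))`.
#'
#' @param strength Activation strength, % of maximum tetanic isometric
#'   force; must be < 100.
#' @param muscle A [muscle_params()].
#' @return Dimensionless stimulus amplitude.
#' @export
stim_amplitude <- function(strength, muscle = muscle_params()) {
  stopifnot(strength >= 0, strength < 100)
  a <- strength / 100
  a * muscle$k_off / (muscle$k_on * (1 - a))
}

#' Taylor resistive fluid model parameters
#'
#' Local drag on each link from the normal and tangential components of its
#' velocity through still water: quadratic normal pressure drag on the
#' projected span (the constant body height) and skin friction on the local
#' cross-section perimeter.
#'
#' @param rho Water density, kg/m^3.
#' @param c_n Normal drag coefficient (dimensionless).
#' @param c_t Tangential (skin-friction) coefficient, much smaller than
#'   `c_n`.
#' @return An object of class `fluid_params`.
#' @export
fluid_params <- function(rho = 1000, c_n = 1.0, c_t = 0.01) {
  stopifnot(rho > 0, c_n > 0, c_t >= 0)
  structure(list(rho = rho, c_n = c_n, c_t = c_t), class = "fluid_params")
}
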