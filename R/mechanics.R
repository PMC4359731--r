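#' Moment at one joint
#'
#' Linear viscoelastic passive moment plus the antagonist muscle moment:
#' `M_i = -k_b dphi_i - c_b d(dphi_i)/dt + (F_L - F_R) w_i`, where
#' `dphi_i = phi_{i+1} - phi_i` and `w_i` is the local cross-bar half-width
#' (the muscle moment arm).  Muscle forces only pull (must be >= 0).
#'
#' @param dphi Joint angle difference, radians.
#' @param dphidot Rate of change of `dphi`, rad/s.
#' @param passive A [passive_properties()].
#' @param force_left,force_right Muscle forces on the two sides, N (>= 0).
#' @param w Cross-bar half-width at the joint, m.
#' @return Moment in N m.
#' @export
joint_moment <- function(dphi, dphidot, passive = passive_properties(),
                         force_left = 0, force_right = 0, w = 0) {
  stopifnot(all(force_left >= 0), all(force_right >= 0))
  -passive$k_b * dphi - passive$c_b * dphidot +
    (force_left - force_right) * w
}

# fraction of each joint's muscle span lying behind the muscle-free head
# region; fractional coverage at the boundary joint makes the total
# muscle converge quadratically under refinement
muscle_joint_coverage <- function(body) {
  n <- body$n
  hf <- body$plan$head_fraction
  j <- seq_len(n - 1)
  pmin(pmax(((j + 0.5) / n - hf) * n, 0), 1)
}

# indices (1-based) of muscle-bearing joints
muscle_joints <- function(body) {
  which(muscle_joint_coverage(body) > 0)
}

# assemble the C++ dynamics context
make_rod_context <- function(body, passive = passive_properties(),
                             muscle = muscle_params(),
                             wave = activation_wave(),
                             fluid = fluid_params(),
                             act_on = TRUE, fluid_on = TRUE) {
  n <- body$n
  plan <- body$plan
  jm <- muscle_joints(body)
  wbar <- (body$w[seq_len(n - 1)] + body$w[2:n]) / 2
  s_joint <- seq_len(n - 1) / n
  p0 <- muscle$sigma_max * muscle$muscle_fraction *
    (2 * wbar[jm]) * plan$height * muscle_joint_coverage(body)[jm]
  # cross-section perimeter at the 3 Gauss points of each link
  gx <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  s_g <- outer(body$s, gx / (2 * n), "+")
  perim_g <- matrix(ellipse_perimeter(width_profile(pmin(pmax(s_g, 0), 1),
                                                    plan) / 2,
                                      plan$height / 2),
                    nrow = n)
  # joint viscoelastic constants are specified for the reference
  # 50-section discretization; the continuum stiffness EI = k_b * ell_ref
  # is held fixed under refinement (k_b_joint = EI / ell), so the steady
  # kinematics are discretization-invariant
  ref_scale <- if (!is.null(body$ref_scale)) body$ref_scale
               else body$ell * 50 / plan$total_length
  rod_context(list(
    n = n, ell = body$ell, mass = body$mass, inertia = body$inertia,
    wbar = wbar, s_joint = s_joint, muscle_joints = jm - 1L,
    kb = passive$k_b / ref_scale, cb = passive$c_b / ref_scale,
    P0 = p0, k_on = muscle$k_on, k_off = muscle$k_off,
    gamma_wdd = muscle$gamma_wdd, fl_width = muscle$fl_width,
    a_p0 = muscle$a_p0, v_max = muscle$v_max,
    ecc_plateau = muscle$ecc_plateau,
    pec_gain = muscle$pec_gain, pec_slack = muscle$pec_slack,
    freq = wave$frequency, duty = wave$duty,
    stim_amp = stim_amplitude(wave$strength, muscle),
    ramp_rate = atanh(wave$ramp_level) / wave$ramp_time,
    edge = wave$edge, mirror = wave$mirror, act_on = act_on,
    rho = fluid$rho, c_n = fluid$c_n, c_t = fluid$c_t,
    height = plan$height, perim_g = perim_g, fluid_on = fluid_on))
}

#' Assemble a rod state vector
#'
#' @param body A [build_body()] result.
#' @param head Head endpoint position, length-2, m.
#' @param angles Link angles, radians (recycled to `n`).
#' @param head_velocity Head endpoint velocity, m/s.
#' @param angular_velocity Link angular velocities, rad/s (recycled).
#' @param c_left,c_right Initial bound-calcium levels of the muscle
#'   hemisegments (recycled).
#' @return Numeric state vector as used by [rod_derivative()].
#' @export
rod_state <- function(body, head = c(0, 0), angles = 0,
                      head_velocity = c(0, 0), angular_velocity = 0,
                      c_left = 0, c_right = 0) {
  n <- body$n
  nm <- length(muscle_joints(body))
  c(head, rep_len(angles, n), head_velocity,
    rep_len(angular_velocity, n), rep_len(c_left, nm),
    rep_len(c_right, nm))
}

#' Time derivative of the full rod + muscle state
#'
#' Evaluates the equations of motion of the constrained multilink rod
#' (generalized coordinates: head position and link angles, so the
#' inextensibility constraints are satisfied exactly) together with the
#' muscle calcium kinetics, under the given activation wave and fluid
#' model.  With fluid and activation disabled the formulation conserves
#' total linear momentum exactly.
#'
#' @param state State vector from [rod_state()].
#' @param body A [build_body()] result.
#' @param t Time, s.
#' @param passive,muscle,wave,fluid Parameter objects.
#' @param act_on,fluid_on Logical switches for the activation wave and the
#'   fluid forces.
#' @return The state time-derivative (numeric vector).
#' @export
rod_derivative <- function(state, body, t = 0,
                           passive = passive_properties(),
                           muscle = muscle_params(),
                           wave = activation_wave(),
                           fluid = fluid_params(),
                           act_on = TRUE, fluid_on = TRUE) {
  ctx <- make_rod_context(body, passive, muscle, wave, fluid,
                          act_on, fluid_on)
  rod_deriv(t, state, ctx)
}

# link centre positions for one state (or a matrix of link angle rows)
# head: length-2 or nt x 2; phi: length-n or nt x n
link_centres <- function(head, phi, ell) {
  if (is.null(dim(phi))) {
    phi <- matrix(phi, nrow = 1)
    head <- matrix(head, nrow = 1)
  }
  cphi <- cos(phi); sphi <- sin(phi)
  cumx <- ell * t(apply(cphi, 1, cumsum))
  cumy <- ell * t(apply(sphi, 1, cumsum))
  x <- head[, 1] + cumx - 0.5 * ell * cphi
  y <- head[, 2] + cumy - 0.5 * ell * sphi
  list(x = x, y = y)
}

# link centre velocities given head velocity and angular velocities
link_velocities <- function(headvel, phi, phidot, ell) {
  if (is.null(dim(phi))) {
    phi <- matrix(phi, nrow = 1); phidot <- matrix(phidot, nrow = 1)
    headvel <- matrix(headvel, nrow = 1)
  }
  ts <- sin(phi) * phidot; tc <- cos(phi) * phidot
  cums <- ell * t(apply(ts, 1, cumsum))
  cumc <- ell * t(apply(tc, 1, cumsum))
  vx <- headvel[, 1] - (cums - 0.5 * ell * ts)
  vy <- headvel[, 2] + (cumc - 0.5 * ell * tc)
  list(vx = vx, vy = vy)
}
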