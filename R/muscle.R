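#' Force-length curve
#'
#' Gaussian dependence of active force on muscle length, normalized to 1 at
#' the optimal length.
#'
#' @param length Muscle length, metres (vectorized).
#' @param l_opt Optimal length, metres.
#' @param muscle A [muscle_params()].
#' @return Dimensionless factor in (0, 1].
#' @export
force_length <- function(length, l_opt, muscle = muscle_params()) {
  z <- (length / l_opt - 1) / muscle$fl_width
  exp(-z^2)
}

#' Force-velocity curve
#'
#' Hill hyperbola for shortening (1 at zero velocity, 0 at `v_max`), and a
#' saturating eccentric branch for lengthening that rises continuously (C1
#' at v = 0) to the eccentric plateau.
#'
#' @param v Shortening velocity in optimal lengths per second (positive =
#'   shortening, negative = lengthening; vectorized).
#' @param muscle A [muscle_params()].
#' @return Dimensionless factor in \[0, ecc_plateau\].
#' @export
force_velocity <- function(v, muscle = muscle_params()) {
  vh <- v / muscle$v_max
  out <- numeric(length(vh))
  sh <- vh >= 0 & vh < 1
  out[sh] <- (1 - vh[sh]) / (1 + vh[sh] / muscle$a_p0)
  ec <- vh < 0
  u <- -vh[ec]
  ke <- (muscle$ecc_plateau - 1) * muscle$a_p0 / (muscle$a_p0 + 1)
  out[ec] <- 1 + (muscle$ecc_plateau - 1) * u / (ke + u)
  out
}

#' Instantaneous muscle force
#'
#' `F = P0 * c * FL(L) * FV(v)`, never negative.
#'
#' @param c Bound-calcium / activation level in \[0, 1\].
#' @param length Muscle length, metres.
#' @param v Shortening velocity, metres per second (positive = shortening).
#' @param p0 Maximum isometric tetanic force of this hemisegment, N.
#' @param l_opt Optimal length, metres.
#' @param muscle A [muscle_params()].
#' @return Force in newtons (vectorized).
#' @export
muscle_force <- function(c, length, v, p0, l_opt,
                         muscle = muscle_params()) {
  pmax(0, p0 * c * force_length(length, l_opt, muscle) *
         force_velocity(v / l_opt, muscle))
}

#' Passive tension of the parallel elastic component
#'
#' A stretched hemisegment resists elongation with a quadratic toe-region
#' spring that engages beyond the slack strain:
#' `F = pec_gain * P0 * max(0, L/L_opt - 1 - pec_slack)^2`.
#' Around the working strains of steady swimming (a few percent) it
#' carries no load; at large bends it pulls the body back, as muscle and
#' skin tissue do.
#'
#' @param length Muscle length, metres.
#' @param p0 Maximum isometric force of the hemisegment, N.
#' @param l_opt Optimal (rest) length, metres.
#' @param muscle A [muscle_params()].
#' @return Passive tension in newtons (vectorized).
#' @export
passive_muscle_force <- function(length, p0, l_opt,
                                 muscle = muscle_params()) {
  s <- pmax(0, length / l_opt - 1 - muscle$pec_slack)
  muscle$pec_gain * p0 * s^2
}

#' Time derivative of the bound-calcium level
#'
#' Two-state calcium kinetics with work-dependent deactivation:
#' `dc/dt = k_on stim (1 - c) - k_off c - gamma c max(0, F v)`.
#' The WDD term removes activation in proportion to positive shortening
#' power, and vanishes as `c -> 0`, so `c` stays in \[0, 1\] for any bounded
#' stimulus and motion.
#'
#' @param c Bound-calcium level in \[0, 1\].
#' @param stim Dimensionless stimulus drive (>= 0).
#' @param force Current muscle force, N.
#' @param v Shortening velocity, m/s (positive = shortening).
#' @param muscle A [muscle_params()].
#' @return dc/dt, 1/s.
#' @export
muscle_state_derivative <- function(c, stim, force, v,
                                    muscle = muscle_params()) {
  muscle$k_on * stim * (1 - c) - muscle$k_off * c -
    muscle$gamma_wdd * c * pmax(0, force * v)
}

#' Isometric work-loop / step-response oracle
#'
#' Closed-form solution of the calcium kinetics under constant stimulus and
#' isometric conditions (no WDD): `c(t)` relaxes exponentially to
#' `stim k_on / (stim k_on + k_off)` with rate `stim k_on + k_off`.
#'
#' @param t Time(s), s.
#' @param stim Constant stimulus drive.
#' @param c0 Initial level.
#' @param muscle A [muscle_params()].
#' @return `c(t)`.
#' @export
isometric_activation <- function(t, stim, c0 = 0,
                                 muscle = muscle_params()) {
  r <- stim * muscle$k_on + muscle$k_off
  cinf <- stim * muscle$k_on / r
  cinf + (c0 - cinf) * exp(-r * t)
}

#' Simulated work loop of an isolated muscle segment
#'
#' Imposes a sinusoidal length change `L(t) = l_opt (1 + eps sin(2 pi f t))`
#' and a phased square-wave stimulus on a single hemisegment, integrates the
#' calcium kinetics (including work-dependent deactivation), and reports the
#' net work per cycle, the integral of force times shortening (positive when
#' the muscle does work on its attachments).
#'
#' @param frequency Movement frequency, cycles/s.
#' @param strength Activation strength, % of maximum isometric force.
#' @param strain Length-change amplitude `eps` (fraction of optimal length).
#' @param stim_phase Cycle fraction at which the stimulus burst starts
#'   (0 = the moment the muscle starts shortening from maximum length,
#'   i.e. the peak of `sin` is at phase 0.25; shortening occupies phases
#'   0.25-0.75 of `sin(2 pi f t)`... the burst start is relative to `t = 0`).
#' @param duty Stimulus duty fraction.
#' @param n_cycles Number of cycles to simulate (the first are discarded as
#'   transient; at least 5 settled cycles are required).
#' @param p0 Maximum isometric force, N.
#' @param l_opt Optimal length, m.
#' @param muscle A [muscle_params()].
#' @param samples_per_cycle Output sampling density.
#' @return A list with `work` (net work per settled cycle, J), `settled`
#'   (logical: cycle-to-cycle variation < 1%), and the sampled time series
#'   (`t`, `length`, `force`, `stim`, `c`).  A warning is raised when the
#'   loop has not settled.
#' @export
work_loop <- function(frequency = 4, strength = 10, strain = 0.05,
                      stim_phase = 0.25, duty = 0.36, n_cycles = 8,
                      p0 = 1, l_opt = 0.01, muscle = muscle_params(),
                      samples_per_cycle = 400) {
  stopifnot(n_cycles >= 6)
  amp <- stim_amplitude(strength, muscle)
  period <- 1 / frequency
  len <- function(t) l_opt * (1 + strain * sin(2 * pi * frequency * t))
  vel <- function(t) -l_opt * strain * 2 * pi * frequency *
    cos(2 * pi * frequency * t)          # shortening rate, +ve shortening
  stim_f <- function(t) {
    amp * square_pulse((frequency * t - stim_phase) %% 1, duty, 0.002)
  }
  deriv <- function(t, y, parms) {
    cc <- min(max(y[1], 0), 1)
    f <- muscle_force(cc, len(t), vel(t), p0, l_opt, muscle)
    list(muscle_state_derivative(cc, stim_f(t), f, vel(t), muscle))
  }
  times <- seq(0, n_cycles * period, by = period / samples_per_cycle)
  sol <- deSolve::lsoda(c(c = 0), times, deriv, parms = NULL,
                        rtol = 1e-9, atol = 1e-11)
  cc <- pmin(pmax(sol[, 2], 0), 1)
  tt <- sol[, 1]
  ll <- len(tt); vv <- vel(tt)
  ff <- muscle_force(cc, ll, vv, p0, l_opt, muscle)
  per_cycle <- vapply(seq_len(n_cycles), function(k) {
    idx <- which(tt >= (k - 1) * period & tt <= k * period)
    # net work done by the muscle: int F (-dL) = int F v dt, v = shortening
    trapz(tt[idx], ff[idx] * vv[idx])
  }, numeric(1))
  settled_cycles <- per_cycle[max(2, n_cycles - 4):n_cycles]
  spread <- diff(range(settled_cycles))
  scale <- max(abs(settled_cycles), 1e-12)
  settled <- spread / scale < 0.01
  if (!settled) {
    warning("work loop has not settled: cycle-to-cycle net work varies by ",
            signif(100 * spread / scale, 3), "%", call. = FALSE)
  }
  list(work = per_cycle[n_cycles], per_cycle = per_cycle, settled = settled,
       t = tt, length = ll, force = ff, c = cc,
       stim = stim_f(tt), velocity = vv)
}

# trapezoidal rule
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
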