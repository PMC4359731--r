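#' Full simulation configuration
#'
#' Bundles every parameter group of the model plus integration settings.
#' An experiment is typically 8 simulated seconds of activation at a
#' prescribed cycle frequency and muscle activation strength, from rest
#' (straight body, still water, relaxed muscle).
#'
#' @param plan A [body_plan()].
#' @param passive A [passive_properties()].
#' @param muscle A [muscle_params()].
#' @param activation An [activation_wave()].
#' @param fluid A [fluid_params()].
#' @param duration Simulated time, s (at least 2 activation cycles).
#' @param samples_per_cycle Output samples per activation cycle (>= 50,
#'   needed by the wave-speed estimator).
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param seed Reserved; the core model is deterministic and ignores it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(plan = body_plan(),
                              passive = passive_properties(),
                              muscle = muscle_params(),
                              activation = activation_wave(),
                              fluid = fluid_params(),
                              duration = 8, samples_per_cycle = 200,
                              rtol = 1e-7, atol = 1e-9, seed = NULL) {
  stopifnot(inherits(plan, "body_plan"),
            inherits(passive, "passive_properties"),
            inherits(muscle, "muscle_params"),
            inherits(activation, "activation_wave"),
            inherits(fluid, "fluid_params"),
            rtol > 0, atol > 0)
  if (duration < 2 / activation$frequency) {
    stop("duration must cover at least 2 activation cycles", call. = FALSE)
  }
  if (samples_per_cycle < 50) {
    stop("samples_per_cycle must be >= 50 (wave-speed estimation needs ",
         "sub-cycle resolution)", call. = FALSE)
  }
  structure(list(plan = plan, passive = passive, muscle = muscle,
                 activation = activation, fluid = fluid,
                 duration = duration,
                 samples_per_cycle = as.integer(samples_per_cycle),
                 rtol = rtol, atol = atol, seed = seed),
            class = "simulation_config")
}

#' Run a swimming simulation
#'
#' Integrates the coupled rod + muscle system with the stiff adaptive
#' solver ([deSolve::lsoda]) from rest: straight body along +x, zero
#' velocities, fully relaxed muscle.  The result is a uniformly sampled
#' trajectory carrying the rod state, muscle state, stimulation and forces
#' at every sample, plus the steady-state analysis window (the final two
#' full cycles, starting no earlier than 5 s so the start-up ramp has
#' essentially finished).
#'
#' @param config A [simulation_config()].
#' @param act_on,fluid_on Logical switches (disable activation and/or fluid
#'   forces for diagnostic runs).
#' @param initial_state Optional full state vector overriding the rest
#'   start (see [rod_state()]).
#' @return An object of class `swim_trajectory`.
#' @export
run_simulation <- function(config, act_on = TRUE, fluid_on = TRUE,
                           initial_state = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  body <- build_body(config$plan)
  wave <- config$activation
  ctx <- make_rod_context(body, config$passive, config$muscle, wave,
                          config$fluid, act_on = act_on,
                          fluid_on = fluid_on)
  n <- body$n
  jm <- muscle_joints(body)
  nm <- length(jm)
  y0 <- if (is.null(initial_state)) rod_state(body) else initial_state
  stopifnot(length(y0) == 2 * (n + 2) + 2 * nm)

  dt <- 1 / (wave$frequency * config$samples_per_cycle)
  times <- seq(0, config$duration, by = dt)
  rod_use_context(ctx)
  sol <- suppressWarnings(
    deSolve::vode(y0, times, func = "rod_deriv_native",
                  dllname = "lampswim", initfunc = NULL, parms = NULL,
                  rtol = config$rtol, atol = config$atol,
                  mf = 22, maxsteps = 100000))
  istate <- attr(sol, "istate")
  bad <- !all(is.finite(sol)) || nrow(sol) < length(times)
  if (bad || (!is.null(istate) && istate[1] < 0)) {
    tfail <- if (nrow(sol) > 0) sol[nrow(sol), 1] else 0
    last <- sol[max(1, nrow(sol)), -1]
    phi <- last[3:(n + 2)]
    stop("solver failed at t = ", signif(tfail, 4), " s (max joint angle ",
         signif(max(abs(diff(phi)), na.rm = TRUE), 3),
         " rad); parameters may be unstable", call. = FALSE)
  }

  tt <- sol[, 1]
  nt <- length(tt)
  head <- sol[, 2:3, drop = FALSE]
  phi <- sol[, 4:(n + 3), drop = FALSE]
  headvel <- sol[, (n + 4):(n + 5), drop = FALSE]
  phidot <- sol[, (n + 6):(2 * n + 5), drop = FALSE]
  cL <- cR <- stimL <- stimR <- forceL <- forceR <- NULL
  if (nm > 0) {
    cL <- sol[, (2 * n + 6):(2 * n + 5 + nm), drop = FALSE]
    cR <- sol[, (2 * n + 6 + nm):(2 * n + 5 + 2 * nm), drop = FALSE]
  }

  pos <- link_centres(head, phi, body$ell)
  vel <- link_velocities(headvel, phi, phidot, body$ell)
  mfrac <- body$mass / sum(body$mass)
  com <- cbind(pos$x %*% mfrac, pos$y %*% mfrac)
  vcom <- cbind(vel$vx %*% mfrac, vel$vy %*% mfrac)
  tip <- cbind(head[, 1] + body$ell * rowSums(cos(phi)),
               head[, 2] + body$ell * rowSums(sin(phi)))
  # contour length measured from the link endpoint positions (the
  # generalized coordinates keep it exact up to rounding)
  ex <- body$ell * cos(phi); ey <- body$ell * sin(phi)
  contour <- rowSums(sqrt(ex^2 + ey^2))

  # per-sample forces and stimulation from the model itself
  stimL <- stimR <- forceL <- forceR <- velL <- velR <-
    lenL <- lenR <- matrix(0, nt, nm)
  fluid_fx <- fluid_fy <- matrix(0, nt, n)
  for (i in seq_len(nt)) {
    sn <- rod_snapshot(tt[i], sol[i, -1], ctx)
    stimL[i, ] <- sn$stim_l;  stimR[i, ] <- sn$stim_r
    forceL[i, ] <- sn$force_l; forceR[i, ] <- sn$force_r
    velL[i, ] <- sn$vel_l;    velR[i, ] <- sn$vel_r
    lenL[i, ] <- sn$len_l;    lenR[i, ] <- sn$len_r
    fluid_fx[i, ] <- sn$fluid_fx; fluid_fy[i, ] <- sn$fluid_fy
  }

  period <- 1 / wave$frequency
  t_end <- tt[nt]
  win_start <- t_end - 2 * period
  steady_reached <- win_start >= min(5, 0.99 * t_end)
  idx <- which(tt >= win_start - 1e-9)
  prev <- which(tt >= win_start - 2 * period - 1e-9 & tt < win_start - 1e-9)
  speed <- sqrt(vcom[, 1]^2 + vcom[, 2]^2)
  converged <- NA
  if (length(prev) > 10) {
    m1 <- mean(speed[idx]); m0 <- mean(speed[prev])
    converged <- abs(m1 - m0) < 0.005 * max(m1, 1e-12)
  }

  structure(list(
    time = tt, dt = dt, head = head, phi = phi, headvel = headvel,
    phidot = phidot, x = pos$x, y = pos$y, vx = vel$vx, vy = vel$vy,
    com = com, vcom = vcom, tip = tip, contour_length = contour,
    c_left = cL, c_right = cR, stim_left = stimL, stim_right = stimR,
    force_left = forceL, force_right = forceR,
    vel_left = velL, vel_right = velR, len_left = lenL, len_right = lenR,
    fluid_fx = fluid_fx, fluid_fy = fluid_fy,
    body = body, config = config, muscle_joints = jm,
    steady = list(index = idx, t_start = win_start, t_end = t_end,
                  reached = steady_reached),
    converged = converged),
    class = "swim_trajectory")
}

#' @export
print.swim_trajectory <- function(x, ...) {
  f <- x$config$activation$frequency
  cat("<swim_trajectory> ", signif(x$time[length(x$time)], 4), " s at f = ",
      f, " /s, A = ", x$config$activation$strength, "%, ",
      x$body$n, " sections; converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Save / load a trajectory
#'
#' Trajectories are large array bundles; they are stored as serialized R
#' objects with the full configuration embedded.  Use
#' [export_midlines()] for a text (CSV) interchange format.
#'
#' @param traj A `swim_trajectory`.
#' @param path File path.
#' @return `read_trajectory` returns the `swim_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "swim_trajectory"))
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- readRDS(path)
  stopifnot(inherits(traj, "swim_trajectory"))
  traj
}
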