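#' Mean forward swimming speed
#'
#' Projects the centre-of-mass motion onto the mean heading (the direction
#' of total COM displacement over the steady-state window).  The reported
#' speed is the exact time average over the window -- displacement along
#' the heading divided by window duration -- in body lengths per second.
#' A sliding half-cycle average of the projected COM velocity is returned
#' alongside, as plotted in typical speed-versus-time records.
#'
#' @param traj A [run_simulation()] trajectory.
#' @return A list: `U` (BL/s), `series` (half-cycle-averaged projected
#'   velocity, BL/s, full time base), `heading` (unit vector).
#' @export
forward_speed <- function(traj) {
  win <- steady_window(traj)
  h <- mean_heading(traj, win)
  L <- traj$body$plan$total_length
  u <- (traj$vcom[, 1] * h[1] + traj$vcom[, 2] * h[2]) / L
  k <- max(3L, round(traj$config$samples_per_cycle / 2))
  series <- as.numeric(stats::filter(u, rep(1 / k, k), sides = 2))
  d <- traj$com[win[length(win)], ] - traj$com[win[1], ]
  dt <- traj$time[win[length(win)]] - traj$time[win[1]]
  U <- sum(d * h) / (dt * L)
  list(U = U, series = series, heading = h)
}

#' Tail-beat amplitude
#'
#' Half the peak-to-peak lateral excursion of the tail tip about the mean
#' swimming path, averaged over the steady cycles, in body lengths.
#'
#' @param traj A trajectory.
#' @return Amplitude in BL.
#' @export
tail_amplitude <- function(traj) {
  win <- steady_window(traj)
  h <- mean_heading(traj, win)
  nv <- c(-h[2], h[1])
  L <- traj$body$plan$total_length
  cbar <- colMeans(traj$com[win, , drop = FALSE])
  lat <- ((traj$tip[win, 1] - cbar[1]) * nv[1] +
          (traj$tip[win, 2] - cbar[2]) * nv[2]) / L
  spc <- traj$config$samples_per_cycle
  ncyc <- max(1L, floor(length(win) / spc))
  amps <- vapply(seq_len(ncyc), function(k) {
    seg <- lat[((k - 1) * spc + 1):min(k * spc, length(lat))]
    (max(seg) - min(seg)) / 2
  }, numeric(1))
  mean(amps)
}

#' Speed of the backward-travelling curvature wave
#'
#' Joint curvature is `kappa_i = dphi_i / segment_length`.  For each joint
#' in the mid-body analysis band the upward zero-crossing times of the
#' (mean-removed) curvature are located by linear interpolation; crossing
#' events are chained head-to-tail and crossing time is regressed on arc
#' position for each event.  The wave speed is `1/slope` (BL/s), averaged
#' over the events in the steady window; the regression R-squared is
#' reported as a quality metric and a warning is raised below 0.95
#' ("non-uniform wave").
#'
#' @param traj A trajectory.
#' @param band Arc-position band (BL) of joints used in the regression;
#'   the passive head region and the last tail joint are excluded by the
#'   default.
#' @return A list: `V_c` (BL/s), `r_squared` (mean across events),
#'   `n_events`, and per-event slopes.
#' @export
curvature_wave_speed <- function(traj, band = c(0.25, 0.9)) {
  win <- steady_window(traj)
  n <- traj$body$n
  s_joint <- seq_len(n - 1) / n
  jb <- which(s_joint >= band[1] & s_joint <= band[2] &
                seq_len(n - 1) < n - 1)
  if (length(jb) < 4) stop("analysis band contains fewer than 4 joints",
                           call. = FALSE)
  tt <- traj$time[win]
  kap <- traj$phi[win, jb + 1, drop = FALSE] -
         traj$phi[win, jb, drop = FALSE]
  kap <- sweep(kap, 2, colMeans(kap))
  crossings <- lapply(seq_along(jb), function(j) {
    z <- kap[, j]
    i <- which(z[-length(z)] < 0 & z[-1] >= 0)
    tt[i] + (tt[i + 1] - tt[i]) * (-z[i]) / (z[i + 1] - z[i])
  })
  if (any(lengths(crossings) == 0)) {
    warning("non-uniform wave: some joints show no curvature zero crossing",
            call. = FALSE)
    return(list(V_c = NA_real_, r_squared = NA_real_, n_events = 0L,
                slopes = numeric(0)))
  }
  # chain each event backward along the body: at each joint take the first
  # crossing not earlier than at the previous joint
  first <- crossings[[1]]
  events <- list()
  for (t0 in first) {
    tev <- numeric(length(jb)); tev[1] <- t0; ok <- TRUE
    for (j in seq_along(jb)[-1]) {
      cand <- crossings[[j]][crossings[[j]] >= tev[j - 1] - 1e-9]
      if (length(cand) == 0) { ok <- FALSE; break }
      tev[j] <- cand[1]
    }
    if (ok) events[[length(events) + 1]] <- tev
  }
  if (length(events) == 0) {
    warning("non-uniform wave: no complete crossing event in the window",
            call. = FALSE)
    return(list(V_c = NA_real_, r_squared = NA_real_, n_events = 0L,
                slopes = numeric(0)))
  }
  s <- s_joint[jb]
  fits <- vapply(events, function(tev) {
    f <- stats::lm.fit(cbind(1, s), tev)
    slope <- f$coefficients[2]
    r2 <- 1 - sum(f$residuals^2) / sum((tev - mean(tev))^2)
    c(slope, r2)
  }, numeric(2))
  slopes <- fits[1, ]; r2 <- fits[2, ]
  good <- slopes > 0
  if (!any(good)) {
    warning("non-uniform wave: no backward-travelling crossing event",
            call. = FALSE)
    return(list(V_c = NA_real_, r_squared = mean(r2), n_events = 0L,
                slopes = slopes))
  }
  r2m <- mean(r2[good])
  if (is.finite(r2m) && r2m < 0.95) {
    warning("non-uniform wave: space-time regression R^2 = ",
            signif(r2m, 3), call. = FALSE)
  }
  list(V_c = mean(1 / slopes[good]), r_squared = r2m,
       n_events = sum(good), slopes = slopes)
}

#' Ratio of curvature to activation wave speed
#'
#' The activation wave travels at exactly one body length per cycle, so its
#' speed in BL/s equals the cycle frequency; the ratio is
#' `V_c / frequency`.
#'
#' @inheritParams curvature_wave_speed
#' @return A list: `ratio`, `V_c`, `V_a`, `r_squared`.
#' @export
wave_ratio <- function(traj, band = c(0.25, 0.9)) {
  cw <- curvature_wave_speed(traj, band)
  f <- traj$config$activation$frequency
  list(ratio = cw$V_c / f, V_c = cw$V_c, V_a = f,
       r_squared = cw$r_squared)
}

#' Net muscle work per segment over one cycle
#'
#' For each muscle-bearing joint, the net work done by the two hemisegments
#' over the final full steady cycle: the time integral of force times
#' shortening velocity, summed over sides.  Negative values mean work is
#' done on the muscle by the rest of the body and the water.
#'
#' @param traj A trajectory.
#' @return A data frame with `joint` (index), `s` (arc position, BL) and
#'   `work` (J).
#' @export
segment_work <- function(traj) {
  f <- traj$config$activation$frequency
  t_end <- traj$time[length(traj$time)]
  idx <- which(traj$time >= t_end - 1 / f - 1e-9)
  tt <- traj$time[idx]
  w <- vapply(seq_along(traj$muscle_joints), function(k) {
    trapz(tt, traj$force_left[idx, k] * traj$vel_left[idx, k]) +
      trapz(tt, traj$force_right[idx, k] * traj$vel_right[idx, k])
  }, numeric(1))
  data.frame(joint = traj$muscle_joints,
             s = traj$muscle_joints / traj$body$n, work = w)
}

#' Kinematic summary of a trajectory
#'
#' @param traj A trajectory.
#' @param band Analysis band for the wave-speed regression.
#' @return An object of class `kinematics_summary`: mean forward speed `U`
#'   (BL/s), `amplitude` (BL), curvature wave speed `V_c` and activation
#'   wave speed `V_a` (BL/s), their `ratio`, regression `r_squared`, total
#'   muscle `work` per cycle (J), and the trajectory's `converged` flag.
#' @export
summarize_kinematics <- function(traj, band = c(0.25, 0.9)) {
  fs <- forward_speed(traj)
  wr <- wave_ratio(traj, band)
  wk <- segment_work(traj)
  structure(list(U = fs$U, amplitude = tail_amplitude(traj),
                 V_c = wr$V_c, V_a = wr$V_a, ratio = wr$ratio,
                 r_squared = wr$r_squared, work = sum(wk$work),
                 converged = isTRUE(traj$converged)),
            class = "kinematics_summary")
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat("U = ", signif(x$U, 4), " BL/s, amplitude = ",
      signif(x$amplitude, 3), " BL, wave ratio = ", signif(x$ratio, 3),
      " (R^2 ", signif(x$r_squared, 3), ")\n", sep = "")
  invisible(x)
}

steady_window <- function(traj) {
  if (!isTRUE(traj$steady$reached)) {
    warning("trajectory may not be in steady state; values reflect the ",
            "final two cycles anyway", call. = FALSE)
  }
  traj$steady$index
}

mean_heading <- function(traj, win) {
  d <- traj$com[win[length(win)], ] - traj$com[win[1], ]
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) c(1, 0) else d / nrm
}

#' Synthetic travelling-wave trajectory
#'
#' Constructs a trajectory with prescribed kinematics -- a curvature wave
#' `kappa(s, t) = kappa0 sin(2 pi (f t - s / lambda))`, a rigid forward COM
#' drift and a sinusoidal tail tip -- for validating the kinematic
#' estimators against known construction parameters.  No dynamics are
#' involved.
#'
#' @param frequency Wave frequency, cycles/s.
#' @param wavelength Curvature wavelength, BL (wave speed is
#'   `frequency * wavelength` BL/s).
#' @param speed Forward COM speed, BL/s.
#' @param amplitude Tail-tip lateral amplitude, BL.
#' @param kappa0 Curvature amplitude, 1/m.
#' @param duration Simulated record length, s.
#' @param samples_per_cycle Samples per cycle.
#' @param plan Body plan used for the discretization.
#' @param standing If `TRUE`, build a standing wave
#'   `kappa = kappa0 sin(2 pi f t) sin(2 pi s)` instead (degenerate case
#'   with no single travelling speed).
#' @return A `swim_trajectory`-compatible object.
#' @export
synthetic_wave_trajectory <- function(frequency = 4, wavelength = 0.8,
                                      speed = 1, amplitude = 0.1,
                                      kappa0 = 20, duration = 2,
                                      samples_per_cycle = 200,
                                      plan = body_plan(),
                                      standing = FALSE) {
  body <- build_body(plan)
  n <- body$n
  L <- plan$total_length
  dt <- 1 / (frequency * samples_per_cycle)
  tt <- seq(0, duration, by = dt)
  nt <- length(tt)
  s_joint <- seq_len(n - 1) / n
  kap <- if (standing) {
    outer(sin(2 * pi * frequency * tt), sin(2 * pi * s_joint)) * kappa0
  } else {
    kappa0 * sin(2 * pi * outer(frequency * tt, s_joint / wavelength, "-"))
  }
  phi <- cbind(0, t(apply(kap * body$ell, 1, cumsum)))
  com <- cbind(speed * L * tt, 0)
  vcom <- cbind(rep(speed * L, nt), 0)
  tip <- cbind(speed * L * tt + L,
               amplitude * L * sin(2 * pi * frequency * tt))
  cfg <- simulation_config(plan = plan,
                           activation = activation_wave(
                             frequency = frequency),
                           duration = duration,
                           samples_per_cycle = samples_per_cycle)
  jm <- muscle_joints(body)
  zeros <- matrix(0, nt, length(jm))
  win <- which(tt >= tt[nt] - 2 / frequency - 1e-9)
  structure(list(
    time = tt, dt = dt, head = com, phi = phi,
    headvel = vcom, phidot = matrix(0, nt, n),
    x = NULL, y = NULL, vx = NULL, vy = NULL,
    com = com, vcom = vcom, tip = tip,
    contour_length = rep(L, nt),
    c_left = zeros, c_right = zeros, stim_left = zeros,
    stim_right = zeros, force_left = zeros, force_right = zeros,
    vel_left = zeros, vel_right = zeros,
    len_left = zeros, len_right = zeros,
    fluid_fx = matrix(0, nt, n), fluid_fy = matrix(0, nt, n),
    body = body, config = cfg, muscle_joints = jm,
    steady = list(index = win, t_start = tt[win[1]], t_end = tt[nt],
                  reached = TRUE),
    converged = TRUE),
    class = "swim_trajectory")
}
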