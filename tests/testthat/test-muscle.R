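test_that("isometric calcium kinetics match the closed-form solution", {
  mp <- muscle_params()
  for (stim in c(0.05, 0.4)) {
    ode <- deSolve::lsoda(c(c = 0), seq(0, 0.5, 0.01),
                          function(t, y, p) {
                            list(muscle_state_derivative(y, stim, 0, 0, mp))
                          }, parms = NULL, rtol = 1e-11, atol = 1e-13)
    expect_equal(ode[, 2], isometric_activation(ode[, 1], stim, 0, mp),
                 tolerance = 1e-8)
  }
  # fully relaxed with no stimulus is a fixed point
  expect_identical(muscle_state_derivative(0, 0, 0, 0, mp), 0)
})

test_that("activation strength maps to the isometric plateau fraction", {
  mp <- muscle_params()
  for (a in c(0.1, 1, 20)) {
    s <- stim_amplitude(a, mp)
    plateau <- s * mp$k_on / (s * mp$k_on + mp$k_off)
    expect_equal(plateau, a / 100, tolerance = 1e-12)
  }
})

test_that("force endpoints follow the Hill model structure", {
  mp <- muscle_params()
  l0 <- 0.01
  expect_equal(muscle_force(1, l0, 0, 2.5, l0, mp), 2.5)       # P0
  expect_equal(muscle_force(0, 0.8 * l0, 0.3, 2.5, l0, mp), 0) # no Ca
  expect_equal(muscle_force(1, l0, mp$v_max * l0, 2.5, l0, mp), 0)
  expect_equal(force_length(l0, l0, mp), 1)
  expect_equal(force_velocity(0, mp), 1)
  # C1 continuity at zero velocity
  expect_equal(force_velocity(1e-9, mp), 1, tolerance = 1e-6)
  expect_equal(force_velocity(-1e-9, mp), 1, tolerance = 1e-6)
  slope_sh <- (force_velocity(1e-6, mp) - 1) / (1e-6 / mp$v_max)
  slope_ec <- (force_velocity(-1e-6, mp) - 1) / (-1e-6 / mp$v_max)
  expect_equal(slope_sh, slope_ec, tolerance = 1e-4)
  # eccentric plateau saturates
  expect_equal(force_velocity(-100 * mp$v_max, mp), mp$ecc_plateau,
               tolerance = 1e-2)
  expect_true(all(force_velocity(seq(-10, 10, 0.01), mp) >= 0))
})

test_that("work loops are positive for shortening-phase stimulation and negative for lengthening", {
  pos <- work_loop(stim_phase = 0.25, n_cycles = 8)
  expect_gt(pos$work, 0)
  expect_true(pos$settled)
  neg <- work_loop(stim_phase = 0.75, n_cycles = 8)
  expect_lt(neg$work, 0)
  expect_true(all(pos$c >= 0 & pos$c <= 1))
})

test_that("work-dependent deactivation lowers force after shortening work", {
  mp0 <- muscle_params(gamma_wdd = 0)
  mp1 <- muscle_params(gamma_wdd = 2000)
  w0 <- work_loop(stim_phase = 0.25, strength = 50, p0 = 5,
                  muscle = mp0, n_cycles = 8)
  w1 <- work_loop(stim_phase = 0.25, strength = 50, p0 = 5,
                  muscle = mp1, n_cycles = 8)
  # after the burst has done shortening work, the WDD muscle has shed
  # more activation, so its force falls faster and stays strictly lower
  period <- 1 / 4
  late <- w0$t > max(w0$t) - 0.5 * period
  expect_lt(max(w1$force[late]), max(w0$force[late]))
  expect_lt(max(w1$c[late]), max(w0$c[late]))
  expect_true(all(w1$c >= 0 & w1$c <= 1))
})
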