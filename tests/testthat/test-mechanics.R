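test_that("joint moment follows the linear viscoelastic + antagonist law", {
  pp <- passive_properties(k_b = 0.3, c_b = 0.02)
  expect_identical(joint_moment(0, 0, pp), 0)
  expect_equal(joint_moment(0.1, 0, pp), -0.1 * 0.3)
  expect_equal(joint_moment(0, 0.5, pp), -0.5 * 0.02)
  # equal antagonist forces cancel: passive moment only
  expect_equal(joint_moment(0.1, 0.2, pp, force_left = 2, force_right = 2,
                            w = 0.004),
               joint_moment(0.1, 0.2, pp))
  expect_equal(joint_moment(0, 0, pp, force_left = 1.5, force_right = 0.5,
                            w = 0.004), 1 * 0.004)
  expect_error(joint_moment(0, 0, pp, force_left = -1), "force")
})

test_that("straight resting rod is in equilibrium and rigid translation is force-free", {
  body <- build_body(small_plan())
  n <- body$n
  d0 <- rod_derivative(rod_state(body), body, act_on = FALSE)
  expect_equal(max(abs(d0)), 0)
  # uniform translation with fluid disabled: zero acceleration everywhere
  st <- rod_state(body, angles = 0.3, head_velocity = c(0.12, -0.05))
  d1 <- rod_derivative(st, body, act_on = FALSE, fluid_on = FALSE)
  acc <- d1[(n + 3):(2 * n + 4)]
  expect_lt(max(abs(acc)), 1e-12)
})

test_that("accelerations match the numeric Euler-Lagrange oracle on small chains", {
  for (spec in list(
    list(m = c(1.3, 0.7), ell = 0.5, phi = c(0.4, -0.7),
         om = c(1.5, -2.0)),
    list(m = c(0.4, 1.1, 0.9), ell = 0.3, phi = c(0.2, 1.1, -0.5),
         om = c(-1.2, 0.7, 2.5)))) {
    body <- toy_body(spec$m, spec$ell)
    n <- body$n
    kb <- 2.0
    q <- c(0.3, -0.2, spec$phi)
    qd <- c(0.2, 0.1, spec$om)
    st <- rod_state(body, head = q[1:2], angles = spec$phi,
                    head_velocity = qd[1:2], angular_velocity = spec$om)
    d <- rod_derivative(st, body,
                        passive = passive_properties(k_b = kb, c_b = 0),
                        act_on = FALSE, fluid_on = FALSE)
    acc <- d[(n + 3):(2 * n + 4)]
    ref <- oracle_accelerations(body, q, qd, k_b = kb)
    expect_equal(acc, as.numeric(ref), tolerance = 1e-8)
  }
})

test_that("linear momentum is conserved without muscle and fluid forces", {
  cfg <- quick_config(duration = 1, rtol = 1e-12, atol = 1e-14)
  body <- build_body(cfg$plan)
  st <- rod_state(body, angles = 0.4 * sin(seq_len(body$n)),
                  head_velocity = c(0.03, -0.02),
                  angular_velocity = 0.5)
  traj <- run_simulation(cfg, act_on = FALSE, fluid_on = FALSE,
                         initial_state = st)
  drift <- apply(traj$vcom, 2, function(v) diff(range(v)))
  expect_lt(max(drift), 1e-10)
})

test_that("mirrored activation yields the y-negated trajectory", {
  # the vector field itself is exactly equivariant under reflection
  cfg <- quick_config()
  body <- build_body(cfg$plan)
  nm <- length(lampswim:::muscle_joints(body))
  st <- rod_state(body, angles = 0.2 * sin(seq_len(body$n)),
                  head_velocity = c(0.01, -0.02), angular_velocity = 0.4,
                  c_left = seq(0, 0.5, length.out = nm),
                  c_right = seq(0.5, 0, length.out = nm))
  refl <- function(s) {
    n <- body$n
    c(s[1], -s[2], -s[3:(n + 2)], s[n + 3], -s[n + 4],
      -s[(n + 5):(2 * n + 4)],
      s[(2 * n + 5 + nm):(2 * n + 4 + 2 * nm)],   # sides swap
      s[(2 * n + 5):(2 * n + 4 + nm)])
  }
  w2 <- activation_wave(frequency = 3, strength = 1, mirror = TRUE)
  d1 <- rod_derivative(st, body, t = 0.7)
  d2 <- rod_derivative(refl(st), body, t = 0.7, wave = w2)
  expect_equal(d2, refl(d1), tolerance = 1e-14)

  # and whole trajectories mirror to within the (tight) solver tolerance
  cfg1 <- quick_config(duration = 1.5, rtol = 1e-12, atol = 1e-14)
  cfg2 <- cfg1
  cfg2$activation$mirror <- TRUE
  t1 <- run_simulation(cfg1)
  t2 <- run_simulation(cfg2)
  expect_lt(max(abs(t2$com[, 2] + t1$com[, 2])), 1e-10)
  expect_lt(max(abs(t2$phi + t1$phi)), 1e-10)
  expect_lt(max(abs(t2$com[, 1] - t1$com[, 1])), 1e-10)
})

test_that("a passive bent rod relaxes with monotonically decreasing energy", {
  cfg <- quick_config(duration = 2)
  body <- build_body(cfg$plan)
  st <- rod_state(body, angles = 0.8 * sin(2 * seq_len(body$n) / body$n))
  traj <- run_simulation(cfg, act_on = FALSE, initial_state = st)
  kin <- 0.5 * rowSums(sweep(traj$vx^2 + traj$vy^2, 2, body$mass, "*")) +
    0.5 * rowSums(sweep(traj$phidot^2, 2, body$inertia, "*"))
  dphi <- traj$phi[, -1] - traj$phi[, -body$n]
  k_joint <- cfg$passive$k_b * body$n / 50   # EI held fixed under refinement
  pot <- 0.5 * k_joint * rowSums(dphi^2)
  e <- kin + pot
  expect_true(all(diff(e) <= 1e-10 * e[1]))
  expect_lt(e[length(e)], 0.01 * e[1])
})

test_that("contour length is conserved through an active swimming run", {
  traj <- run_simulation(quick_config(duration = 2))
  L <- traj$body$plan$total_length
  expect_lt(max(abs(traj$contour_length - L)) / L, 1e-6)
})
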