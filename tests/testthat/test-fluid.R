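test_that("resistive force vanishes without motion and obeys the quadratic law", {
  fl <- fluid_params()
  expect_equal(taylor_force(c(0, 0), 0.3, 0.006, 0.0073, 0.004, fl),
               c(0, 0))
  # pure tangential motion with no skin friction
  fl0 <- fluid_params(c_t = 0)
  ang <- 0.7
  e <- c(cos(ang), sin(ang))
  expect_equal(taylor_force(0.3 * e, ang, 0.006, 0.0073, 0.004, fl0),
               c(0, 0))
  # doubling a pure normal velocity quadruples the force
  nv <- c(-sin(ang), cos(ang))
  f1 <- taylor_force(0.2 * nv, ang, 0.006, 0.0073, 0.004, fl)
  f2 <- taylor_force(0.4 * nv, ang, 0.006, 0.0073, 0.004, fl)
  expect_equal(f2, 4 * f1, tolerance = 1e-12)
  expect_lt(sum(f1 * nv), 0)   # opposes motion
})

test_that("forces are frame invariant under rotation", {
  fl <- fluid_params()
  set.seed(42)
  for (i in 1:20) {
    ang <- stats::runif(1, -pi, pi)
    v <- stats::rnorm(2, sd = 0.3)
    th <- stats::runif(1, -pi, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    f <- taylor_force(v, ang, 0.005, 0.0073, 0.004, fl)
    fr <- taylor_force(as.numeric(R %*% v), ang + th, 0.005, 0.0073,
                       0.004, fl)
    expect_equal(fr, as.numeric(R %*% f), tolerance = 1e-10)
  }
})

test_that("a towed straight rod matches the per-link closed form", {
  # uniform velocity, no rotation: the Gauss quadrature of the normal
  # force density reduces exactly to the per-link closed form
  body <- build_body(body_plan())
  fl <- fluid_params(c_t = 0)
  cfg <- simulation_config(fluid = fluid_params(c_t = 0), duration = 2)
  v <- c(-0.08, 0.13)
  st <- rod_state(body, angles = 0.4, head_velocity = v)
  ctx <- lampswim:::make_rod_context(body, cfg$passive, cfg$muscle,
                                     cfg$activation, cfg$fluid,
                                     act_on = FALSE, fluid_on = TRUE)
  sn <- lampswim:::rod_snapshot(0, st, ctx)
  ref <- vapply(seq_len(body$n), function(i) {
    taylor_force(v, 0.4, 2 * body$w[i], body$plan$height, body$ell, fl)
  }, numeric(2))
  expect_equal(as.numeric(sn$fluid_fx), ref[1, ], tolerance = 1e-10)
  expect_equal(as.numeric(sn$fluid_fy), ref[2, ], tolerance = 1e-10)
  # with skin friction the independent quadrature oracle is matched
  cfg2 <- simulation_config(duration = 2)
  ctx2 <- lampswim:::make_rod_context(body, cfg2$passive, cfg2$muscle,
                                      cfg2$activation, cfg2$fluid,
                                      act_on = FALSE, fluid_on = TRUE)
  sn2 <- lampswim:::rod_snapshot(0, st, ctx2)
  fl2 <- cfg2$fluid
  e <- c(cos(0.4), sin(0.4)); nv <- c(-sin(0.4), cos(0.4))
  vt <- sum(v * e); vn <- sum(v * nv); sp <- sqrt(sum(v^2))
  ref2 <- vapply(seq_len(body$n), function(i) {
    s0 <- (i - 1) / body$n; s1 <- i / body$n
    fN <- -0.5 * fl2$rho * fl2$c_n * body$plan$height * body$ell *
      vn * abs(vn)
    perim_int <- stats::integrate(function(s) {
      lampswim:::ellipse_perimeter(width_profile(s, body$plan) / 2,
                                   body$plan$height / 2)
    }, s0, s1, rel.tol = 1e-12)$value * body$plan$total_length
    fT <- -0.5 * fl2$rho * fl2$c_t * perim_int * vt * sp
    fT * e + fN * nv
  }, numeric(2))
  expect_equal(as.numeric(sn2$fluid_fx), ref2[1, ], tolerance = 1e-8)
  expect_equal(as.numeric(sn2$fluid_fy), ref2[2, ], tolerance = 1e-8)
})

test_that("fluid power is dissipative at every link through a swimming run", {
  traj <- run_simulation(quick_config(duration = 1.5))
  # total fluid power on each link: translational + spin contributions
  # (recompute spin torque from snapshots is implicit in tau-less storage;
  #  translational power alone can be slightly positive only through the
  #  torque channel, so test the full power via the snapshot interface)
  body <- traj$body
  cfg <- traj$config
  ctx <- lampswim:::make_rod_context(body, cfg$passive, cfg$muscle,
                                     cfg$activation, cfg$fluid)
  n <- body$n
  idx <- seq(1, length(traj$time), by = 7)
  for (i in idx) {
    st <- c(traj$head[i, ], traj$phi[i, ], traj$headvel[i, ],
            traj$phidot[i, ], traj$c_left[i, ], traj$c_right[i, ])
    sn <- lampswim:::rod_snapshot(traj$time[i], st, ctx)
    power <- sn$fluid_fx * traj$vx[i, ] + sn$fluid_fy * traj$vy[i, ] +
      sn$fluid_tau * traj$phidot[i, ]
    expect_true(all(power <= 1e-12))
  }
})
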