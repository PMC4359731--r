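make_table <- function(df) {
  df$ok <- TRUE
  df$converged <- TRUE
  class(df) <- c("sweep_table", class(df))
  df
}

test_that("the quadratic maximum is recovered exactly from parabolic data", {
  tab <- make_table(data.frame(frequency = 2:6, activation = 1,
                               U = -(2:6 - 4)^2 + 2))
  m <- optimal_frequency(tab, 1)
  expect_equal(m$f_opt, 4, tolerance = 1e-10)
  expect_equal(m$U_opt, 2, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  expect_false(m$extrapolated)
})

test_that("degenerate speed-frequency data are rejected", {
  flat <- make_table(data.frame(frequency = 2:6, activation = 1,
                                U = 0.3 * (2:6) + 1))
  expect_error(optimal_frequency(flat, 1), "no maximum")
  few <- make_table(data.frame(frequency = 2:4, activation = 1,
                               U = c(1, 2, 1)))
  expect_error(optimal_frequency(few, 1), "at least 4")
})

test_that("speed maps are recovered from noiseless generated maxima", {
  alpha <- 4.05; beta <- -0.642
  q0 <- -2.1; q1 <- 0.8; q2 <- 0.35
  U <- seq(0.5, 1.9, length.out = 7)
  maxima <- data.frame(activation = exp(q0 + q1 * U + q2 * U^2),
                       f_opt = alpha * U + beta, U_opt = U)
  maps <- fit_speed_maps(maxima)
  expect_equal(maps$alpha, alpha, tolerance = 1e-8)
  expect_equal(maps$beta, beta, tolerance = 1e-8)
  expect_equal(c(maps$q0, maps$q1, maps$q2), c(q0, q1, q2),
               tolerance = 1e-8)
  expect_equal(maps$f_of_U(1.2), alpha * 1.2 + beta, tolerance = 1e-8)
  expect_equal(maps$A_of_U(1.2), exp(q0 + q1 * 1.2 + q2 * 1.2^2),
               tolerance = 1e-8)
  expect_gt(maps$r_squared_f, 1 - 1e-12)

  # log-linearized fit agrees with a direct nonlinear least-squares fit
  nl <- minpack.lm::nlsLM(activation ~ exp(a0 + a1 * U_opt + a2 * U_opt^2),
                          data = maxima,
                          start = list(a0 = -1, a1 = 0.5, a2 = 0.2))
  expect_equal(unname(stats::coef(nl)), c(maps$q0, maps$q1, maps$q2),
               tolerance = 1e-2)
})

test_that("closed loop refuses extrapolation beyond the fitted range", {
  U <- seq(0.8, 1.5, length.out = 5)
  maxima <- data.frame(activation = exp(-2 + U), f_opt = 4 * U - 0.5,
                       U_opt = U)
  maps <- fit_speed_maps(maxima)
  expect_error(closed_loop(2.0, maps), "fitted range")
  expect_error(closed_loop(0.2, maps), "fitted range")
})

test_that("a single-pair sweep row matches a direct simulation", {
  cfg <- quick_config(duration = 2.5)
  tab <- sweep_experiments(frequencies = 3, activations = 1,
                           base_config = cfg)
  expect_identical(nrow(tab), 1L)
  expect_true(tab$ok)
  direct <- run_simulation(lampswim:::with_activation(cfg, 3, 1))
  ks <- suppressWarnings(summarize_kinematics(direct))
  expect_equal(tab$U, ks$U, tolerance = 1e-12)
  expect_equal(tab$amplitude, ks$amplitude, tolerance = 1e-12)
  expect_equal(tab$ratio, ks$ratio, tolerance = 1e-12)
})

test_that("calibration returns the initial guess when targets are already met", {
  cfg <- simulation_config()
  # stub evaluator: metrics depend deterministically on the candidate
  calls <- 0
  ev_ok <- function(c2) {
    calls <<- calls + 1
    list(ratio = 0.74, amplitude = 0.13, r_squared = 0.99)
  }
  out <- calibrate_passive(cfg, evaluate = ev_ok)
  expect_equal(out$passive$k_b, cfg$passive$k_b)
  expect_equal(out$passive$c_b, cfg$passive$c_b)
  expect_identical(calls, 1)
})

test_that("calibration searches past failing candidates and reports near misses", {
  cfg <- simulation_config()
  # stiff-limit behaviour: very large k_b drives the ratio to 1 and the
  # amplitude to nearly zero, so such candidates must be rejected
  ev <- function(c2) {
    if (c2$passive$k_b > 5 * cfg$passive$k_b) {
      list(ratio = 0.99, amplitude = 0.01, r_squared = 0.9)
    } else if (c2$passive$k_b < cfg$passive$k_b) {
      list(ratio = 0.75, amplitude = 0.12, r_squared = 0.99)
    } else {
      list(ratio = 0.95, amplitude = 0.05, r_squared = 0.97)
    }
  }
  out <- calibrate_passive(cfg, k_b_grid = cfg$passive$k_b * c(1, 10, 0.5),
                           c_b_grid = cfg$passive$c_b, evaluate = ev)
  expect_equal(out$passive$k_b, cfg$passive$k_b * 0.5)
  expect_true(any(!out$trace$hit))
  ev_never <- function(c2) list(ratio = 1.2, amplitude = 0.4,
                                r_squared = 0.5)
  expect_error(calibrate_passive(cfg, evaluate = ev_never), "near misses")
})
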