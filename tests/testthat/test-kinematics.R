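test_that("estimators recover the construction parameters of synthetic waves", {
  # f = 4, lambda = 0.8 BL -> V_c = 3.2 BL/s, ratio 0.8
  syn <- synthetic_wave_trajectory(frequency = 4, wavelength = 0.8,
                                   speed = 1, amplitude = 0.1)
  fs <- forward_speed(syn)
  expect_equal(fs$U, 1, tolerance = 1e-9)
  expect_equal(tail_amplitude(syn), 0.1, tolerance = 1e-3)
  cw <- curvature_wave_speed(syn)
  expect_equal(cw$V_c, 3.2, tolerance = 0.01 * 3.2)
  expect_gt(cw$r_squared, 0.999)
  wr <- wave_ratio(syn)
  expect_equal(wr$ratio, 0.8, tolerance = 0.01)
  # wavelength 1 BL travels at exactly the activation speed
  syn1 <- synthetic_wave_trajectory(frequency = 3, wavelength = 1)
  expect_equal(wave_ratio(syn1)$ratio, 1.0, tolerance = 0.01)
})

test_that("a rigid translation yields its prescribed speed and no tail beat", {
  syn <- synthetic_wave_trajectory(frequency = 4, wavelength = 0.8,
                                   speed = 0.1, amplitude = 0, kappa0 = 5)
  expect_equal(forward_speed(syn)$U, 0.1, tolerance = 1e-9)
  expect_equal(tail_amplitude(syn), 0, tolerance = 1e-12)
})

test_that("a standing wave raises the non-uniform-wave warning", {
  syn <- synthetic_wave_trajectory(frequency = 4, standing = TRUE)
  expect_warning(curvature_wave_speed(syn), "non-uniform")
})

test_that("wave ratio is curvature speed over activation speed", {
  syn <- synthetic_wave_trajectory(frequency = 4, wavelength = 0.75)
  wr <- wave_ratio(syn)
  expect_equal(wr$V_a, 4)
  expect_equal(wr$ratio, wr$V_c / 4)
})

test_that("segment work vanishes without activation and matches the loop-area oracle", {
  cfg <- quick_config(duration = 2)
  body <- build_body(cfg$plan)
  st <- rod_state(body, angles = 0.3 * sin(seq_len(body$n)))
  passive <- run_simulation(cfg, act_on = FALSE, initial_state = st)
  w0 <- suppressWarnings(segment_work(passive))
  expect_true(all(w0$work == 0))

  # dual-route check of the work quadrature on an analytic loop with a
  # closed-form area: F = F0 (1 + a sin), L = L0 + d cos over one cycle
  F0 <- 0.8; a <- 0.5; d <- 0.002; L0 <- 0.004; Tc <- 0.25
  tt <- seq(0, Tc, length.out = 40001)
  th <- 2 * pi * tt / Tc
  Fm <- F0 * (1 + a * sin(th))
  Lm <- L0 + d * cos(th)
  v <- d * 2 * pi / Tc * sin(th)              # shortening rate = -dL/dt
  exact <- pi * F0 * a * d                    # closed form of int F (-dL)
  time_route <- lampswim:::trapz(tt, Fm * v)
  loop_route <- -sum(0.5 * (Fm[-1] + Fm[-40001]) * diff(Lm))  # shoelace
  expect_equal(time_route, exact, tolerance = 1e-8)
  expect_equal(loop_route, exact, tolerance = 1e-8)

  # on a real run the loop-area route reproduces segment_work
  traj <- std_traj()
  wk <- segment_work(traj)
  f <- traj$config$activation$frequency
  t_end <- traj$time[length(traj$time)]
  idx <- which(traj$time >= t_end - 1 / f - 1e-9)
  for (k in c(5, 20, 35)) {
    area <- function(F, L) {
      x <- L[idx]; y <- F[idx]
      -sum(0.5 * (y[-1] + y[-length(y)]) * diff(x))
    }
    oracle <- area(traj$force_left[, k], traj$len_left[, k]) +
      area(traj$force_right[, k], traj$len_right[, k])
    expect_equal(wk$work[k], oracle, tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})

test_that("steady forward speed oscillates at twice the cycle frequency and lateral at once", {
  traj <- std_traj()
  f <- traj$config$activation$frequency
  win <- traj$steady$index
  # use three cycles for sharper spectral lines
  spc <- traj$config$samples_per_cycle
  win <- seq(max(1, win[length(win)] - 3 * spc), win[length(win)])
  h <- forward_speed(traj)$heading
  nvec <- c(-h[2], h[1])
  fwd <- traj$vcom[win, ] %*% h
  lat <- traj$vcom[win, ] %*% nvec
  peak_freq <- function(x) {
    x <- x - mean(x)
    sp <- Mod(stats::fft(x))^2
    nf <- length(x)
    freqs <- (seq_len(nf) - 1) / (nf * traj$dt)
    keep <- freqs > 0.2 & freqs < 0.5 / traj$dt
    freqs[keep][which.max(sp[keep])]
  }
  expect_equal(peak_freq(fwd), 2 * f, tolerance = 0.15)
  expect_equal(peak_freq(lat), f, tolerance = 0.15)
})

test_that("speed estimate agrees with the displacement oracle and the run is steady", {
  traj <- std_traj()
  expect_true(traj$steady$reached)
  fs <- forward_speed(traj)
  win <- traj$steady$index
  L <- traj$body$plan$total_length
  disp <- traj$com[win[length(win)], ] - traj$com[win[1], ]
  dt <- traj$time[win[length(win)]] - traj$time[win[1]]
  expect_equal(fs$U, sqrt(sum(disp^2)) / dt / L, tolerance = 1e-9)
  expect_gt(fs$U, 0.2)
})
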