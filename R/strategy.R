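#' Default sweep grids
#'
#' The standard experiment grid: cycle frequencies 2-6 per second and
#' activation strengths log-spaced from 0.1% to 20% of maximum isometric
#' force.  The `fast` preset is a reduced 3 x 4 grid for quick checks.
#'
#' @param n Number of activation levels.
#' @return Numeric vector.
#' @export
default_frequencies <- function() c(2, 3, 4, 5, 6)

#' @rdname default_frequencies
#' @export
default_activations <- function(n = 8) {
  10^seq(log10(0.1), log10(20), length.out = n)
}

# replace the swept fields of a configuration
with_activation <- function(config, frequency, strength) {
  a <- config$activation
  config$activation <- activation_wave(frequency = frequency,
                                       strength = strength,
                                       duty = a$duty,
                                       ramp_time = a$ramp_time,
                                       ramp_level = a$ramp_level,
                                       edge = a$edge, mirror = a$mirror)
  config
}

#' Frequency x activation sweep
#'
#' Runs a simulation and kinematic analysis for every combination of cycle
#' frequency and activation strength.  Failed or non-converged runs are
#' recorded with their flag, never dropped.
#'
#' @param frequencies Cycle frequencies, 1/s.
#' @param activations Activation strengths, % of maximum isometric force
#'   (log spacing recommended).
#' @param base_config A [simulation_config()] supplying everything that is
#'   not swept.
#' @param band Wave-speed analysis band.
#' @param verbose Print a one-line summary per run.
#' @return A data frame of class `sweep_table`: one row per (frequency,
#'   activation) pair with the kinematic summary, `converged` and `ok`
#'   flags and any solver `error` message.
#' @export
sweep_experiments <- function(frequencies = default_frequencies(),
                              activations = default_activations(),
                              base_config = simulation_config(),
                              band = c(0.25, 0.9), verbose = FALSE) {
  stopifnot(length(frequencies) > 0, length(activations) > 0)
  grid <- expand.grid(frequency = frequencies, activation = activations,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    f <- grid$frequency[i]; a <- grid$activation[i]
    cfg <- with_activation(base_config, f, a)
    res <- tryCatch({
      traj <- run_simulation(cfg)
      ks <- suppressWarnings(summarize_kinematics(traj, band))
      data.frame(frequency = f, activation = a, U = ks$U,
                 amplitude = ks$amplitude, V_c = ks$V_c,
                 ratio = ks$ratio, r_squared = ks$r_squared,
                 work = ks$work, converged = ks$converged, ok = TRUE,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(frequency = f, activation = a, U = NA_real_,
                 amplitude = NA_real_, V_c = NA_real_, ratio = NA_real_,
                 r_squared = NA_real_, work = NA_real_, converged = FALSE,
                 ok = FALSE, error = conditionMessage(e))
    })
    if (verbose) {
      message(sprintf("f = %.2g, A = %.3g%%: U = %.3g BL/s, R = %.3g%s",
                      f, a, res$U, res$ratio,
                      if (isTRUE(res$converged)) "" else " (not converged)"))
    }
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", class(out))
  out
}

#' Speed-maximizing frequency at one activation level
#'
#' Fits `U = a f^2 + b f + c` by least squares over the sweep rows at the
#' given activation and locates the maximum of the parabola.
#'
#' @param table A `sweep_table`.
#' @param activation Activation strength (%) to extract (matched to the
#'   nearest table value).
#' @return A list: `f_opt`, `U_opt`, `r_squared`, `extrapolated` (is
#'   `f_opt` outside the swept range), and the quadratic `coefficients`.
#' @export
optimal_frequency <- function(table, activation) {
  rows <- table[table$ok &
                  abs(table$activation - activation) <
                  1e-8 + 1e-6 * activation, , drop = FALSE]
  if (nrow(rows) < 4) {
    stop("need at least 4 swept frequencies at activation ", activation,
         "%", call. = FALSE)
  }
  fit <- stats::lm(U ~ frequency + I(frequency^2), data = rows)
  cf <- stats::coef(fit)
  a <- cf[[3]]; b <- cf[[2]]; cc <- cf[[1]]
  fspan <- diff(range(rows$frequency))
  if (!is.finite(a) || a >= 0 ||
      abs(a) * fspan^2 < 1e-8 * max(abs(rows$U), 1e-12)) {
    stop("no maximum in range: quadratic coefficient is not negative",
         call. = FALSE)
  }
  f_opt <- -b / (2 * a)
  U_opt <- cc - b^2 / (4 * a)
  r2 <- summary(fit)$r.squared
  list(f_opt = f_opt, U_opt = U_opt, r_squared = r2,
       extrapolated = f_opt < min(rows$frequency) ||
         f_opt > max(rows$frequency),
       coefficients = c(a = a, b = b, c = cc))
}

#' Fit the speed maps
#'
#' From the speed-maximizing points (activation A, optimal frequency f*,
#' maximal speed U*): a linear map `f*(U) = alpha U + beta` and an
#' activation map `A(U) = exp(q2 U^2 + q1 U + q0)` (fitted as a quadratic
#' in U on the log-activation scale).
#'
#' @param maxima Data frame with columns `activation`, `f_opt`, `U_opt`
#'   (one row per activation level, from [optimal_frequency()]).
#' @param f_margin Maxima whose optimal frequency lies more than this far
#'   (cycles/s) outside the swept frequency range are treated as
#'   unreliable long-range extrapolations of the quadratic and excluded
#'   from the map fits (they stay in `maxima`, and the excluded levels are
#'   listed in `dropped`).  Only applies when the maxima carry their
#'   sweep's frequency range (as those from [extract_maxima()] do).
#' @return An object of class `speed_maps` with coefficients, diagnostics,
#'   the fitted speed range, and accessor functions `f_of_U` / `A_of_U`.
#' @export
fit_speed_maps <- function(maxima, f_margin = 1) {
  stopifnot(all(c("activation", "f_opt", "U_opt") %in% names(maxima)))
  dropped <- NULL
  f_range <- attr(maxima, "f_range")
  if (!is.null(f_range)) {
    bad <- maxima$f_opt < f_range[1] - f_margin |
      maxima$f_opt > f_range[2] + f_margin
    dropped <- maxima[bad, , drop = FALSE]
    maxima <- maxima[!bad, , drop = FALSE]
  }
  if (nrow(maxima) < 4) {
    stop("need at least 4 speed-maximizing points", call. = FALSE)
  }
  ffit <- stats::lm(f_opt ~ U_opt, data = maxima)
  X <- cbind(1, maxima$U_opt, maxima$U_opt^2)
  if (kappa(crossprod(X)) > 1e12) {
    stop("activation-map design matrix is ill-conditioned", call. = FALSE)
  }
  afit <- stats::lm(log(activation) ~ U_opt + I(U_opt^2), data = maxima)
  alpha <- stats::coef(ffit)[[2]]; beta <- stats::coef(ffit)[[1]]
  q <- stats::coef(afit)
  maps <- list(alpha = alpha, beta = beta,
               q0 = q[[1]], q1 = q[[2]], q2 = q[[3]],
               r_squared_f = summary(ffit)$r.squared,
               r_squared_a = summary(afit)$r.squared,
               residuals_f = stats::resid(ffit),
               residuals_a = stats::resid(afit),
               U_range = range(maxima$U_opt),
               maxima = maxima, dropped = dropped)
  maps$f_of_U <- function(U) maps$alpha * U + maps$beta
  maps$A_of_U <- function(U) exp(maps$q0 + maps$q1 * U + maps$q2 * U^2)
  class(maps) <- "speed_maps"
  maps
}

#' @export
print.speed_maps <- function(x, ...) {
  cat("<speed_maps> f*(U) = ", signif(x$alpha, 4), " U + ",
      signif(x$beta, 4), " (R^2 ", signif(x$r_squared_f, 4), ")\n",
      "            ln A(U) = ", signif(x$q2, 4), " U^2 + ",
      signif(x$q1, 4), " U + ", signif(x$q0, 4), " (R^2 ",
      signif(x$r_squared_a, 4), ")\n",
      "            fitted U range ", signif(x$U_range[1], 3), "-",
      signif(x$U_range[2], 3), " BL/s\n", sep = "")
  invisible(x)
}

#' Closed-loop speed control
#'
#' The comprehensive model: the sole input is the desired swimming speed;
#' frequency and activation strength are computed from the fitted maps and
#' the full simulation is run at that operating point.
#'
#' @param U_desired Desired forward speed(s), BL/s.
#' @param maps A [fit_speed_maps()] result.
#' @param base_config Base [simulation_config()].
#' @param band Wave-speed analysis band.
#' @param allow_extrapolation Permit speeds outside the fitted range.
#' @param verbose Print one line per run.
#' @return A data frame: one row per desired speed with `frequency`,
#'   `activation`, `U_achieved`, `rel_error`, `ratio`, `amplitude`,
#'   `r_squared`, `converged`.
#' @export
closed_loop <- function(U_desired, maps, base_config = simulation_config(),
                        band = c(0.25, 0.9), allow_extrapolation = FALSE,
                        verbose = FALSE) {
  stopifnot(inherits(maps, "speed_maps"))
  out_of_range <- U_desired < maps$U_range[1] - 1e-9 |
    U_desired > maps$U_range[2] + 1e-9
  if (any(out_of_range) && !allow_extrapolation) {
    stop("desired speed(s) ",
         paste(signif(U_desired[out_of_range], 3), collapse = ", "),
         " BL/s outside the fitted range [",
         signif(maps$U_range[1], 3), ", ", signif(maps$U_range[2], 3),
         "]; set allow_extrapolation = TRUE to override", call. = FALSE)
  }
  rows <- lapply(U_desired, function(U) {
    f <- maps$f_of_U(U)
    a <- maps$A_of_U(U)
    res <- tryCatch({
      cfg <- with_activation(base_config, f, a)
      traj <- run_simulation(cfg)
      ks <- suppressWarnings(summarize_kinematics(traj, band))
      data.frame(U_desired = U, frequency = f, activation = a,
                 U_achieved = ks$U, rel_error = abs(ks$U - U) / U,
                 ratio = ks$ratio, amplitude = ks$amplitude,
                 r_squared = ks$r_squared, converged = ks$converged,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(U_desired = U, frequency = f, activation = a,
                 U_achieved = NA_real_, rel_error = NA_real_,
                 ratio = NA_real_, amplitude = NA_real_,
                 r_squared = NA_real_, converged = FALSE,
                 error = conditionMessage(e))
    })
    if (verbose) {
      message(sprintf(
        "U* = %.3g: f = %.3g /s, A = %.3g%% -> U = %.4g BL/s (err %.3g%%)%s",
        U, f, a, res$U_achieved, 100 * res$rel_error,
        if (is.na(res$U_achieved)) paste0(" [", res$error, "]") else ""))
    }
    res
  })
  do.call(rbind, rows)
}

#' Sweep, extract maxima and fit the speed maps in one pass
#'
#' @inheritParams sweep_experiments
#' @return A list: `table` (the sweep), `maxima`, `maps`.
#' @export
build_speed_maps <- function(frequencies = default_frequencies(),
                             activations = default_activations(),
                             base_config = simulation_config(),
                             band = c(0.25, 0.9), verbose = FALSE) {
  table <- sweep_experiments(frequencies, activations, base_config,
                             band, verbose)
  maxima <- extract_maxima(table)
  list(table = table, maxima = maxima, maps = fit_speed_maps(maxima))
}

#' Extract all speed-maximizing points from a sweep table
#'
#' @param table A `sweep_table`.
#' @return Data frame with one row per activation level that admits an
#'   interior maximum: `activation`, `f_opt`, `U_opt`, `r_squared`,
#'   `extrapolated`.
#' @export
extract_maxima <- function(table) {
  acts <- sort(unique(table$activation[table$ok]))
  rows <- lapply(acts, function(a) {
    m <- tryCatch(optimal_frequency(table, a), error = function(e) NULL)
    if (is.null(m)) return(NULL)
    data.frame(activation = a, f_opt = m$f_opt, U_opt = m$U_opt,
               r_squared = m$r_squared, extrapolated = m$extrapolated)
  })
  out <- do.call(rbind, rows)
  attr(out, "f_range") <- range(table$frequency[table$ok])
  out
}

#' One-time calibration of the passive tissue parameters
#'
#' Grid search over joint stiffness and damping (and optionally the normal
#' drag coefficient) for the first parameter set whose closed-loop
#' behaviour meets the targets: mean curvature/activation wave-speed ratio
#' within the observed lamprey range, a stable backward-travelling wave at
#' every probed point, and tail-beat amplitude within the anguilliform
#' range.  Candidates are evaluated in grid order with the initial guess
#' (the `base_config` values) first, so a base configuration that already
#' meets the targets is returned unchanged.
#'
#' @param base_config Base [simulation_config()].
#' @param k_b_grid,c_b_grid,c_n_grid Candidate values; the base
#'   configuration's own values are always probed first.
#' @param targets List with `ratio` and `amplitude` ranges (and
#'   `min_r_squared` for wave stability).
#' @param speeds Desired closed-loop speeds probed per candidate.
#' @param frequencies,activations Reduced sweep used to fit maps per
#'   candidate.
#' @param evaluate Optional evaluation function
#'   `function(config) -> list(ratio, amplitude, r_squared)` replacing the
#'   built-in (simulation-based) evaluation; used to probe the search
#'   logic cheaply.
#' @param verbose Report candidates as they are probed.
#' @return A list: `passive` ([passive_properties()]), `fluid`
#'   ([fluid_params()]), the achieved `metrics`, and the `trace` of all
#'   probed candidates.  Errors with a table of near misses when no
#'   candidate meets the targets.
#' @export
calibrate_passive <- function(base_config = simulation_config(),
                              k_b_grid = NULL, c_b_grid = NULL,
                              c_n_grid = NULL,
                              targets = list(ratio = c(0.65, 0.79),
                                             amplitude = c(0.08, 0.18),
                                             min_r_squared = 0.95),
                              speeds = c(0.8, 1.2, 1.6),
                              frequencies = c(2, 4, 6),
                              activations = 10^seq(log10(0.3), log10(10),
                                                   length.out = 4),
                              evaluate = NULL, verbose = FALSE) {
  kb0 <- base_config$passive$k_b; cb0 <- base_config$passive$c_b
  cn0 <- base_config$fluid$c_n
  if (is.null(k_b_grid)) k_b_grid <- kb0 * c(1, 0.5, 2, 0.25, 4)
  if (is.null(c_b_grid)) c_b_grid <- cb0 * c(1, 0.5, 2)
  if (is.null(c_n_grid)) c_n_grid <- cn0
  c_n_grid <- c_n_grid[c_n_grid >= 0.5 * cn0 & c_n_grid <= 2 * cn0 |
                         c_n_grid == cn0]
  grid <- expand.grid(k_b = k_b_grid, c_b = c_b_grid, c_n = c_n_grid,
                      KEEP.OUT.ATTRS = FALSE)
  # initial guess first, then the rest in grid order
  is0 <- grid$k_b == kb0 & grid$c_b == cb0 & grid$c_n == cn0
  grid <- rbind(grid[is0, , drop = FALSE], grid[!is0, , drop = FALSE])
  if (is.null(evaluate)) {
    evaluate <- function(cfg) {
      bm <- build_speed_maps(frequencies, activations, cfg)
      cl <- closed_loop(speeds, bm$maps, cfg, allow_extrapolation = TRUE)
      list(ratio = mean(cl$ratio, na.rm = TRUE),
           amplitude = mean(cl$amplitude, na.rm = TRUE),
           r_squared = min(cl$r_squared, na.rm = TRUE))
    }
  }
  trace <- list()
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$passive <- passive_properties(grid$k_b[i], grid$c_b[i])
    cfg$fluid <- fluid_params(base_config$fluid$rho, grid$c_n[i],
                              base_config$fluid$c_t)
    met <- tryCatch(evaluate(cfg), error = function(e) {
      list(ratio = NA_real_, amplitude = NA_real_, r_squared = NA_real_,
           error = conditionMessage(e))
    })
    hit <- is.finite(met$ratio) &&
      met$ratio >= targets$ratio[1] && met$ratio <= targets$ratio[2] &&
      met$amplitude >= targets$amplitude[1] &&
      met$amplitude <= targets$amplitude[2] &&
      is.finite(met$r_squared) && met$r_squared >= targets$min_r_squared
    trace[[i]] <- data.frame(k_b = grid$k_b[i], c_b = grid$c_b[i],
                             c_n = grid$c_n[i], ratio = met$ratio,
                             amplitude = met$amplitude,
                             r_squared = met$r_squared, hit = hit)
    if (verbose) {
      message(sprintf("k_b = %.3g, c_b = %.3g, c_n = %.3g: R = %.3g, amp = %.3g %s",
                      grid$k_b[i], grid$c_b[i], grid$c_n[i],
                      met$ratio, met$amplitude,
                      if (hit) "[hit]" else ""))
    }
    if (hit) {
      return(list(passive = cfg$passive, fluid = cfg$fluid, metrics = met,
                  trace = do.call(rbind, trace)))
    }
  }
  near <- do.call(rbind, trace)
  stop("no parameter set in the search box meets the calibration targets; ",
       "near misses:\n",
       paste(utils::capture.output(print(near)), collapse = "\n"),
       call. = FALSE)
}
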