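# Shared fixtures: cheap configurations for dynamical property tests
# (where the exact calibrated physics does not matter) and a cached
# standard run reused across test files.

# small body for fast dynamics tests; taper fixed so no 50-section
# calibration constraint applies
small_plan <- function(n = 20) {
  body_plan(n_segments = n)
}

quick_config <- function(n = 20, frequency = 3, strength = 1,
                         duration = 2, ...) {
  simulation_config(plan = small_plan(n),
                    activation = activation_wave(frequency = frequency,
                                                 strength = strength),
                    duration = duration, samples_per_cycle = 60, ...)
}

.cache <- new.env(parent = emptyenv())

# one moderately long default-body run shared by several tests
std_traj <- function() {
  if (is.null(.cache$std)) {
    .cache$std <- run_simulation(simulation_config(duration = 7))
  }
  .cache$std
}

# a hand-built rigid-link body with O(1) masses for oracle comparisons
toy_body <- function(masses, ell, widths = NULL) {
  n <- length(masses)
  if (is.null(widths)) widths <- rep(0.05 * ell, n)
  structure(list(
    plan = body_plan(), n = n, ell = ell, mass = masses,
    inertia = masses * ell^2 / 12,
    s = (seq_len(n) - 0.5) / n, w = widths,
    has_muscle = rep(FALSE, n),
    s_com = 0.5, com_segment = 1L,
    ref_scale = 1),   # joint constants used as given, no EI rescaling
    class = "discrete_body")
}
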