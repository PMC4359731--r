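#' Stimulus drive at a body position and time
#'
#' Evaluates the CPG output: a square wave of duty `wave$duty`, travelling
#' head-to-tail at one body length per cycle, in antiphase on the two sides,
#' multiplied by the start-up ramp and scaled to the stimulus amplitude that
#' corresponds to `wave$strength` percent of maximum isometric force.
#' The left side of a segment at arc position `s = 0` turns on at `t = 0`.
#'
#' @param s Arc position(s) of the segment centre, body lengths in \[0, 1\].
#' @param side `"left"` or `"right"`.
#' @param t Time(s), seconds (>= 0).
#' @param wave An [activation_wave()].
#' @param muscle A [muscle_params()] (sets the strength-to-amplitude
#'   scaling).
#' @return Dimensionless stimulus drive, vectorized over `s` and/or `t`.
#' @export
stim_drive <- function(s, side = c("left", "right"), t,
                       wave = activation_wave(), muscle = muscle_params()) {
  side <- match.arg(side)
  if (any(s < 0 | s > 1)) stop("arc position s must lie in [0, 1]",
                               call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (wave$mirror) side <- if (side == "left") "right" else "left"
  shift <- if (side == "right") 0.5 else 0
  x <- (wave$frequency * t - s + shift) %% 1
  amp <- stim_amplitude(wave$strength, muscle)
  amp * activation_ramp(t, wave) * square_pulse(x, wave$duty, wave$edge)
}

# smoothed cyclic unit pulse: 1 on [0, duty), 0 elsewhere, tanh edges of
# width `edge` (cycle fraction); exact square wave when edge = 0
square_pulse <- function(x, duty, edge) {
  if (edge <= 0) return(as.numeric(x >= 0 & x < duty))
  v <- 0
  for (k in -1:1) {
    z <- x + k
    v <- v + 0.5 * (tanh(z / edge) - tanh((z - duty) / edge))
  }
  v
}
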