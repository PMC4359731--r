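#' Parametric body plan of the swimmer
#'
#' Describes the continuous body: a 21 cm, 15 g animal of uniform density and
#' neutral buoyancy, with a constant-height elliptical cross-section.  The
#' width profile rises smoothly from a rounded snout to its maximum in the
#' gill region and tapers monotonically to the tail; its one free shape
#' parameter is calibrated (once, analytically at construction) so that the
#' resting centre of mass falls in segment 18 of 50, the only printed
#' geometric consequence of the real outline.
#'
#' @param total_length Body length in metres.
#' @param total_mass Body mass in kilograms.
#' @param height Body height in metres (constant along the body).
#' @param width_max Maximum body width (gill region), metres.
#' @param width_tail Body width at the tail tip, metres.
#' @param n_segments Number of body sections the rod is discretized into.
#' @param head_fraction Fraction of body length (from the snout) carrying no
#'   swimming muscle (head and gill region).
#' @param gill_position Arc position (body lengths) of the width maximum.
#' @param snout_width Width at the snout tip, metres.
#' @param taper_shape Taper exponent; `NULL` (default) calibrates it so the
#'   resting centre of mass lies in segment 18 of a 50-section body.
#' @return An object of class `body_plan`.
#' @export
body_plan <- function(total_length = 0.21, total_mass = 0.015,
                      height = 0.0073, width_max = 0.0073,
                      width_tail = 0.0005, n_segments = 50,
                      head_fraction = 0.12, gill_position = 0.1,
                      snout_width = 0.25 * width_max, taper_shape = NULL) {
  stopifnot(total_length > 0, total_mass > 0, height > 0,
            width_max > width_tail, width_tail > 0,
            head_fraction >= 0, head_fraction < 1,
            gill_position > 0, gill_position < 0.5)
  if (n_segments < 10) {
    stop("n_segments must be at least 10", call. = FALSE)
  }
  plan <- structure(
    list(total_length = total_length, total_mass = total_mass,
         height = height, width_max = width_max, width_tail = width_tail,
         n_segments = as.integer(n_segments), head_fraction = head_fraction,
         gill_position = gill_position, snout_width = snout_width,
         taper_shape = taper_shape, calibrated = is.null(taper_shape)),
    class = "body_plan")
  if (is.null(taper_shape)) {
    plan$taper_shape <- calibrate_taper(plan)
  }
  plan
}

# arc position of the centre of mass for a given taper exponent,
# by fine quadrature of the width profile (area ~ width at constant height)
com_arc_position <- function(plan, n_quad = 4000L) {
  s <- (seq_len(n_quad) - 0.5) / n_quad
  w <- width_profile(s, plan)
  sum(s * w) / sum(w)
}

# choose the taper exponent so the resting COM sits at the centre of
# segment 18 of 50 (arc position 17.5/50)
calibrate_taper <- function(plan) {
  target <- 17.5 / 50
  f <- function(p) {
    plan$taper_shape <- p
    com_arc_position(plan) - target
  }
  lo <- 0.05; hi <- 12
  if (f(lo) * f(hi) > 0) {
    stop("body plan cannot place the resting centre of mass in segment 18 ",
         "of 50: COM arc position spans [",
         signif(f(hi) + target, 4), ", ", signif(f(lo) + target, 4),
         "] over the taper search range", call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Body width at an arc position
#'
#' Smooth (C1) width profile: a half-sine rise from the snout to the gill
#' maximum, then a `(1 - u^2)^p` taper to the tail width, where `u` is the
#' normalized distance beyond the gill region and `p` is the calibrated
#' taper exponent.
#'
#' @param s Arc position(s) along the body in body lengths, in \[0, 1\]
#'   (0 = snout, 1 = tail tip).
#' @param plan A [body_plan()].
#' @return Width in metres, same length as `s`.
#' @export
width_profile <- function(s, plan) {
  if (any(s < 0 | s > 1)) {
    stop("arc position s must lie in [0, 1]", call. = FALSE)
  }
  sg <- plan$gill_position
  p <- plan$taper_shape
  w <- numeric(length(s))
  head <- s <= sg
  w[head] <- plan$snout_width +
    (plan$width_max - plan$snout_width) * sin(pi * s[head] / (2 * sg))^2
  u <- (s[!head] - sg) / (1 - sg)
  w[!head] <- plan$width_tail +
    (plan$width_max - plan$width_tail) * (1 - u^2)^p
  w
}

#' Discretize a body plan into rigid sections
#'
#' Splits the body into `n_segments` equal-length rigid links.  Section
#' masses come from integrating the elliptical cross-section area (constant
#' height x local width) over each section at uniform density, normalized so
#' they sum exactly to the total mass.  Cross-bar half-widths (the muscle
#' moment arms) equal half the local width at the section centre; sections
#' whose centre lies within the muscle-free head fraction carry no muscle.
#'
#' @param plan A [body_plan()].
#' @return An object of class `discrete_body` with per-section `mass`,
#'   `inertia`, arc positions `s` (section centres, body lengths),
#'   half-widths `w`, `has_muscle`, and the segment index containing the
#'   resting centre of mass (`com_segment`).
#' @export
build_body <- function(plan) {
  stopifnot(inherits(plan, "body_plan"))
  n <- plan$n_segments
  ell <- plan$total_length / n
  # per-section area integrals by 5-point Gauss-Legendre
  gx <- c(-0.9061798459386640, -0.5384693101056831, 0,
          0.5384693101056831, 0.9061798459386640)
  gw <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
          0.4786286704993665, 0.2369268850561891)
  s_lo <- (seq_len(n) - 1) / n
  area <- vapply(seq_len(n), function(i) {
    s <- s_lo[i] + (gx + 1) / (2 * n)
    sum(gw * width_profile(s, plan)) / (2 * n)   # integral of w over section, BL
  }, numeric(1))
  mass <- plan$total_mass * area / sum(area)
  s_mid <- (seq_len(n) - 0.5) / n
  w <- width_profile(s_mid, plan) / 2
  inertia <- mass * (ell^2 + (2 * w)^2) / 12
  has_muscle <- s_mid >= plan$head_fraction

  # resting COM from the continuous profile (independent of n)
  s_com <- com_arc_position(plan)
  com_segment <- min(n, 1L + floor(s_com * n))
  if (isTRUE(plan$calibrated) && n == 50L && com_segment != 18L) {
    stop("width profile places the resting centre of mass in segment ",
         com_segment, " of 50, not segment 18; adjust taper_shape",
         call. = FALSE)
  }
  structure(
    list(plan = plan, n = n, ell = ell, mass = mass, inertia = inertia,
         s = s_mid, w = w, has_muscle = has_muscle,
         s_com = s_com, com_segment = as.integer(com_segment)),
    class = "discrete_body")
}

#' @export
print.discrete_body <- function(x, ...) {
  cat("<discrete_body> ", x$n, " sections, L = ", x$plan$total_length,
      " m, M = ", signif(sum(x$mass), 6), " kg, COM in segment ",
      x$com_segment, "\n", sep = "")
  invisible(x)
}

# perimeter of an ellipse with semi-axes a, b (Ramanujan approximation)
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}
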