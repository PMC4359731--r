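#' Taylor resistive force on one link
#'
#' Decomposes the link velocity into normal and tangential components in the
#' link frame and applies the resistive law: quadratic pressure drag
#' `F_N = -1/2 rho c_n h l v_N |v_N|` on the projected span (the constant
#' body height `h`) and skin friction
#' `F_T = -1/2 rho c_t P l v_T |v|` on the local elliptical cross-section
#' perimeter `P`.  This R implementation treats the link velocity as uniform
#' along the link (no spin term) and is the reference form used in tests;
#' the simulator integrates the same force density along each link by Gauss
#' quadrature, which additionally yields the spin torque.
#'
#' @param velocity Length-2 link velocity vector, m/s (world frame).
#' @param angle Link orientation, radians.
#' @param width Local body width, m.
#' @param height Body height, m.
#' @param len Link length, m.
#' @param fluid A [fluid_params()].
#' @return Length-2 force vector, N (world frame).
#' @export
taylor_force <- function(velocity, angle, width, height, len,
                         fluid = fluid_params()) {
  stopifnot(length(velocity) == 2, all(is.finite(velocity)))
  e <- c(cos(angle), sin(angle))
  n <- c(-sin(angle), cos(angle))
  v_t <- sum(velocity * e)
  v_n <- sum(velocity * n)
  speed <- sqrt(v_t^2 + v_n^2)
  perim <- ellipse_perimeter(width / 2, height / 2)
  f_n <- -0.5 * fluid$rho * fluid$c_n * height * len * v_n * abs(v_n)
  f_t <- -0.5 * fluid$rho * fluid$c_t * perim * len * v_t * speed
  f_t * e + f_n * n
}
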