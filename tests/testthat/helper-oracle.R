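# Independent Euler-Lagrange oracle for a free planar chain of rigid
# links with a joint bending potential.  The equations of motion are
# derived numerically from the kinetic energy: link-centre velocities come
# from a complex-step derivative of the position map along the velocity
# direction, and all configuration derivatives use Richardson-extrapolated
# central differences.  No part of the hand-derived mass-matrix/Coriolis
# algebra of the package is reused.

# link centre positions (complex-capable) for q = (xh, yh, phi_1..phi_n)
chain_positions <- function(body, q) {
  n <- body$n; ell <- body$ell
  phi <- q[3:(n + 2)]
  ex <- cos(phi); ey <- sin(phi)
  px <- q[1] + ell * cumsum(ex) - 0.5 * ell * ex
  py <- q[2] + ell * cumsum(ey) - 0.5 * ell * ey
  list(x = px, y = py)
}

# kinetic energy T(q, qd); velocities via complex step along qd
chain_kinetic <- function(body, q, qd) {
  h <- 1e-100
  p <- chain_positions(body, q + (0+1i) * h * qd)
  vx <- Im(p$x) / h; vy <- Im(p$y) / h
  n <- body$n
  omega <- qd[3:(n + 2)]
  0.5 * sum(body$mass * (vx^2 + vy^2)) + 0.5 * sum(body$inertia * omega^2)
}

# Richardson-extrapolated central difference of f at x along e_k
fd_partial <- function(f, x, k, h = 1e-3) {
  d <- function(hh) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + hh; xm[k] <- xm[k] - hh
    (f(xp) - f(xm)) / (2 * hh)
  }
  (4 * d(h / 2) - d(h)) / 3
}

chain_bending_energy <- function(body, q, k_b) {
  phi <- q[3:(body$n + 2)]
  0.5 * k_b * sum(diff(phi)^2)
}

# generalized accelerations from the numeric Euler-Lagrange equations
oracle_accelerations <- function(body, q, qd, k_b = 0) {
  nq <- length(q)
  Tq <- function(qq) chain_kinetic(body, qq, qd)
  # mass matrix by polarization of the quadratic form T(q, .)
  M <- matrix(0, nq, nq)
  basis <- diag(nq)
  Te <- vapply(seq_len(nq), function(i) chain_kinetic(body, q, basis[, i]),
               numeric(1))
  for (i in seq_len(nq)) {
    for (j in i:nq) {
      Tij <- chain_kinetic(body, q, basis[, i] + basis[, j])
      M[i, j] <- M[j, i] <- Tij - Te[i] - Te[j]
    }
  }
  # dM/dq_k contracted with qd twice, and dT/dq
  Mdotqd <- numeric(nq)
  dTdq <- vapply(seq_len(nq), function(k) fd_partial(Tq, q, k), numeric(1))
  for (k in seq_len(nq)) {
    dMk <- fd_partial(function(qq) {
      Mk <- matrix(0, nq, nq)
      Tek <- vapply(seq_len(nq), function(i) {
        chain_kinetic(body, qq, basis[, i])
      }, numeric(1))
      for (i in seq_len(nq)) {
        for (j in seq_len(nq)) {
          Mk[i, j] <- chain_kinetic(body, qq, basis[, i] + basis[, j]) -
            Tek[i] - Tek[j]
        }
      }
      Mk
    }, q, k)
    Mdotqd <- Mdotqd + dMk %*% qd * qd[k]
  }
  Q <- -vapply(seq_len(nq), function(k) {
    fd_partial(function(qq) chain_bending_energy(body, qq, k_b), q, k)
  }, numeric(1))
  solve(M, Q + dTdq - as.numeric(Mdotqd))
}
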