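# Angle-based feature series: angle of flight, angular velocity and
# acceleration per projection plane, and the orthogonal velocity components.

# Displacement steps of a coordinate matrix, with zero-length steps dropped
# (degenerate-step policy: a stationary frame defines no direction, so the
# step is removed from the series rather than imputed). Returns the retained
# displacement vectors, their start times and their own durations.
path_steps <- function(P, t, eps = 1e-12) {
  d <- diff(P)
  len <- sqrt(rowSums(d^2))
  keep <- len > eps
  list(d = d[keep, , drop = FALSE], len = len[keep],
       t0 = t[-length(t)][keep], dt = diff(t)[keep])
}

#' Angle of flight
#'
#' The turning angle between consecutive displacement vectors,
#' \eqn{\alpha_i = \arccos(v_i \cdot v_{i+1} / (|v_i||v_{i+1}|))}, in
#' radians within \[0, pi\]: 0 for continued straight motion, pi for an
#' exact reversal. The arccos argument is clamped to \[-1, 1\] for
#' floating-point safety; zero-length displacements are dropped first.
#'
#' @param seg a `segment` (or any object with `$xyz`, `$t`) with >= 3
#'   samples.
#' @param dims integer columns selecting a projection (default all three).
#' @return list with `alpha` (radians), `dt` (time between consecutive
#'   displacement starts) and `t0` (start time of the earlier displacement).
#' @export
angle_of_flight <- function(seg, dims = 1:3) {
  st <- path_steps(seg$xyz[, dims, drop = FALSE], seg$t)
  m <- nrow(st$d)
  if (m < 2L)
    return(list(alpha = numeric(0), dt = numeric(0), t0 = numeric(0)))
  i <- seq_len(m - 1L)
  dots <- rowSums(st$d[i, , drop = FALSE] * st$d[i + 1L, , drop = FALSE])
  ca <- dots / (st$len[i] * st$len[i + 1L])
  list(alpha = acos(pmin(1, pmax(-1, ca))),
       dt = st$t0[i + 1L] - st$t0[i],
       t0 = st$t0[i])
}

#' Angular velocity and acceleration per projection
#'
#' Four variants each: the projections to the X-Y, Y-Z and X-Z planes and
#' the full 3D path. Angular velocity is the angle of flight divided by the
#' elapsed time between the two displacements; angular acceleration is its
#' forward difference over time.
#'
#' @param seg a `segment`.
#' @return named list of 8 series: `angvel_XY`, `angvel_YZ`, `angvel_XZ`,
#'   `angvel_3D`, `angacc_XY`, `angacc_YZ`, `angacc_XZ`, `angacc_3D`.
#' @export
angular_rates <- function(seg) {
  planes <- list(XY = 1:2, YZ = 2:3, XZ = c(1L, 3L), `3D` = 1:3)
  out <- list()
  for (p in names(planes)) {
    af <- angle_of_flight(seg, planes[[p]])
    av <- af$alpha / af$dt
    aa <- if (length(av) >= 2L) diff(av) / diff(af$t0) else numeric(0)
    out[[paste0("angvel_", p)]] <- av
    out[[paste0("angacc_", p)]] <- aa
  }
  out
}

#' Orthogonal components of velocity
#'
#' Decomposes the instantaneous velocity into persistence (tendency to keep
#' heading tangential to the path), turning and inclination components.
#' Each displacement is converted to spherical coordinates
#' (`rho`, azimuth `theta`, polar angle `phi`); the angle increments
#' `Theta_i = theta_{i+1} - theta_i` and `Phi_i = phi_{i+1} - phi_i`
#' together with the step speed `v_i = rho_i / (t_{i+1} - t_i)` give
#' \deqn{P_i = v_i \sin\Phi_i \cos\Theta_i,\quad
#'       T_i = v_i \sin\Phi_i \sin\Theta_i,\quad
#'       I_i = v_i \cos\Phi_i,}
#' so \eqn{P_i^2 + T_i^2 + I_i^2 = v_i^2} identically. Zero-length
#' displacements are dropped (degenerate-step policy). The azimuth uses
#' `atan2`, the quadrant-correct form of the azimuthal arctangent.
#'
#' @param seg a `segment` with >= 3 samples.
#' @return named list of series `pvel`, `tvel`, `ivel` (and `v`, the step
#'   speeds they decompose).
#' @export
orthogonal_velocities <- function(seg) {
  st <- path_steps(seg$xyz, seg$t)
  m <- nrow(st$d)
  if (m < 2L) {
    e <- numeric(0)
    return(list(pvel = e, tvel = e, ivel = e, v = e))
  }
  theta <- atan2(st$d[, 2L], st$d[, 1L])
  phi <- acos(pmin(1, pmax(-1, st$d[, 3L] / st$len)))
  v <- st$len / st$dt
  i <- seq_len(m - 1L)
  Theta <- theta[i + 1L] - theta[i]
  Phi <- phi[i + 1L] - phi[i]
  list(pvel = v[i] * sin(Phi) * cos(Theta),
       tvel = v[i] * sin(Phi) * sin(Theta),
       ivel = v[i] * cos(Phi),
       v = v[i])
}
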