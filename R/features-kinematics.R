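#' Kinematic feature series of a segment
#'
#' Axial velocity, acceleration and jerk along each axis via second-order
#' central finite differences (one-sided at the boundaries), plus the
#' unsigned 3D speed and its signed derivatives. Raw signed 3D velocity is
#' not exposed — an insect only flies forward, so speed carries the
#' information — while accelerations and jerks keep their sign:
#' `raccel = d|v|/dt` (radial acceleration) and `rjerk = d(raccel)/dt`
#' capture all three components at once, unlike the axial series.
#'
#' @param seg a `segment` with at least 5 samples (the jerk stencil).
#' @return named list of 12 numeric series (one value per sample):
#'   `speed`, `raccel`, `rjerk`, `vx`, `vy`, `vz`, `ax`, `ay`, `az`,
#'   `jx`, `jy`, `jz`.
#' @export
kinematics <- function(seg) {
  n <- length(seg$t)
  if (n < 5L)
    stopf("degenerate segment '%s': %d samples, need >= 5", seg$segment_id, n)
  t <- seg$t
  v <- apply(seg$xyz, 2L, finite_diff, t = t)
  a <- apply(v, 2L, finite_diff, t = t)
  j <- apply(a, 2L, finite_diff, t = t)
  speed <- sqrt(rowSums(v^2))
  raccel <- finite_diff(speed, t)
  rjerk <- finite_diff(raccel, t)
  list(speed = speed, raccel = raccel, rjerk = rjerk,
       vx = v[, 1L], vy = v[, 2L], vz = v[, 3L],
       ax = a[, 1L], ay = a[, 2L], az = a[, 3L],
       jx = j[, 1L], jy = j[, 2L], jz = j[, 3L])
}
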