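#' Second-order finite-difference derivative
#'
#' Three-point Lagrange differentiation: central stencils on interior
#' points, one-sided second-order stencils at the two boundary points.
#' Handles non-uniform time steps; exact for quadratics.
#'
#' @param y numeric vector of samples.
#' @param t numeric vector of strictly increasing times, same length.
#' @return numeric vector `dy/dt` of the same length.
#' @export
finite_diff <- function(y, t) {
  n <- length(y)
  stopifnot(length(t) == n, n >= 3L)
  # derivative at time tt from three points (ta,ya),(tb,yb),(tc,yc)
  d3 <- function(tt, ta, tb, tc, ya, yb, yc) {
    ya * (2 * tt - tb - tc) / ((ta - tb) * (ta - tc)) +
      yb * (2 * tt - ta - tc) / ((tb - ta) * (tb - tc)) +
      yc * (2 * tt - ta - tb) / ((tc - ta) * (tc - tb))
  }
  i <- 2:(n - 1L)
  out <- numeric(n)
  out[i] <- d3(t[i], t[i - 1L], t[i], t[i + 1L], y[i - 1L], y[i], y[i + 1L])
  out[1L] <- d3(t[1L], t[1L], t[2L], t[3L], y[1L], y[2L], y[3L])
  out[n] <- d3(t[n], t[n - 2L], t[n - 1L], t[n], y[n - 2L], y[n - 1L], y[n])
  out
}

#' First-order forward-difference rate of change
#'
#' \eqn{\dot a_i = (a_{i+1} - a_i) / (t_{i+1} - t_i)}; length shrinks by one.
#' Used by the planar curvature and angular-rate features, which are defined
#' on forward differences.
#'
#' @param a numeric vector.
#' @param t times, same length as `a`.
#' @return numeric vector of length `length(a) - 1`.
#' @export
forward_diff <- function(a, t) {
  stopifnot(length(a) == length(t), length(a) >= 2L)
  diff(a) / diff(t)
}
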