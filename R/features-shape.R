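# Whole-segment shape descriptors: straightness, centroid distance,
# planar curvature, fractal dimension.

#' Straightness (tortuosity) of a segment
#'
#' Ratio of the distance actually travelled to the straight-line chord
#' between start and end,
#' \eqn{S = \sum_i |p_{i+1}-p_i| \, / \, |p_N - p_0| \ge 1};
#' exactly 1 for collinear monotone motion.
#'
#' @param seg a `segment`.
#' @return scalar `S`, or `NA` when start and end coincide (chord 0;
#'   resolved by the imputation policy at matrix assembly).
#' @export
straightness <- function(seg) {
  P <- seg$xyz
  path <- sum(sqrt(rowSums(diff(P)^2)))
  chord <- sqrt(sum((P[nrow(P), ] - P[1L, ])^2))
  if (chord == 0) return(NA_real_)
  path / chord
}

#' Centroid distance function
#'
#' Distance of each sample to the segment centroid
#' \eqn{C_i = |p_i - \bar p|}. Constant for smooth circular motion;
#' variable under sudden direction changes.
#'
#' @param seg a `segment`.
#' @return numeric series of length `nrow(seg$xyz)`.
#' @export
centroid_distance <- function(seg) {
  P <- seg$xyz
  ctr <- colMeans(P)
  sqrt(rowSums((P - matrix(ctr, nrow(P), 3L, byrow = TRUE))^2))
}

# signed planar curvature series on a 2D projection, forward differences:
#   k_i = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)
# steps with zero planar speed are dropped (degenerate-step policy)
curvature_series <- function(xy, t) {
  n <- nrow(xy)
  if (n < 3L) return(numeric(0))
  xd <- forward_diff(xy[, 1L], t)
  yd <- forward_diff(xy[, 2L], t)
  t1 <- t[-length(t)]
  xdd <- forward_diff(xd, t1)
  ydd <- forward_diff(yd, t1)
  i <- seq_len(n - 2L)
  den <- (xd[i]^2 + yd[i]^2)^1.5
  k <- (xd[i] * ydd - yd[i] * xdd) / den
  k[den > 0]
}

#' Planar curvature summaries
#'
#' Signed curvature of the projections onto the X-Y, Y-Z and X-Z planes,
#' from forward-difference derivatives, summarised by mean and standard
#' deviation per plane.
#'
#' @param seg a `segment` with >= 3 samples.
#' @return named list of six scalars `curv_<plane>_mean`, `curv_<plane>_sd`;
#'   `NA` sentinels when a projection collapses.
#' @export
curvature <- function(seg) {
  planes <- list(XY = 1:2, YZ = 2:3, XZ = c(1L, 3L))
  out <- list()
  for (p in names(planes)) {
    k <- curvature_series(seg$xyz[, planes[[p]], drop = FALSE], seg$t)
    out[[paste0("curv_", p, "_mean")]] <-
      if (length(k)) mean(k) else NA_real_
    out[[paste0("curv_", p, "_sd")]] <-
      if (length(k) >= 2L) stats::sd(k) else NA_real_
  }
  out
}

#' Fractal dimension of a path
#'
#' Self-similarity dimension \eqn{d = \log n / \log(1/S)} with `n` the
#' total 3D path length and `1/S` the diagonal of the axis-aligned bounding
#' box. A straight path gives exactly 1; a dense planar Brownian-like path
#' approaches 2. The measure inherits the unit dependence of its
#' definition (lengths in metres); a bounding-box diagonal of exactly 1
#' makes the denominator vanish and yields the `NA` sentinel.
#'
#' @param seg a `segment` (or any object with `$xyz`).
#' @return scalar dimension, or `NA` for degenerate geometry.
#' @export
fractal_dimension <- function(seg) {
  P <- seg$xyz
  n <- sum(sqrt(rowSums(diff(P)^2)))
  diag_len <- sqrt(sum(apply(P, 2L, function(c) diff(range(c)))^2))
  if (n <= 0 || diag_len <= 0 || abs(log(diag_len)) < 1e-12)
    return(NA_real_)
  log(n) / log(diag_len)
}
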