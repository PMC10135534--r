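# Incremental 3D convex hull (volume and surface area).
#
# Small point sets (tens of samples per segment), so an incremental
# construction with vectorised visibility tests is adequate in plain R.
# Degenerate sets follow the package's conventions: coplanar points have
# volume 0 and surface area equal to twice the planar hull area (both faces
# of the flat polyhedron); collinear or coincident sets have volume and
# area 0.

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# cross products of the rows of two matrices
cross3_rows <- function(U, V) {
  cbind(U[, 2] * V[, 3] - U[, 3] * V[, 2],
        U[, 3] * V[, 1] - U[, 1] * V[, 3],
        U[, 1] * V[, 2] - U[, 2] * V[, 1])
}

#' 3D convex hull volume and surface area
#'
#' @param P numeric matrix (n x 3) of points in metres.
#' @return list with `volume` (m^3) and `area` (m^2).
#' @export
convex_hull_3d <- function(P) {
  P <- unique(as.matrix(P))
  n <- nrow(P)
  scale <- max(apply(P, 2L, function(c) diff(range(c))), 0)
  if (n < 3L || scale == 0)
    return(list(volume = 0, area = 0))
  eps <- 1e-10 * scale

  # initial simplex: farthest point pair seed, then farthest from the
  # line, then farthest from the plane
  d1 <- which.max(rowSums((P - P[rep(1L, n), , drop = FALSE])^2))
  a <- P[1L, ]; b <- P[d1, ]
  ab <- b - a
  rel <- P - matrix(a, n, 3L, byrow = TRUE)
  lin_d <- sqrt(rowSums(cross3_rows(matrix(ab, n, 3L, byrow = TRUE), rel)^2))
  if (max(lin_d) <= eps * sqrt(sum(ab^2)))
    return(list(volume = 0, area = 0))           # collinear
  cpt <- which.max(lin_d)
  nrm <- cross3(ab, P[cpt, ] - a)
  pl_d <- as.numeric(rel %*% nrm) / sqrt(sum(nrm^2))
  if (max(abs(pl_d)) <= eps) {                   # coplanar
    basis <- svd(scale(P, center = TRUE, scale = FALSE))$v[, 1:2]
    Q <- P %*% basis
    h <- grDevices::chull(Q[, 1L], Q[, 2L])
    hx <- Q[h, 1L]; hy <- Q[h, 2L]
    area2d <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
    return(list(volume = 0, area = 2 * area2d))
  }
  dpt <- which.max(abs(pl_d))

  verts <- c(1L, d1, cpt, dpt)
  centroid <- colMeans(P[verts, , drop = FALSE])
  # faces: index triples FV, outward normals FN, a base point FP
  FV <- rbind(verts[c(1, 2, 3)], verts[c(1, 2, 4)],
              verts[c(1, 3, 4)], verts[c(2, 3, 4)])
  FN <- cross3_rows(P[FV[, 2], , drop = FALSE] - P[FV[, 1], , drop = FALSE],
                    P[FV[, 3], , drop = FALSE] - P[FV[, 1], , drop = FALSE])
  flip <- rowSums(FN * (P[FV[, 1], , drop = FALSE] -
                          matrix(centroid, 4L, 3L, byrow = TRUE))) < 0
  FN[flip, ] <- -FN[flip, ]

  for (pi in setdiff(seq_len(n), verts)) {
    p <- P[pi, ]
    FP <- P[FV[, 1], , drop = FALSE]
    vis <- rowSums(FN * (matrix(p, nrow(FV), 3L, byrow = TRUE) - FP)) >
      eps * sqrt(rowSums(FN^2))
    if (!any(vis)) next
    # horizon: edges of visible faces not shared between two visible faces
    vv <- FV[vis, , drop = FALSE]
    e1 <- rbind(vv[, c(1, 2), drop = FALSE], vv[, c(2, 3), drop = FALSE],
                vv[, c(3, 1), drop = FALSE])
    ekey <- pmin(e1[, 1], e1[, 2]) * (n + 1) + pmax(e1[, 1], e1[, 2])
    horizon <- e1[!(ekey %in% ekey[duplicated(ekey)]), , drop = FALSE]
    FV <- FV[!vis, , drop = FALSE]
    FN <- FN[!vis, , drop = FALSE]
    inner <- colMeans(P[unique(c(as.vector(FV), pi)), , drop = FALSE])
    if (nrow(horizon)) {
      A <- P[horizon[, 1], , drop = FALSE]
      B <- P[horizon[, 2], , drop = FALSE]
      NN <- cross3_rows(B - A, matrix(p, nrow(A), 3L, byrow = TRUE) - A)
      ok <- sqrt(rowSums(NN^2)) > eps^2
      flip <- rowSums(NN * (A - matrix(inner, nrow(A), 3L, byrow = TRUE))) < 0
      NN[flip, ] <- -NN[flip, ]
      FV <- rbind(FV, cbind(horizon[ok, , drop = FALSE], pi))
      FN <- rbind(FN, NN[ok, , drop = FALSE])
    }
  }

  ctr <- colMeans(P[unique(as.vector(FV)), , drop = FALSE])
  A <- P[FV[, 1], , drop = FALSE]
  B <- P[FV[, 2], , drop = FALSE]
  C <- P[FV[, 3], , drop = FALSE]
  CM <- matrix(ctr, nrow(FV), 3L, byrow = TRUE)
  vol <- sum(abs(rowSums((A - CM) * cross3_rows(B - CM, C - CM)))) / 6
  area <- sum(sqrt(rowSums(cross3_rows(B - A, C - A)^2))) / 2
  list(volume = vol, area = area)
}

#' Convex hull metrics of a segment
#'
#' Volume and surface area of the smallest convex polyhedron bounding the
#' segment's points — shape descriptors of the space a flight occupies.
#'
#' @param seg a `segment` with >= 4 points.
#' @return named list `hull_volume` (m^3), `hull_area` (m^2); `NA` sentinels
#'   when all points coincide.
#' @export
convex_hull_metrics <- function(seg) {
  P <- seg$xyz
  if (nrow(unique(P)) < 2L)
    return(list(hull_volume = NA_real_, hull_area = NA_real_))
  h <- convex_hull_3d(P)
  list(hull_volume = h$volume, hull_area = h$area)
}
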