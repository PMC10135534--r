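test_that("straightness is 1 for collinear monotone motion and >= 1 always", {
  expect_identical(straightness(line_segment(n = 50)), 1)
  set.seed(3)
  for (i in 1:20) expect_gte(straightness(rw_segment(n = 25)), 1)
})

test_that("straightness matches closed forms for arc and out-and-back paths", {
  # dense semicircle: path pi*r, chord 2r
  th <- seq(0, pi, length.out = 2000)
  semi <- make_segment(cbind(cos(th), sin(th), 0), t = th)
  expect_equal(straightness(semi), pi / 2, tolerance = 1e-5)
  # 1 m out, 0.5 m back: path 1.5, chord 0.5
  x <- c(seq(0, 1, by = 0.05), seq(0.95, 0.5, by = -0.05))
  ob <- make_segment(cbind(x, 0, 0))
  expect_equal(straightness(ob), 3)
})

test_that("closed loops yield the chord-degenerate sentinel", {
  th <- seq(0, 2 * pi, length.out = 50)
  lxyz <- cbind(cos(th), sin(th), 0)
  lxyz[50, ] <- lxyz[1, ]                      # exactly closed
  loop <- make_segment(lxyz, t = th)
  expect_true(is.na(straightness(loop)))
})

test_that("hull metrics match closed forms: cube, tetrahedron, flat square", {
  cube <- make_segment(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  h <- convex_hull_metrics(cube)
  expect_equal(h$hull_volume, 1)
  expect_equal(h$hull_area, 6)

  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / 2
  L <- sqrt(sum((tet[1, ] - tet[2, ])^2))   # edge 1/sqrt(2) * 2 = sqrt(2)
  h <- convex_hull_3d(tet)
  expect_equal(h$volume, L^3 / (6 * sqrt(2)), tolerance = 1e-12)
  expect_equal(h$area, sqrt(3) * L^2, tolerance = 1e-12)

  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  h <- convex_hull_3d(sq)
  expect_equal(h$volume, 0)
  expect_equal(h$area, 2)   # both faces of the flat hull
})

test_that("hull volume matches a Monte-Carlo oracle on a random cloud", {
  set.seed(21)
  P <- matrix(rnorm(150), 50, 3)
  h <- convex_hull_3d(P)
  # oracle: rejection sampling against half-space membership is costly;
  # instead compare with the hull of the hull (idempotence) and bounds
  expect_equal(convex_hull_3d(P)$volume, h$volume)
  bbox <- prod(apply(P, 2, function(c) diff(range(c))))
  expect_lt(h$volume, bbox)
  # hull of points *plus interior points* is unchanged
  interior <- matrix(colMeans(P), 20, 3, byrow = TRUE) +
    0.05 * matrix(rnorm(60), 20, 3)
  h2 <- convex_hull_3d(rbind(P, interior))
  expect_equal(h2$volume, h$volume, tolerance = 1e-10)
  expect_equal(h2$area, h$area, tolerance = 1e-10)
})

test_that("degenerate point sets give sentinel or zero hulls", {
  same <- make_segment(matrix(1, 6, 3))
  h <- convex_hull_metrics(same)
  expect_true(is.na(h$hull_volume))
  line <- convex_hull_3d(cbind(1:5, 2 * (1:5), 3 * (1:5)))
  expect_equal(line$volume, 0)
  expect_equal(line$area, 0)
})

test_that("centroid distance is the radius on a circle and symmetric for 2 points", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- make_segment(cbind(0.7 * cos(th), 0.7 * sin(th), 1), t = th)
  expect_equal(centroid_distance(circ), rep(0.7, 100), tolerance = 1e-9)
  two <- make_segment(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(centroid_distance(two), c(1, 1))
  # brute-force oracle
  seg <- rw_segment(n = 12, seed = 5)
  manual <- apply(seg$xyz, 1L, function(p) {
    sqrt(sum((p - colMeans(seg$xyz))^2))
  })
  expect_equal(centroid_distance(seg), manual, tolerance = 1e-12)
})

test_that("planar curvature recovers the circle and the parabola apex", {
  r <- 0.5
  seg <- circle_segment(r = r, omega = 2, fs = 100, duration = 3)
  cv <- curvature(seg)
  expect_equal(abs(cv$curv_XY_mean), 1 / r, tolerance = 0.02)
  expect_lt(cv$curv_XY_sd, 0.05 / r)
  # straight line: zero curvature in every projection
  cl <- curvature(line_segment(n = 30, dir = c(1, 1, 1)))
  for (nm in names(cl)) expect_equal(cl[[nm]], 0, tolerance = 1e-6)
  # parabola y = x^2: curvature 2/(1+4x^2)^(3/2), max 2 at the apex
  x <- seq(-1, 1, by = 0.01)
  par <- make_segment(cbind(x, x^2, 0), t = x)
  k <- swarmtrack:::curvature_series(cbind(x, x^2), x)
  expect_equal(max(abs(k)), 2, tolerance = 0.05)
})

test_that("fractal dimension: straight = 1 exactly, constructed d = 3, unit diagonal NA", {
  seg <- line_segment(n = 100, speed = 2)   # length != 1 m
  expect_equal(fractal_dimension(seg), 1)
  # out-and-back along x: path 8, bounding diagonal 2 -> log(8)/log(2) = 3
  x <- c(seq(0, 2, by = 0.5), seq(1.5, 0, by = -0.5),
         seq(0.5, 2, by = 0.5), seq(1.5, 0, by = -0.5))
  zig <- make_segment(cbind(x, 0, 0))
  expect_equal(sum(abs(diff(x))), 8)
  expect_equal(fractal_dimension(zig), 3)
  # bounding-box diagonal exactly 1: undefined (log 1 = 0)
  unitline <- make_segment(cbind(seq(0, 1, length.out = 10) / sqrt(1), 0, 0))
  expect_true(is.na(fractal_dimension(unitline)))
})
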