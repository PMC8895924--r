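# geometry primitives against closed forms and brute-force oracles

test_that("fit_sphere recovers exact and noisy spheres", {
  # octahedron on the unit sphere
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  fit <- fit_sphere(oct)
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
  expect_lt(fit$rms_residual, 1e-12)

  # exact recovery for an arbitrary sphere
  set.seed(101)
  center <- c(3, -2, 7); radius <- 23
  u <- matrix(rnorm(60), ncol = 3)
  pts <- sweep(radius * u / sqrt(rowSums(u^2)), 2, center, `+`)
  fit <- fit_sphere(pts)
  expect_equal(fit$center, center, tolerance = 1e-9)
  expect_equal(fit$radius, radius, tolerance = 1e-9)

  # Monte-Carlo: jittered samples, sigma = 0.5
  set.seed(102)
  res <- replicate(100, {
    u <- matrix(rnorm(60), ncol = 3)
    pts <- sweep(radius * u / sqrt(rowSums(u^2)), 2, center, `+`) +
      matrix(rnorm(60, sd = 0.5), ncol = 3)
    f <- fit_sphere(pts)
    c(f$radius, f$rms_residual)
  })
  expect_true(all(abs(res[1, ] - radius) < 0.5))
  expect_equal(mean(res[2, ]), 0.5, tolerance = 0.15)

  # coplanar points are a degeneracy, not a fit
  flat <- cbind(matrix(rnorm(20), ncol = 2), 0)
  expect_error(fit_sphere(flat), "coplanar|degenerate")
})

test_that("fit_line matches principal-direction oracle and orients last-to-first", {
  # collinear points on the z axis, ordered distal (negative z) last
  pts <- cbind(0, 0, seq(10, -10, length.out = 7))
  ax <- fit_line(pts)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-12)
  expect_gt(ax$direction[3], 0)                 # points toward the first point
  expect_equal(ax$point, c(0, 0, 0), tolerance = 1e-12)

  # two points define the line through both
  ax2 <- fit_line(rbind(c(1, 1, 1), c(2, 3, 5)))
  expect_equal(ax2$direction, (c(1, 1, 1) - c(2, 3, 5)) / sqrt(21),
               tolerance = 1e-12)

  # arc segment: direction equals the principal direction of a dense
  # resampling of the same arc (eigen-decomposition oracle)
  R <- 1200
  th <- seq(0, 100 / R, length.out = 11)
  arc <- cbind(0, R - R * cos(th), -R * sin(th))
  ax3 <- fit_line(arc)
  th_dense <- seq(0, 100 / R, length.out = 1e5)
  dense <- cbind(0, R - R * cos(th_dense), -R * sin(th_dense))
  sc <- eigen(cov(dense))$vectors[, 1]
  if (sc[3] < 0) sc <- -sc
  # same arc sampled at 11 vs 1e5 stations: directions agree to ~(h/R)^2
  expect_lt(angle_between(ax3$direction, sc) * pi / 180, 2e-5)

  expect_error(fit_line(rbind(c(1, 2, 3), c(1, 2, 3))), "identical")
})

test_that("skew_distance: closed cases, parallel flag, brute-force grid oracle", {
  a <- fm_axis(c(0, 0, 0), c(1, 0, 0))
  b <- fm_axis(c(0, 0, 5), c(0, 1, 0))
  sk <- skew_distance(a, b)
  expect_false(sk$parallel_flag)
  expect_equal(sk$distance, 5, tolerance = 1e-12)
  expect_equal(sk$point_on_line1, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(sk$point_on_line2, c(0, 0, 5), tolerance = 1e-12)
  expect_equal(sqrt(sum((sk$point_on_line1 - sk$point_on_line2)^2)),
               sk$distance, tolerance = 1e-9)

  # intersecting lines
  sk0 <- skew_distance(fm_axis(c(0, 0, 0), c(1, 0, 0)),
                       fm_axis(c(3, 0, 0), c(0, 1, 1)))
  expect_equal(sk0$distance, 0, tolerance = 1e-12)

  # parallel lines
  skp <- skew_distance(fm_axis(c(0, 0, 0), c(1, 0, 0)),
                       fm_axis(c(2, 3, 4), c(-1, 0, 0)))
  expect_true(skp$parallel_flag)
  expect_equal(skp$distance, 5, tolerance = 1e-12)

  # random pairs vs the 2000x2000 grid oracle
  set.seed(103)
  for (i in 1:10) {
    a <- fm_axis(rnorm(3, sd = 5), rnorm(3))
    b <- fm_axis(rnorm(3, sd = 5), rnorm(3))
    sk <- skew_distance(a, b)
    expect_equal(sk$distance, grid_line_distance(a, b), tolerance = 1e-3)
  }
})

test_that("skew_distance is symmetric and rigid-invariant", {
  set.seed(104)
  for (i in 1:20) {
    a <- fm_axis(rnorm(3, sd = 10), rnorm(3))
    b <- fm_axis(rnorm(3, sd = 10), rnorm(3))
    d_ab <- skew_distance(a, b)$distance
    expect_equal(skew_distance(b, a)$distance, d_ab, tolerance = 1e-9)
    rig <- random_rigid()
    d_rig <- skew_distance(apply_rigid_axis(a, rig),
                           apply_rigid_axis(b, rig))$distance
    expect_equal(d_rig, d_ab, tolerance = 1e-9)
  }
})

test_that("angle_between handles orthogonal, equal and clamping cases", {
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90, tolerance = 1e-12)
  expect_equal(angle_between(c(1, 0, 0), c(1, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(angle_between(c(1, 0, 0), c(-1, 1e-9, 0)), 180, tolerance = 1e-6)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("projected_angle matches the rotation-matrix oracle and is antisymmetric", {
  u <- c(cos(pi / 9), sin(pi / 9), 0.5)
  expect_equal(projected_angle(u, c(1, 0, 0), c(0, 0, 1)), 20, tolerance = 1e-9)
  expect_equal(projected_angle(u, u, c(0, 0, 1)), 0, tolerance = 1e-9)

  set.seed(105)
  for (i in 1:50) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    # v in the plane perpendicular to n
    v0 <- rnorm(3); v <- v0 - sum(v0 * n) * n
    theta <- runif(1, -179, 179)
    # oracle: construct u by rotating v about n by a known angle
    th <- theta * pi / 180
    u <- v * cos(th) + pracma_cross(n, v) * sin(th) + rnorm(1) * n
    expect_equal(projected_angle(u, v, n), theta, tolerance = 1e-9)
    expect_equal(projected_angle(v, u, n), -projected_angle(u, v, n),
                 tolerance = 1e-9)
    # flipping the sign reference flips the sign
    expect_equal(projected_angle(u, v, n, signed_about = -n), -theta,
                 tolerance = 1e-9)
  }

  expect_error(projected_angle(c(0, 0, 1), c(1, 0, 0), c(0, 0, 1)),
               "degenerate")
})

test_that("circumradius closed forms and one-circle property", {
  r1 <- circumradius(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0))
  expect_equal(r1$radius, 1, tolerance = 1e-12)
  expect_equal(r1$center, c(1, 0, 0), tolerance = 1e-12)

  # equilateral triangle, side 1: R = 1/sqrt(3) (abc / 4K oracle)
  eq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(circumradius(eq[1, ], eq[2, ], eq[3, ])$radius, 1 / sqrt(3),
               tolerance = 1e-12)

  # three samples of a 1200 mm arc
  R <- 1200
  th <- c(0.01, 0.1, 0.3)
  arc <- cbind(R * cos(th), R * sin(th), 0)
  expect_equal(circumradius(arc[1, ], arc[2, ], arc[3, ])$radius, R,
               tolerance = 1e-6)

  # any 3 distinct points of one random circle in 3D give its radius, and
  # the center is equidistant from all three
  set.seed(106)
  for (i in 1:20) {
    rad <- runif(1, 1, 2000)
    ctr <- rnorm(3, sd = 100)
    rig <- random_rigid()
    th <- sort(runif(3, 0, 2 * pi))
    pts <- t(apply(cbind(rad * cos(th), rad * sin(th), 0), 1,
                   function(p) rig$R %*% p + ctr))
    cc <- circumradius(pts[1, ], pts[2, ], pts[3, ])
    expect_equal(cc$radius, rad, tolerance = 1e-6 * rad)
    d <- sqrt(rowSums(sweep(pts, 2, cc$center)^2))
    expect_lt(max(d) - min(d), 1e-6)
  }

  expect_error(circumradius(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("max_deviation_point finds the sagitta and tie-breaks by index", {
  # sampled semicircle, chord = diameter: deviation 1 at the apex
  th <- seq(0, pi, length.out = 41)
  semi <- cbind(cos(th), sin(th), 0)
  md <- max_deviation_point(semi, c(1, 0, 0), c(-1, 0, 0))
  expect_equal(md$deviation, 1, tolerance = 1e-9)
  expect_equal(md$index, 21L)

  # all points on the chord: deviation 0, first index wins
  online <- cbind(seq(0, 1, length.out = 5), 0, 0)
  md0 <- max_deviation_point(online, c(0, 0, 0), c(1, 0, 0))
  expect_equal(md0$deviation, 0)
  expect_equal(md0$index, 1L)

  # dense arc: max deviation approximates the closed-form sagitta
  R <- 900; arc_angle <- 0.5
  th <- seq(-arc_angle / 2, arc_angle / 2, length.out = 2001)
  arc <- cbind(R * sin(th), R * cos(th), 0)
  md2 <- max_deviation_point(arc, arc[1, ], arc[2001, ])
  sagitta <- R * (1 - cos(arc_angle / 2))
  expect_equal(md2$deviation, sagitta, tolerance = 1e-4)
})
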