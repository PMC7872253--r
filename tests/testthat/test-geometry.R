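# Geometric primitives and least-squares fits against independent oracles.

test_that("plane_from_points reproduces canonical planes and rejects degenerate input", {
  pl <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_error(plane_from_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
  expect_error(plane_from_points(c(1, 2, 3), c(1, 2, 3), c(0, 1, 0)),
               "collinear|coincident")
})

test_that("plane_from_points matches the generator's stored cut-plane normal", {
  fem <- generate_femur(femur_params())
  lm <- fem$landmarks
  pl <- plane_from_points(lm$craniomedial, lm$caudomedial, lm$craniolateral)
  stored <- fem$truth$cut_plane_normals$a
  expect_lt(min(vnorm(pl$normal - stored), vnorm(pl$normal + stored)), 1e-9)
})

test_that("plane orientation is cyclic-invariant and flips under swaps", {
  set.seed(41)
  for (i in 1:10) {
    p <- matrix(rnorm(9, sd = 10), 3L)
    n1 <- plane_from_points(p[1, ], p[2, ], p[3, ])$normal
    n2 <- plane_from_points(p[2, ], p[3, ], p[1, ])$normal
    n3 <- plane_from_points(p[2, ], p[1, ], p[3, ])$normal
    expect_equal(n1, n2, tolerance = 1e-9)
    expect_equal(n1, -n3, tolerance = 1e-9)
  }
})

test_that("fit_sphere is exact on noiseless samples and refuses degenerate sets", {
  pts <- sample_sphere_points(100, c(1, 2, 3), 12, seed = 11)
  fit <- fit_sphere(pts)
  expect_equal(fit$center, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(fit$radius, 12, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
  expect_error(fit_sphere(pts[1:3, ]), "at least 4")
  flat <- cbind(matrix(rnorm(40), ncol = 2L), 0)
  expect_error(fit_sphere(flat), "coplanar")
})

test_that("fit_sphere on noisy data matches the multistart orthogonal-distance oracle", {
  pts <- sample_sphere_points(2000, c(1, 2, 3), 12, sd = 0.2, seed = 12)
  fit <- fit_sphere(pts)
  orc <- oracle_sphere_fit(pts)
  expect_lt(vnorm(fit$center - orc$center), 0.05)
  expect_lt(abs(fit$radius - orc$radius), 0.05)
})

test_that("fit_sphere centre error shrinks roughly as sigma/sqrt(n)", {
  errs <- sapply(c(200L, 3200L), function(n) {
    mean(sapply(1:6, function(s) {
      pts <- sample_sphere_points(n, c(0, 0, 0), 12, sd = 0.3, seed = 100 + s * 7 + n)
      vnorm(fit_sphere(pts)$center)
    }))
  })
  # 16x the points: expect about 4x smaller error; allow a loose factor
  expect_lt(errs[2L], errs[1L] / 2)
})

test_that("fit_axis recovers cylinder axes in arbitrary pose and flags isotropy", {
  cyl <- sample_cylinder_points(500, seed = 21)
  fa <- fit_axis(cyl)
  expect_lt(acos(min(1, abs(fa$direction[3L]))) * 180 / pi, 1e-4)
  expect_equal(fa$radius, 8, tolerance = 1e-6)

  R <- rotation_about(c(1, 2, 0), 37)
  fa2 <- fit_axis(cyl %*% t(R))
  true_dir <- drop(R %*% c(0, 0, 1))
  expect_lt(acos(min(1, abs(sum(fa2$direction * true_dir)))) * 180 / pi, 0.1)

  expect_error(fit_axis(sample_sphere_points(200, c(0, 0, 0), 10, seed = 3)),
               "anisotropy")
})

test_that("fit_axis direction error is < 1e-6 rad on noiseless cylinders across poses", {
  set.seed(77)
  for (i in 1:5) {
    R <- rotation_about(rnorm(3), runif(1, -180, 180))
    cyl <- sample_cylinder_points(800, radius = 6, half_len = 40,
                                  seed = 400 + i) %*% t(R)
    fa <- fit_axis(cyl)
    true_dir <- drop(R %*% c(0, 0, 1))
    expect_lt(acos(min(1, abs(sum(fa$direction * true_dir)))), 1e-6)
  }
})

test_that("closest_approach handles intersecting, offset and skew lines", {
  x_axis <- line3(c(0, 0, 0), c(1, 0, 0))
  y_axis <- line3(c(0, 0, 0), c(0, 1, 0))
  ca <- closest_approach(x_axis, y_axis)
  expect_equal(ca$distance, 0, tolerance = 1e-12)
  expect_equal(ca$point_a, c(0, 0, 0), tolerance = 1e-12)

  off <- line3(c(0, 0, 1), c(0, 1, 0))
  ca2 <- closest_approach(x_axis, off)
  expect_equal(ca2$distance, 1, tolerance = 1e-12)
  expect_equal(ca2$point_a, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ca2$point_b, c(0, 0, 1), tolerance = 1e-12)

  expect_error(closest_approach(x_axis, line3(c(0, 5, 0), c(1, 0, 0))),
               "parallel")
})

test_that("closest_approach agrees with the grid-search oracle and is symmetric", {
  set.seed(31)
  for (i in 1:5) {
    a <- line3(rnorm(3, sd = 5), rnorm(3))
    b <- line3(rnorm(3, sd = 5), rnorm(3))
    ca <- closest_approach(a, b)
    orc <- oracle_closest_approach(a, b)
    expect_lt(abs(ca$distance - orc$distance), 1e-6)
    sw <- closest_approach(b, a)
    expect_equal(sw$distance, ca$distance, tolerance = 1e-12)
    expect_equal(sw$point_a, ca$point_b, tolerance = 1e-9)
    expect_equal(sw$point_b, ca$point_a, tolerance = 1e-9)
  }
})

test_that("projected_angle follows the right-hand-rule sign and atan2 oracle", {
  expect_equal(projected_angle(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), -90)
  expect_equal(projected_angle(c(1, 2, 0.5), c(1, 2, 0.5), c(0, 0, 1)), 0)
  expect_error(projected_angle(c(0, 0, 2), c(1, 0, 0), c(0, 0, 1)),
               "undefined projection")
  set.seed(51)
  for (i in 1:20) {
    v <- rnorm(3); r <- rnorm(3); n <- rnorm(3)
    a1 <- projected_angle(v, r, n)
    expect_equal(a1, oracle_projected_angle(v, r, unitize(n)), tolerance = 1e-9)
    expect_equal(projected_angle(r, v, n), -a1, tolerance = 1e-9)
  }
})

test_that("rigid transforms validate rotations and compose with geometry", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "reflection")
  expect_error(rigid_transform(matrix(rnorm(9), 3L)), "orthogonal")
  tr <- random_rigid_transform(seed = 61)
  pl <- plane(c(1, 2, 3), c(0, 0, 1))
  p_on <- c(5, -4, 3)
  expect_lt(abs(plane_distance(apply_transform(tr, pl),
                               apply_transform(tr, p_on))), 1e-9)
})
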