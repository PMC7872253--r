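# Femoral frame construction and the alignment measurements.

test_that("femoral frame axes come out orthonormal with the documented conventions", {
  ax <- line3(c(0, 0, 0), c(0, 0, 1))
  fr <- build_femoral_frame(ax, c(20, 0, -100), c(-20, 0, -100), "right")
  expect_equal(fr$axis_ml, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$axis_cc, c(0, 1, 0), tolerance = 1e-12)
  M <- rbind(fr$axis_prox, fr$axis_ml, fr$axis_cc)
  expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-9)

  frL <- build_femoral_frame(ax, c(20, 0, -100), c(-20, 0, -100), "left")
  expect_equal(frL$axis_cc, c(0, -1, 0), tolerance = 1e-12)

  # transcondylar direction already orthogonal: ml is its exact normalization
  fr2 <- build_femoral_frame(ax, c(3, 4, 0), c(0, 0, 0), "right")
  expect_equal(fr2$axis_ml, c(0.6, 0.8, 0), tolerance = 1e-12)

  expect_error(build_femoral_frame(ax, c(0.1, 0, 50), c(-0.1, 0, -50), "right"),
               "ill-conditioned")
})

test_that("frame axes recover the generator frame after a random rigid pose", {
  fem <- generate_femur(femur_params())
  tr <- random_rigid_transform(seed = 83)
  mesh <- apply_transform(tr, fem$mesh)
  lm <- apply_transform(tr, fem$landmarks)
  mr <- measure_femur(mesh, lm$condyle_medial, lm$condyle_lateral, "right")
  for (axis in c("prox", "ml", "cc")) {
    truth_dir <- drop(tr$rotation %*% fem$truth$frame_axes[[axis]])
    got <- mr$frame[[paste0("axis_", axis)]]
    expect_lt(acos(min(1, sum(truth_dir * got))) * 180 / pi, 0.1)
  }
})

test_that("neck axis points from diaphysis toward head and validates input", {
  pts <- matrix(rep(c(0, 0, 5), 12), ncol = 3L, byrow = TRUE) +
    matrix(rnorm(36, sd = 0.01), ncol = 3L)
  na <- compute_neck_axis(c(0, 0, 10), pts)
  expect_equal(na$direction, c(0, 0, 1), tolerance = 0.01)
  expect_equal(na$point, c(0, 0, 10))
  expect_error(compute_neck_axis(c(0, 0, 10), pts[1:5, ]), "at least 10")
  coincident <- matrix(rep(c(0, 0, 10), 12), ncol = 3L, byrow = TRUE)
  expect_error(compute_neck_axis(c(0, 0, 10), coincident), "degenerate")
})

test_that("inclination and version reproduce constructed angles and limits", {
  ax <- line3(c(0, 0, 0), c(0, 0, 1))
  fr <- build_femoral_frame(ax, c(20, 0, -100), c(-20, 0, -100), "right")
  d135 <- c(sin(135 * pi / 180), 0, -cos(135 * pi / 180))
  expect_equal(compute_inclination(fr, line3(c(0, 0, 0), d135)), 135,
               tolerance = 1e-9)
  expect_equal(compute_inclination(fr, line3(c(0, 0, 0), c(0, 0, 1))), 180,
               tolerance = 1e-9)
  # neck in the frontal plane: no version
  expect_equal(compute_version(fr, line3(c(0, 0, 0), d135)), 0, tolerance = 1e-9)
})

test_that("neck length handles intersecting, coincident and synthetic axes", {
  diaph <- line3(c(0, 0, 0), c(0, 0, 1))
  neck <- line3(c(0, 0, 50) + 40 * unitize(c(1, 0, 1)), c(1, 0, 1))
  expect_equal(compute_neck_length(neck$point, neck, diaph), 40, tolerance = 1e-9)
  on_axis <- line3(c(0, 0, 30), c(1, 0, 0.5))
  expect_equal(compute_neck_length(c(0, 0, 30), on_axis, diaph), 0,
               tolerance = 1e-9)
  fem <- generate_femur(femur_params(neck_length = 35))
  tr <- fem$truth
  expect_equal(compute_neck_length(tr$head_center, tr$neck_axis,
                                   tr$diaphyseal_axis), 35, tolerance = 0.5)
})

test_that("acetabular diameter averages both sides and requires them", {
  am <- acetabular_diameter(left = list(cranial = c(0, 0, 0), caudal = c(22, 0, 0)),
                            right = list(cranial = c(0, 0, 0), caudal = c(0, 24, 0)))
  expect_equal(am$left_diameter, 22)
  expect_equal(am$right_diameter, 24)
  expect_equal(am$mean_diameter, 23)
  expect_error(acetabular_diameter(left = list(cranial = c(0, 0, 0),
                                               caudal = c(22, 0, 0))),
               "both sides")
})

test_that("mesh-based measurements are invariant under joint rigid transforms", {
  fem <- generate_femur(femur_params(version = 25, inclination = 140,
                                     neck_length = 38))
  base <- measure_femur(fem$mesh, fem$landmarks$condyle_medial,
                        fem$landmarks$condyle_lateral, "right")
  tr <- random_rigid_transform(seed = 97)
  posed <- measure_femur(apply_transform(tr, fem$mesh),
                         drop(apply_transform(tr, fem$landmarks$condyle_medial)),
                         drop(apply_transform(tr, fem$landmarks$condyle_lateral)),
                         "right")
  expect_lt(abs(posed$version - base$version), 1e-6)
  expect_lt(abs(posed$inclination - base$inclination), 1e-6)
  expect_lt(abs(posed$neck_length - base$neck_length), 1e-6)
})

test_that("mirroring a femur preserves |version|, inclination and neck length", {
  fem <- generate_femur(femur_params(version = 20))
  sag <- plane(c(0, 0, 0), c(0, 1, 0))
  mmesh <- reflect_across(sag, fem$mesh)
  mlm <- mirror_plan(fem$landmarks, sag)
  mr <- measure_femur(mmesh, mlm$condyle_medial, mlm$condyle_lateral, mlm$side)
  expect_equal(abs(mr$version), 20, tolerance = 1e-6)
  expect_equal(mr$inclination, 135, tolerance = 1e-6)
  expect_equal(mr$neck_length, 35, tolerance = 1e-6)
})
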