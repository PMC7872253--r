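# Chevron planning, virtual osteotomy, thickness, registration, interface fit.

make_landmarks <- function(seed = 1) {
  set.seed(seed)
  repeat {
    pts <- matrix(rnorm(12, sd = 6), 4L)
    ok <- tryCatch({
      landmark_set(pts[1, ], pts[2, ], pts[3, ], pts[4, ],
                   condyle_medial = c(12, 0, -80), condyle_lateral = c(-12, 0, -80))
    }, error = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
}

test_that("chevron planes contain their defining points and the shared ridge", {
  for (s in 1:5) {
    lm <- make_landmarks(s)
    plan <- chevron_planes(lm)
    diag_len <- max(dist(rbind(lm$craniomedial, lm$craniolateral,
                               lm$caudomedial, lm$caudolateral)))
    tol <- 1e-9 * diag_len
    expect_lt(abs(plane_distance(plan$plane_a, lm$craniomedial)), tol)
    expect_lt(abs(plane_distance(plan$plane_a, lm$caudomedial)), tol)
    expect_lt(abs(plane_distance(plan$plane_a, lm$craniolateral)), tol)
    expect_lt(abs(plane_distance(plan$plane_b, lm$caudomedial)), tol)
    expect_lt(abs(plane_distance(plan$plane_b, lm$caudolateral)), tol)
    expect_lt(abs(plane_distance(plan$plane_b, lm$craniolateral)), tol)
    # ridge property: the two shared landmarks lie on BOTH planes
    for (shared in list(lm$caudomedial, lm$craniolateral)) {
      expect_lt(abs(plane_distance(plan$plane_a, shared)), tol)
      expect_lt(abs(plane_distance(plan$plane_b, shared)), tol)
    }
  }
})

test_that("chevron dihedral matches the generator's stored value to 1e-6 degree", {
  fem <- generate_femur(femur_params())
  plan <- chevron_planes(fem$landmarks, head_point = fem$truth$head_center)
  expect_equal(plan$dihedral_angle, fem$truth$chevron_dihedral,
               tolerance = 1e-6)
})

test_that("chevron planning commutes with rigid transforms", {
  lm <- make_landmarks(7)
  tr <- random_rigid_transform(seed = 7)
  plan_then <- apply_transform(tr, chevron_planes(lm))
  then_plan <- chevron_planes(apply_transform(tr, lm))
  for (side in c("plane_a", "plane_b")) {
    p1 <- plan_then[[side]]; p2 <- then_plan[[side]]
    expect_lt(abs(plane_distance(p2, p1$point)), 1e-9)
    expect_lt(min(vnorm(p1$normal - p2$normal), vnorm(p1$normal + p2$normal)),
              1e-9)
  }
})

test_that("clip_mesh splits the femoral head conserving volume, vs a voxel oracle", {
  fem <- generate_femur(femur_params())
  head_mesh <- sphere_mesh(fem$truth$head_center, fem$truth$head_radius,
                           n_lon = 64L, n_lat = 32L, label = "articular")
  plan <- fem$truth$plan
  out <- clip_mesh(head_mesh, plan)
  v_in <- mesh_volume(head_mesh)
  v_sum <- mesh_volume(out$graft) + mesh_volume(out$remainder)
  expect_lt(abs(v_sum - v_in), 1e-3 * v_in)
  expect_true(mesh_is_watertight(out$graft))

  # voxel-counting oracle at 0.2 mm: centres inside the sphere and on the
  # positive side of both planes
  sp <- 0.2
  ctr <- fem$truth$head_center; r <- fem$truth$head_radius
  gx <- seq(ctr[1] - r - 1, ctr[1] + r + 1, by = sp)
  gy <- seq(ctr[2] - r - 1, ctr[2] + r + 1, by = sp)
  gz <- seq(ctr[3] - r - 1, ctr[3] + r + 1, by = sp)
  gg <- as.matrix(expand.grid(gx, gy, gz))
  inside <- rowSums(sweep(gg, 2L, ctr)^2) <= r^2
  da <- plane_distance(plan$plane_a, gg)
  db <- plane_distance(plan$plane_b, gg)
  oracle_vol <- sum(inside & da >= 0 & db >= 0) * sp^3
  expect_lt(abs(mesh_volume(out$graft) - oracle_vol), 0.01 * oracle_vol)
})

test_that("clip_mesh warns on plans that miss the mesh and rejects open meshes", {
  cube <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  lm <- landmark_set(c(10, 0, 0), c(10, 1, 0), c(10, 0, 1), c(10.5, 1, 1))
  plan <- chevron_planes(lm, head_point = c(20, 0, 0))
  expect_warning(out <- clip_mesh(cube, plan), "empty graft")
  expect_equal(mesh_volume(out$remainder), 1, tolerance = 1e-9)
  open_mesh <- bone_mesh(cube$vertices, cube$faces[-1L, , drop = FALSE])
  expect_error(clip_mesh(open_mesh, plan), "watertight")
})

test_that("subchondral thickness of a cut femoral-head cap matches construction", {
  # solid head of radius 12, osteotomy 5 mm below the pole: pole thickness 5
  head <- sphere_mesh(c(0, 0, 0), 12, n_lon = 64L, n_lat = 32L,
                      label = "articular")
  cut <- clip_mesh_plane(head, plane(c(0, 0, 7), c(0, 0, 1)), "positive")
  th <- max_subchondral_thickness(cut, articular_label = "articular")
  expect_equal(th$thickness, 5, tolerance = 0.2)
  expect_true(th$thickness_ok)

  # cutting 9 mm below the pole exceeds the 8 mm bound
  cut9 <- clip_mesh_plane(head, plane(c(0, 0, 3), c(0, 0, 1)), "positive")
  th9 <- max_subchondral_thickness(cut9, articular_label = "articular")
  expect_equal(th9$thickness, 9, tolerance = 0.3)
  expect_false(th9$thickness_ok)

  expect_equal(max_subchondral_thickness(
    bone_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)))$thickness, 0)
  expect_error(max_subchondral_thickness(cut, articular_label = "nonexistent"),
               "no vertices labelled")
})

test_that("landmark superimposition recovers constructed transforms exactly", {
  src <- matrix(c(0, 0, 0, 10, 0, 0, 0, 8, 0, 2, 3, 7), 4L, byrow = TRUE)
  idres <- superimpose_landmarks(src, src)
  expect_lt(idres$rmsd, 1e-12)
  expect_lt(max(abs(idres$transform$rotation - diag(3))), 1e-9)

  tr <- random_rigid_transform(seed = 13)
  dst <- apply_transform(tr, src)
  rec <- superimpose_landmarks(src, dst)
  expect_lt(rec$rmsd, 1e-9)
  expect_lt(max(abs(rec$transform$rotation - tr$rotation)), 1e-9)
  expect_lt(vnorm(rec$transform$translation - tr$translation), 1e-9)

  mirrored <- src %*% diag(c(-1, 1, 1))
  expect_error(superimpose_landmarks(src, mirrored), "reflection")
})

test_that("superimposition rmsd is invariant under pre-rotation of both sets", {
  set.seed(19)
  src <- matrix(rnorm(12, sd = 10), 4L)
  dst <- src + matrix(rnorm(12, sd = 0.5), 4L)
  r0 <- superimpose_landmarks(src, dst)$rmsd
  R <- rotation_about(c(1, 1, 0), 53)
  r1 <- superimpose_landmarks(src %*% t(R), dst %*% t(R))$rmsd
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("interface separation reports zero for identical and 1 mm for offset cuts", {
  scene <- generate_graft_scene(bed_radius = 12, gap_width = 1)
  same <- interface_fit(scene$donor, scene$donor)
  expect_lt(same$max_separation, 1e-6)

  # planar cut faces offset 1 mm along the cut normal
  cube <- box_mesh(c(0, 0, 0), c(10, 10, 10))
  half <- clip_mesh_plane(cube, plane(c(0, 0, 5), c(0, 0, 1)), "positive")
  shifted <- apply_transform(rigid_transform(diag(3), c(0, 0, 1)), half)
  fit <- interface_fit(half, shifted)
  expect_equal(fit$mean_separation, 1, tolerance = 0.05)

  # donor cut with the same plan as the recipient bed: near-zero separation
  fem <- generate_femur(femur_params())
  head_mesh <- sphere_mesh(fem$truth$head_center, fem$truth$head_radius,
                           n_lon = 48L, n_lat = 24L, label = "articular")
  g1 <- clip_mesh(head_mesh, fem$truth$plan)$graft
  g2 <- clip_mesh(head_mesh, fem$truth$plan)$graft
  expect_lt(interface_fit(g1, g2)$mean_separation, 0.1)
})
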