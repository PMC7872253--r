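# HU thresholding, morphology, gap volumetry, isosurface extraction.

flat_volume <- function(value, dims = c(12, 12, 12), spacing = 0.5)
  ct_volume(array(value, dims), spacing)

test_that("bone thresholding is inclusive and monotone in the threshold", {
  vol <- flat_volume(-1000)
  expect_equal(sum(threshold_bone(vol, 300)$voxels), 0L)

  v2 <- flat_volume(-1000)
  v2$voxels[3:5, 3:5, 3:5] <- 300  # exactly at the threshold: included
  expect_equal(sum(threshold_bone(v2, 300)$voxels), 27L)

  set.seed(5)
  v3 <- ct_volume(array(runif(12^3, -1000, 2000), c(12, 12, 12)), 0.5)
  m_lo <- threshold_bone(v3, 200)$voxels
  m_hi <- threshold_bone(v3, 700)$voxels
  expect_true(all(m_lo[m_hi]))  # higher threshold is a subset

  expect_error(threshold_bone(vol, 5000), "HU range")
})

test_that("thresholded counts agree with the rasterizer's bookkeeping", {
  fem <- generate_femur(femur_params(shaft_length = 40, n_lon = 24L))
  ras <- rasterize(list(fem$mesh), hu = 1200, spacing = 0.6)
  m <- threshold_bone(ras$volume, 300)
  expect_equal(sum(m$voxels), ras$bone_voxel_count)
})

test_that("extract_surface yields watertight meshes with near-analytic volume", {
  sp <- 0.5
  n <- 48L
  ctr <- rep((n - 1) / 2 * sp, 3L)
  cs <- (seq_len(n) - 1) * sp
  gg <- expand.grid(x = cs, y = cs, z = cs)
  inside <- (gg$x - ctr[1])^2 + (gg$y - ctr[2])^2 + (gg$z - ctr[3])^2 <= 100
  vol <- ct_volume(array(ifelse(inside, 1200, -1000), c(n, n, n)), sp)
  mesh <- extract_surface(threshold_bone(vol, 300))
  expect_true(mesh_is_watertight(mesh))
  expect_equal(mesh_volume(mesh), 4188.79, tolerance = 0.05)
  expect_equal(colMeans(mesh$vertices), ctr, tolerance = 0.01,
               ignore_attr = TRUE)

  a <- array(FALSE, c(5, 5, 5)); a[3, 3, 3] <- TRUE
  single <- extract_surface(binary_mask(flat_volume(0, c(5, 5, 5)), a))
  expect_true(mesh_is_watertight(single))
  expect_gte(mesh_volume(single), 0.5 * 0.125 * 0.999)
  expect_lte(mesh_volume(single), 1.5 * 0.125)

  expect_error(extract_surface(binary_mask(vol, array(FALSE, c(n, n, n)))),
               "empty mask")
})

test_that("roi_between_bones confines the region to the seam", {
  vol <- flat_volume(-1000, c(40, 12, 12), 0.5)
  a <- array(FALSE, c(40, 12, 12)); a[1:10, , ] <- TRUE
  far <- array(FALSE, c(40, 12, 12)); far[31:40, , ] <- TRUE   # 10 mm apart
  near <- array(FALSE, c(40, 12, 12)); near[13:40, , ] <- TRUE # 1 mm gap
  touching <- array(FALSE, c(40, 12, 12)); touching[11:40, , ] <- TRUE

  expect_equal(sum(roi_between_bones(binary_mask(vol, a),
                                     binary_mask(vol, far), 2)$voxels), 0L)

  roi <- roi_between_bones(binary_mask(vol, a), binary_mask(vol, near), 2)
  slab <- array(FALSE, c(40, 12, 12)); slab[11:12, , ] <- TRUE
  expect_true(all(roi$voxels[slab]))  # contains the full analytic gap slab

  roi_t <- roi_between_bones(binary_mask(vol, a), binary_mask(vol, touching), 2)
  expect_equal(sum(roi_t$voxels), 0L)  # no free voxel at the contact seam

  expect_error(roi_between_bones(binary_mask(vol, a), binary_mask(vol, a), 2),
               "overlap")
})

test_that("segment_gap applies the 250 HU default inclusively and the component rule", {
  expect_equal(formals(segment_gap)$hu_max, 250)

  vol <- flat_volume(-1000, c(30, 10, 10), 0.5)
  vol$voxels[14:15, , ] <- 250  # exactly at the bound: included
  donor <- array(FALSE, dim(vol$voxels)); donor[1:13, , ] <- TRUE
  recip <- array(FALSE, dim(vol$voxels)); recip[16:30, , ] <- TRUE
  vol$voxels[donor] <- 1200; vol$voxels[recip] <- 1200
  dm <- binary_mask(vol, donor); rm <- binary_mask(vol, recip)
  roi <- roi_between_bones(dm, rm, 2)
  g <- segment_gap(vol, roi, donor_mask = dm, recipient_mask = rm)
  expect_equal(g$voxel_count, 2L * 10L * 10L)
  expect_equal(g$volume, 200 * 0.125)
  expect_equal(g$component_count, 1L)

  # perfect apposition: no sub-threshold voxel inside the roi
  vol2 <- flat_volume(1200, c(30, 10, 10), 0.5)
  g2 <- segment_gap(vol2, roi, donor_mask = dm, recipient_mask = rm)
  expect_equal(g2$volume, 0)

  expect_error(segment_gap(vol, binary_mask(vol, array(FALSE, dim(vol$voxels)))),
               "empty region")
})

test_that("isolated pockets not touching both bones are excluded", {
  vol <- flat_volume(1200, c(30, 12, 12), 0.5)
  donor <- array(FALSE, dim(vol$voxels)); donor[1:12, , ] <- TRUE
  recip <- array(FALSE, dim(vol$voxels)); recip[17:30, , ] <- TRUE
  # true gap slab plus an air pocket enclosed inside the recipient side
  vol$voxels[13:16, , ] <- 40
  vol$voxels[22:23, 5:6, 5:6] <- 40
  vol$voxels[donor] <- 1200; vol$voxels[recip] <- 1200
  recip[22:23, 5:6, 5:6] <- FALSE
  dm <- binary_mask(vol, donor); rm <- binary_mask(vol, recip)
  roi_all <- binary_mask(vol, !donor & !recip)
  g <- segment_gap(vol, roi_all, donor_mask = dm, recipient_mask = rm)
  expect_equal(g$voxel_count, 4L * 12L * 12L)  # the pocket is excluded
})

test_that("gap volume shrinks toward the analytic value as voxels shrink", {
  errs <- sapply(c(0.5, 0.25), function(sp) {
    scene <- generate_graft_scene(bed_radius = 10, gap_width = 1, n_lon = 36L)
    ras <- rasterize(list(scene$donor, scene$recipient), hu = c(1200, 1200),
                     spacing = sp)
    donor <- ras$masks[[1]]
    recip <- binary_mask(ras$volume, ras$masks[[2]]$voxels & !donor$voxels)
    roi <- roi_between_bones(donor, recip, 2)
    g <- segment_gap(ras$volume, roi, 250, donor, recip)
    abs(g$volume - scene$truth$analytic_gap_volume)
  })
  expect_lt(errs[2], errs[1])
})
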