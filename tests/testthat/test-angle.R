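test_that("label_components uses 8-connectivity with raster-order labels", {
  m <- matrix(0, 4, 4)
  m[1, 1] <- 1; m[2, 2] <- 1 # corner-touching
  expect_equal(label_components(m)$n, 1L)

  m2 <- matrix(0, 4, 4)
  m2[1, 1] <- 1; m2[1, 3] <- 1 # separated by one background pixel
  lc <- label_components(m2)
  expect_equal(lc$n, 2L)
  expect_equal(lc$labels[1, 1], 1L) # raster-scan first encounter
  expect_equal(lc$labels[1, 3], 2L)

  checker <- outer(1:4, 1:4, function(r, c) (r + c) %% 2)
  expect_equal(label_components(checker)$n, 1L)
})

test_that("label_components agrees with flood fill on random masks", {
  set.seed(55)
  for (i in 1:25) {
    m <- matrix(rbinom(30 * 30, 1, runif(1, 0.1, 0.5)), 30, 30)
    expect_equal(label_components(m)$n, oracle_component_count(m))
  }
})

test_that("fit_ellipse recovers axis-aligned runs", {
  horiz <- cbind(rep(5, 21), 10:30) # 1-px horizontal run
  fh <- fit_ellipse(horiz)
  expect_equal(fh$orientation_deg, 0)
  # moment convention: a uniform run of N pixels has major axis
  # 4 * sd = N * 2/sqrt(3), slightly above the run length
  expect_equal(fh$major_axis_len, 21 * 2 / sqrt(3), tolerance = 1e-3)
  expect_lt(fh$minor_axis_len, 1.5)

  vert <- cbind(10:30, rep(5, 21))
  expect_equal(fit_ellipse(vert)$orientation_deg, 90)
})

test_that("moment orientation matches the covariance eigenvector oracle", {
  set.seed(19)
  for (i in 1:20) {
    theta <- runif(1, -89, 89) * pi / 180
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    pts <- cbind(rnorm(500, 0, 10), rnorm(500, 0, 1)) %*% t(R)
    coords <- cbind(50 - pts[, 2], 50 + pts[, 1]) # back to (row, col)
    got <- fit_ellipse(coords)$orientation_deg
    expect_lt(axial_diff(got, oracle_orientation(coords)), 1e-6)
  }
})

test_that("isotropic pixel sets have undefined orientation", {
  expect_true(is.na(fit_ellipse(cbind(3, 3))$orientation_deg))
  disk <- as.matrix(expand.grid(r = -5:5, c = -5:5))
  disk <- disk[disk[, 1]^2 + disk[, 2]^2 <= 25, ]
  expect_true(is.na(fit_ellipse(disk)$orientation_deg))
})

test_that("leaf angle is the complement of |orientation| from vertical", {
  expect_equal(leaf_angle_from_orientation(90), 0)  # erect blade
  expect_equal(leaf_angle_from_orientation(0), 90)  # horizontal blade
  expect_equal(leaf_angle_from_orientation(60), 30)
  expect_equal(leaf_angle_from_orientation(-60), 30) # side-symmetric
})

test_that("measure_leaf reads a clean leaf and reports missing otherwise", {
  scene <- tiny_scene(n_leaves = 1, base_angles = 30)
  rf <- render_frame(scene, 30)
  roi <- default_rois(scene)$rois[[1]]
  angle <- measure_leaf(clean_mask(rf$plant), roi)
  expect_lt(abs(angle - 30), 1)

  empty <- matrix(0, scene$height, scene$width)
  expect_true(is.na(measure_leaf(empty, roi)))

  speck <- empty
  speck[roi$top + 5, roi$left + 5 + 0:1] <- 1 # 2-px speck
  expect_true(is.na(measure_leaf(speck, roi, min_area = 20)))

  # isotropic region in the ROI: orientation undefined -> missing + warning
  disk <- empty
  for (dr in -4:4) for (dc in -4:4) {
    if (dr^2 + dc^2 <= 16) disk[roi$top + 20 + dr, roi$left + 20 + dc] <- 1
  }
  expect_warning(res <- measure_leaf(disk, roi, min_area = 10), "isotropic")
  expect_true(is.na(res))
})

test_that("measure_series emits complete records in (frame, leaf) order", {
  scene <- tiny_scene(base_angles = c(20, 45, 70))
  sched <- wilting_schedule(10, c(20, 45, 70), jitter_sd = 0, seed = 2)
  rs <- render_tmp_series(scene, sched)
  on.exit(unlink(rs$dir, recursive = TRUE))
  dr <- default_rois(scene)
  rec <- measure_series(load_series(rs$dir, "frame_*.png"), dr$anchor, dr$rois)

  expect_s3_class(rec, "leaf_angle_tbl")
  expect_equal(nrow(rec), 30L)
  expect_equal(sum(is.na(rec$angle_deg)), 0L)
  expect_identical(rec$frame_index, rep(0:9, each = 3))
  expect_identical(rec$leaf_id, rep(1:3, 10))
  expect_true(all(rec$angle_deg >= 0 & rec$angle_deg <= 90))

  means <- tapply(rec$angle_deg, rec$leaf_id, mean)
  expect_true(all(abs(means - c(20, 45, 70)) < 2))
})

test_that("occluded frames yield missing records for exactly that leaf", {
  scene <- tiny_scene(base_angles = c(20, 45, 70))
  occ <- data.frame(frame = c(4L, 5L), leaf_id = c(2L, 2L))
  sched <- wilting_schedule(10, c(20, 45, 70), jitter_sd = 0,
                            occlusions = occ, seed = 2)
  rs <- render_tmp_series(scene, sched)
  on.exit(unlink(rs$dir, recursive = TRUE))
  dr <- default_rois(scene)
  rec <- measure_series(load_series(rs$dir, "frame_*.png"), dr$anchor, dr$rois)

  missing <- rec[is.na(rec$angle_deg), c("frame_index", "leaf_id")]
  expect_equal(missing$frame_index, c(4L, 5L))
  expect_equal(missing$leaf_id, c(2L, 2L))
})

test_that("a one-frame one-leaf series gives exactly one record", {
  scene <- tiny_scene(n_leaves = 1, base_angles = 40)
  sched <- wilting_schedule(1, 40, jitter_sd = 0, seed = 2)
  rs <- render_tmp_series(scene, sched)
  on.exit(unlink(rs$dir, recursive = TRUE))
  dr <- default_rois(scene)
  rec <- measure_series(load_series(rs$dir), dr$anchor, dr$rois)
  expect_equal(nrow(rec), 1L)
  expect_false(is.na(rec$angle_deg))
})

test_that("horizontal mirroring leaves measured angles unchanged", {
  scene <- tiny_scene(base_angles = c(25, 50, 70))
  rf <- render_frame(scene, scene$leaves$base_angle_deg)
  dr <- default_rois(scene)
  mask <- clean_mask(segment_plant(rf$frame))
  w <- scene$width
  mirrored_px <- rf$frame$pixels[, w:1, , drop = FALSE]
  mask_m <- clean_mask(segment_plant(plant_frame(mirrored_px)))
  for (roi in dr$rois) {
    roi_m <- leaf_roi(roi$leaf_id, roi$top, w - roi$left - roi$width,
                      roi$height, roi$width)
    a <- measure_leaf(mask, roi)
    b <- measure_leaf(mask_m, roi_m)
    expect_lt(abs(a - b), 0.5)
  }
})
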