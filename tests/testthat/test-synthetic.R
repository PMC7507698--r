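test_that("rendering is deterministic and validates its inputs", {
  scene <- synthetic_scene(noise_sd = 8, seed = 12)
  a <- render_frame(scene, scene$leaves$base_angle_deg, frame_index = 3)
  b <- render_frame(scene, scene$leaves$base_angle_deg, frame_index = 3)
  expect_identical(a$frame$pixels, b$frame$pixels)

  c <- render_frame(scene, scene$leaves$base_angle_deg, frame_index = 4)
  expect_false(identical(a$frame$pixels, c$frame$pixels)) # new noise draw

  expect_error(render_frame(scene, c(0, 45, 45)), "\\[5, 88\\]")
  expect_error(synthetic_scene(base_angles = 2), "base_angles")
  expect_error(synthetic_scene(width = 90, leaf_length = 80, n_leaves = 1),
               "exit")
})

test_that("a noiseless render equals the drawn geometry exactly", {
  scene <- tiny_scene()
  rf <- render_frame(scene, scene$leaves$base_angle_deg)
  implied <- (rf$frame$pixels[, , 3] == scene$plant_rgb[3]) * 1
  expect_equal(implied, rf$plant)
  # straight leaves: chord ground truth is the base angle itself
  expect_equal(unname(rf$truth), scene$leaves$base_angle_deg, tolerance = 1e-9)
})

test_that("render_series writes n frames and a complete truth table", {
  scene <- tiny_scene()
  sched <- wilting_schedule(15, scene$leaves$base_angle_deg, seed = 3)
  rs <- render_tmp_series(scene, sched)
  on.exit(unlink(rs$dir, recursive = TRUE))
  expect_length(list.files(rs$dir, pattern = "frame_.*\\.png"), 15L)
  expect_equal(nrow(rs$truth), 45L)
  truth_csv <- read_angles_csv(rs$truth_csv)
  expect_equal(nrow(truth_csv), 45L)
})

test_that("drift moves only the drifting leaf's trajectory", {
  sched <- wilting_schedule(30, c(20, 40, 60),
                            drift_per_frame = c(0.5, 0, 0),
                            jitter_sd = 0, seed = 9)
  expect_true(all(diff(sched$angles[, 1]) > 0 | sched$angles[-30, 1] == 88))
  expect_equal(sched$angles[, 2], rep(40, 30))
  expect_equal(sched$angles[, 3], rep(60, 30))
  # clamping holds under extreme drift
  wild <- wilting_schedule(30, 80, drift_per_frame = 2, jitter_sd = 0)
  expect_true(all(wild$angles <= 88 & wild$angles >= 5))
})

test_that("occluded leaves vanish from raster, truth and CSV", {
  scene <- tiny_scene()
  occ <- data.frame(frame = 10L, leaf_id = 2L)
  sched <- wilting_schedule(12, scene$leaves$base_angle_deg,
                            jitter_sd = 0, occlusions = occ, seed = 4)
  rf <- render_frame(scene, sched$angles[11, ], frame_index = 10,
                     occluded_leaves = 2L)
  expect_equal(sum(rf$leaves[["2"]]), 0)
  expect_true(is.na(rf$truth[["2"]]))
  expect_gt(sum(rf$leaves[["1"]]), 0)

  rs <- render_tmp_series(scene, sched)
  on.exit(unlink(rs$dir, recursive = TRUE))
  lines <- readLines(rs$truth_csv)
  expect_equal(lines[1 + 10 * 3 + 2], "10,2,NaN") # header + 10 frames + leaf 2
})

test_that("default ROIs sit beside the stalk and never contain stalk pixels", {
  scene <- tiny_scene(n_leaves = 2, base_angles = c(30, 60))
  dr <- default_rois(scene, margin = 3)
  sc <- leafangler:::stalk_col_range(scene)
  r1 <- dr$rois[[1]] # right-side leaf
  expect_gt(r1$left, sc[2])
  r2 <- dr$rois[[2]] # left-side leaf
  expect_lt(r2$left + r2$width - 1, sc[1])
  expect_equal(dr$anchor$row, scene$height - 1L)
  expect_equal(dr$anchor$col, scene$stalk_col)

  stalk <- leafangler:::stalk_raster(scene)
  for (ang in c(5, 30, 60, 88)) {
    rf <- render_frame(scene, c(ang, ang))
    for (roi in dr$rois) {
      crop <- stalk[(roi$top + 1):(roi$top + roi$height),
                    (roi$left + 1):(roi$left + roi$width)]
      expect_equal(sum(crop), 0)
    }
  }
})

test_that("opposite-side ROIs at the same junction row are disjoint", {
  scene <- tiny_scene(n_leaves = 2, base_angles = c(30, 30))
  scene$leaves$junction_row <- rep(scene$leaves$junction_row[1], 2)
  dr <- default_rois(scene)
  r1 <- dr$rois[[1]]; r2 <- dr$rois[[2]]
  cols1 <- r1$left:(r1$left + r1$width - 1)
  cols2 <- r2$left:(r2$left + r2$width - 1)
  expect_length(intersect(cols1, cols2), 0)
})
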