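test_that("clean_mask bridges 1-px gaps between collinear segments", {
  m <- matrix(0, 9, 15)
  m[5, 2:6] <- 1
  m[5, 8:13] <- 1 # gap at column 7
  expect_equal(label_components(m)$n, 2L)
  cleaned <- clean_mask(m, morph_params(thicken_iters = 0, min_blob_area = 0))
  expect_equal(label_components(cleaned)$n, 1L)
  expect_true(all(cleaned[5, 2:13] == 1))
})

test_that("clean_mask removes blobs below the area floor", {
  m <- matrix(0, 40, 40)
  m[10:12, 10] <- 1 # 3-px blob
  expect_equal(sum(clean_mask(m, morph_params(min_blob_area = 50))), 0)

  # a real structure above the floor survives
  m[20:35, 25:28] <- 1
  cleaned <- clean_mask(m, morph_params(min_blob_area = 50))
  expect_true(all(cleaned[20:35, 25:28] == 1))
  expect_equal(sum(cleaned[1:15, 1:15]), 0)
})

test_that("clean_mask strips salt noise but keeps the leaf pixels", {
  scene <- tiny_scene(n_leaves = 1, base_angles = 40)
  rf <- render_frame(scene, 40)
  noisy <- rf$plant
  set.seed(31)
  specks <- sample(which(noisy == 0), round(0.05 * length(noisy)))
  # drop specks adjacent to the plant so they stay separate components
  near <- leafangler:::dilate3(leafangler:::dilate3(rf$plant))
  specks <- specks[near[specks] == 0]
  noisy[specks] <- 1
  p <- morph_params(thicken_iters = 0, min_blob_area = 50)
  cleaned <- clean_mask(noisy, p)
  # all plant pixels survive
  expect_true(all(cleaned[rf$plant > 0] == 1))
  # the area filter enforces its contract exactly: of the components left
  # after gap repair, those under the floor vanish, those at/over it stay
  pre <- clean_mask(noisy, morph_params(thicken_iters = 0, min_blob_area = 0))
  lc <- label_components(pre)
  areas <- tabulate(lc$labels[lc$labels > 0], lc$n)
  for (lab in seq_len(lc$n)) {
    kept <- any(cleaned[lc$labels == lab] > 0)
    expect_equal(kept, areas[lab] >= 50)
  }
  # the bulk of the speckle is gone (a few percolated clusters that reach
  # the area floor legitimately survive at this density)
  expect_lt(mean(cleaned[specks]), 0.2)
})

test_that("clean_mask is stable under re-application", {
  scene <- tiny_scene()
  rf <- render_frame(scene, scene$leaves$base_angle_deg)
  p <- morph_params()
  once <- clean_mask(rf$plant, p)
  twice <- clean_mask(once, p)
  expect_lt(mean(once != twice), 0.001)
})

test_that("skeletonize thins a bar to a ~1-px path spanning its length", {
  m <- matrix(0, 9, 26)
  m[4:6, 3:22] <- 1 # 20 x 3 horizontal bar
  sk <- skeletonize(m)
  expect_equal(label_components(sk)$n, 1L)
  expect_true(all(sk[m == 0] == 0)) # skeleton within the bar
  expect_true(all(colSums(sk)[4:21] == 1)) # 1-px thick along the run
  expect_gte(sum(colSums(sk) > 0), 18) # spans nearly the full length

  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_equal(skeletonize(single), single)
})

test_that("a stalk+leaf junction skeletonizes to a single branch point cluster", {
  scene <- tiny_scene(n_leaves = 1, base_angles = 50)
  rf <- render_frame(scene, 50)
  sk <- skeletonize(rf$plant)
  nsum <- Reduce(`+`, lapply(leafangler:::RING_OFFSETS, function(o) {
    leafangler:::nbr(sk, o[1], o[2])
  }))
  branch <- (sk == 1 & nsum >= 3) * 1
  expect_gte(sum(branch), 1) # the junction exists
  expect_equal(label_components(branch)$n, 1L) # and there is only one
})

test_that("skeletonization preserves 8-connected component count and subset", {
  set.seed(77)
  for (i in 1:30) {
    m <- random_blob_mask(40, strokes = sample(1:4, 1))
    sk <- skeletonize(m)
    expect_true(all(sk[m == 0] == 0))
    expect_equal(label_components(sk)$n, label_components(m)$n)
  }
})

test_that("prune_skeleton removes spurs but not loops", {
  m <- matrix(0, 12, 60)
  m[6, 3:52] <- 1  # 50-px main path
  m[2:5, 20] <- 1  # 4-px spur
  pruned <- prune_skeleton(m, 10)
  # dangling part of the spur is gone (its attachment pixel touches the
  # main path with >1 neighbor and is never an endpoint)
  expect_equal(sum(pruned[1:4, 20]), 0)
  expect_true(all(pruned[6, 13:42] == 1)) # interior of the main path intact
  expect_gte(sum(pruned[6, ]), 50 - 2 * 10) # end erosion bounded by spur_len

  expect_identical(prune_skeleton(m, 0), m) # spur_len 0 is the identity

  ring <- matrix(0, 10, 10)
  ring[3, 3:7] <- 1; ring[7, 3:7] <- 1; ring[3:7, 3] <- 1; ring[3:7, 7] <- 1
  expect_identical(prune_skeleton(ring, 25), ring) # no endpoints, unchanged
})
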