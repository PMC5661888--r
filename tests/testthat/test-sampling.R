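test_that("distance transform matches the brute-force oracle", {
  set.seed(11)
  for (rep in 1:5) {
    src <- matrix(runif(15 * 12) < 0.15, 15, 12)
    if (!any(src)) src[4, 4] <- TRUE
    expect_equal(distance_transform_2d(src), brute_edt(src), tolerance = 1e-9)
  }
  expect_error(distance_transform_2d(matrix(FALSE, 3, 3)), "source")
})

test_that("box expansion applies the 8-voxel rule with clipping", {
  m <- matrix(0L, 60, 60)
  m[21:31, 25:30] <- 1L  # rows 20..30 0-based
  b <- expand_box(m, slice_index = 2)
  expect_equal(c(b$row_start, b$row_stop), c(12, 39))
  expect_equal(c(b$col_start, b$col_stop), c(16, 38))

  # nodule at the image corner clips at 0
  m2 <- matrix(0L, 30, 30); m2[1:3, 1:3] <- 1L
  b2 <- expand_box(m2)
  expect_equal(c(b2$row_start, b2$col_start), c(0, 0))

  # single interior voxel -> 17 x 17 box
  m3 <- matrix(0L, 40, 40); m3[20, 22] <- 1L
  b3 <- expand_box(m3)
  expect_equal(b3$row_stop - b3$row_start, 17)
  expect_equal(b3$col_stop - b3$col_start, 17)

  expect_error(expand_box(matrix(0L, 5, 5)), "no nodule")
})

test_that("nodule weights decay with distance from the boundary", {
  m <- matrix(0L, 20, 20)
  m[9:11, 9:11] <- 1L  # solid 3x3 block
  b <- expand_box(m)
  pw <- compute_nodule_weights(m, b)
  expect_equal(sum(pw), 1, tolerance = 1e-9)
  expect_true(all(pw >= 0))
  # edge voxel (distance 1 to background) vs centre voxel (distance 2)
  edge <- pw[9 - b$row_start, 10 - b$col_start]   # (9,10) 1-based -> box coords
  ctr <- pw[10 - b$row_start, 10 - b$col_start]
  expect_equal(edge / ctr, exp(1), tolerance = 1e-9)

  # single nodule voxel -> weight exactly 1
  m1 <- matrix(0L, 20, 20); m1[10, 10] <- 1L
  pw1 <- compute_nodule_weights(m1, expand_box(m1))
  expect_equal(max(pw1), 1)

  expect_error(compute_nodule_weights(matrix(1L, 4, 4),
                                      bounding_box_2d(0, 0, 4, 0, 4)),
               "both classes")
})

test_that("background weights modulate distance decay by normalised intensity", {
  m <- matrix(0L, 30, 30)
  m[15, 15] <- 1L
  b <- bounding_box_2d(0, 10, 20, 10, 20)
  ints <- matrix(500, 30, 30)
  ints[15, 13] <- -1000     # darkest voxel in box -> I_i = 0 -> weight 0
  nw <- compute_background_weights(m, ints, b)
  expect_equal(sum(nw), 1, tolerance = 1e-9)
  expect_equal(nw[15 - b$row_start, 13 - b$col_start], 0)

  # constant intensity: weights purely distance-based; ratio over
  # distances 1 and 2 equals e
  flat <- matrix(100, 30, 30)
  nwf <- compute_background_weights(m, flat, b)
  w1 <- nwf[15 - b$row_start, 16 - b$col_start]  # distance 1
  w2 <- nwf[15 - b$row_start, 17 - b$col_start]  # distance 2
  expect_equal(w1 / w2, exp(1), tolerance = 1e-9)

  # equal-intensity voxels: weight strictly decreases with distance
  drow <- nwf[15 - b$row_start, (16:20) - b$col_start]
  expect_true(all(diff(drow) < 0))
})

test_that("the 40% balanced rule yields equal class counts without duplicates", {
  m <- matrix(0L, 40, 40)
  m[11:20, 11:20] <- 1L    # exactly 100 nodule voxels
  set.seed(40)
  v <- matrix(rnorm(1600, -800, 30), 40, 40)     # lung field + noise
  v[m == 1L] <- rnorm(100, 60, 30)
  wm <- weight_map(m, v, slice_index = 0, volume_id = "t")
  ss <- sample_training_voxels(list(wm), fraction = 0.40, seed = 9)
  expect_equal(sum(ss$label == 1), 40)
  expect_equal(sum(ss$label == 0), 40)
  expect_false(any(duplicated(ss[c("slice", "row", "col", "label")])))
  # sampled nodule coordinates really are nodule voxels
  nod <- ss[ss$label == 1, ]
  expect_true(all(m[cbind(nod$row + 1, nod$col + 1)] == 1))

  # fraction 1.0 on a 10-voxel nodule draws each voxel exactly once
  m2 <- matrix(0L, 30, 30); m2[10, 11:20] <- 1L
  set.seed(41)
  wm2 <- weight_map(m2, matrix(rnorm(900, -800, 30), 30, 30), 0, "t2")
  ss2 <- sample_training_voxels(list(wm2), fraction = 1.0, seed = 4)
  nod2 <- ss2[ss2$label == 1, ]
  expect_equal(sort(nod2$col), 10:19)
})

test_that("seeded draw frequencies follow the weights", {
  # a synthetic two-voxel map with pw = (0.8, 0.2), drawing one voxel
  pw <- matrix(0, 2, 2); pw[1, 1] <- 0.8; pw[2, 1] <- 0.2
  nw <- matrix(0, 2, 2); nw[, 2] <- 0.5
  wm <- structure(list(slice_index = 0L,
                       expanded_box = bounding_box_2d(0, 0, 2, 0, 2),
                       pw = pw, nw = nw, volume_id = "mc"),
                  class = "weight_map")
  hits <- 0L
  for (k in 1:2000) {
    ss <- sample_training_voxels(list(wm), fraction = 0.5, seed = k)
    nod <- ss[ss$label == 1, ]
    if (nrow(nod) == 1 && nod$row == 0 && nod$col == 0) hits <- hits + 1L
  }
  expect_equal(hits / 2000, 0.8, tolerance = 0.03)
})

test_that("weighted sampling prefers nodule-edge voxels over uniform sampling", {
  m <- matrix(0L, 40, 40)
  d2 <- outer((1:40 - 20)^2, (1:40 - 20)^2, `+`)
  m[d2 <= 64] <- 1L  # disk of radius 8
  set.seed(42)
  v <- matrix(rnorm(1600, -800, 30), 40, 40)
  v[m == 1L] <- rnorm(sum(m), 60, 30)
  wm <- weight_map(m, v, 0, "disk")
  ss <- sample_training_voxels(list(wm), fraction = 0.4, seed = 17)
  nod <- ss[ss$label == 1, ]
  edt <- distance_transform_2d(m == 0)
  sampled_d <- mean(edt[cbind(nod$row + 1, nod$col + 1)])
  uniform_d <- mean(edt[m == 1])
  expect_lt(sampled_d, uniform_d)
})
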