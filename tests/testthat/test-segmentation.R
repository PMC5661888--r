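spec_small <- patch_spec(size_2d = 9, size_2d_large = 17)

test_that("slice classification applies the inclusive threshold inside the box", {
  v <- flat_volume(c(5, 20, 20))
  box <- bounding_box_2d(2, 5, 10, 6, 12)

  hi <- classify_slice(constant_classifier(0.9), v, box, spec = spec_small)
  expect_equal(sum(hi), 5 * 6)
  expect_true(all(hi[6:10, 7:12] == 1L))
  expect_equal(sum(hi[-(6:10), ]), 0)

  # p = 0.5 with threshold 0.5 labels everything (>= rule)
  border <- classify_slice(constant_classifier(0.5), v, box, spec = spec_small)
  expect_equal(sum(border), 5 * 6)
  lo <- classify_slice(constant_classifier(0.49), v, box, spec = spec_small)
  expect_equal(sum(lo), 0)

  expect_error(classify_slice(constant_classifier(1), v,
                              bounding_box_2d(7, 0, 5, 0, 5),
                              spec = spec_small),
               "outside")
})

test_that("oracle classification reproduces ground truth within the box", {
  ph <- generate_phantom(phantom_config(radius_vox = 4, noise_sd = 0,
                                        shape = c(16, 30, 30), seed = 1))
  cls <- oracle_classifier(ph$mask)
  sl <- ph$start_box$slice_index
  rows <- (ph$start_box$row_start + 1):ph$start_box$row_stop
  cols <- (ph$start_box$col_start + 1):ph$start_box$col_stop
  got <- classify_slice(cls, ph$volume, ph$start_box, spec = spec_small)
  expect_identical(got[rows, cols], ph$mask$labels[sl + 1, rows, cols])
})

test_that("component selection keeps the region nearest the reference", {
  m <- matrix(0L, 12, 12)
  m[2:3, 2:3] <- 1L      # region R1, centroid (1.5, 1.5) 0-based
  m[8:10, 8:10] <- 1L    # region R2, centroid (8, 8)
  near_r2 <- select_component(m, "propagated", reference = c(7, 7))
  expect_equal(near_r2$area, 9)
  expect_true(all(near_r2$mask[8:10, 8:10] == 1L))
  expect_equal(sum(near_r2$mask), 9)

  near_r1 <- select_component(m, "propagated", reference = c(2, 2))
  expect_equal(near_r1$area, 4)

  # single region -> unchanged
  single <- select_component(near_r1$mask, "starting", c(0, 0))
  expect_identical(single$mask, near_r1$mask)

  # empty mask is not an error
  none <- select_component(matrix(0L, 5, 5), "propagated", c(2, 2))
  expect_equal(none$area, 0)

  # tie in centroid distance -> larger area wins; verified by brute force
  t <- matrix(0L, 10, 10)
  t[5, 2:3] <- 1L          # centroid (4, 1.5) 0-based, area 2
  t[4:6, 8] <- 1L          # centroid (4, 7),  area 3
  ref <- c(4, 4.25)        # equidistant: 2.75 from both centroids
  comp <- select_component(t, "propagated", ref)
  # independent check by enumerating both components
  d1 <- sqrt(sum((c(4, 1.5) - ref)^2)); d2 <- sqrt(sum((c(4, 7) - ref)^2))
  expect_equal(d1, d2)
  expect_equal(comp$area, 3)
})

test_that("diagonally linked voxels form one 8-connected component", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 1L; m[3, 3] <- 1L; m[4, 4] <- 1L
  sel <- select_component(m, "starting", c(2, 2))
  expect_equal(sel$area, 3)
})

test_that("propagation stops by the 30% rule with the violating slice excluded", {
  # scripted probabilities: starting slice disk of 40 voxels, next slice up
  # only 4 voxels (10%), next slice down exactly 12 voxels (30%)
  shape <- c(9, 30, 30)
  prob <- array(0, shape)
  prob[5, 13:17, 10:17] <- 1                    # starting slice: 40 voxels
  prob[6, 14:15, 14:15] <- 1                    # 4 voxels = 10% -> stop, excluded
  prob[4, 13:16, 14:16] <- 1                    # 12 voxels = exactly 30% -> kept
  box <- bounding_box_2d(4, 5, 25, 5, 25)
  v <- flat_volume(shape)
  res <- propagate(probability_classifier(prob), v, box, spec = spec_small)

  areas <- res$per_slice_area
  expect_equal(unname(areas["4"]), 40)
  expect_false("5" %in% names(areas))            # the 4-voxel slice is excluded
  expect_equal(res$stop_reason_up, "area_ratio")
  expect_equal(unname(areas["3"]), 12)           # exactly 30% continues
  expect_equal(res$stop_reason_down, "empty_slice") # next slice down is empty
  # monotone stop: every slice outside [3, 4] is empty
  for (s0 in setdiff(0:8, c(3, 4)))
    expect_equal(sum(res$mask$labels[s0 + 1, , ]), 0)
})

test_that("oracle-driven segmentation recovers a sphere phantom exactly", {
  # radius chosen so consecutive slice areas never fall below the 30% rule
  ph <- generate_phantom(phantom_config(radius_vox = 4.3, noise_sd = 20,
                                        shape = c(16, 30, 30), seed = 6))
  res <- segment(oracle_classifier(ph$mask), ph$volume, ph$start_box,
                 spec = spec_small)
  expect_equal(dice(ph$mask, res$mask), 1.0)
  expect_equal(res$stop_reason_up, "empty_slice")
  expect_equal(res$stop_reason_down, "empty_slice")

  # exactly one component per kept slice, mask confined to the box footprint
  for (s in names(res$per_slice_area)) {
    sl <- res$mask$labels[as.integer(s) + 1, , ]
    expect_equal(sum(sl), unname(res$per_slice_area[s]))
    lab <- cfcnn:::.label_components(sl)
    expect_equal(max(lab), 1)
    outside <- sl
    outside[(res$start_box$row_start + 1):res$start_box$row_stop,
            (res$start_box$col_start + 1):res$start_box$col_stop] <- 0L
    expect_equal(sum(outside), 0)
  }

  # constant-zero classifier cannot start
  expect_error(segment(constant_classifier(0), ph$volume, ph$start_box,
                       spec = spec_small),
               "starting slice")
})
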