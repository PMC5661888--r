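test_that("overlap metrics reproduce hand arithmetic and are symmetric", {
  shape <- c(10, 10, 10)
  gt <- array(0L, shape); gt[1:4, 1:5, 1:5] <- 1L          # 100 voxels
  auto <- array(0L, shape); auto[1:4, 1:5, 1:5] <- 1L
  auto[1, 1:4, 1:5] <- 0L                                   # drop 20
  auto[5:6, 1:2, 1:5] <- 1L                                 # add 20 outside
  expect_equal(sum(gt), 100); expect_equal(sum(auto), 100)
  expect_equal(sum(gt * auto), 80)

  expect_equal(dice(gt, auto), 0.8)
  expect_equal(jaccard_overlap(gt, auto), 80 / 120)
  expect_equal(dice(gt, auto), dice(auto, gt))

  idm <- nodule_mask(gt)
  expect_equal(dice(idm, idm), 1)
  expect_equal(jaccard_overlap(idm, idm), 1)

  dis <- array(0L, shape); dis[8:10, 8:10, 8:10] <- 1L
  expect_equal(dice(gt, dis), 0)

  expect_error(dice(array(0L, shape), array(0L, shape)), "empty")
  expect_error(dice(gt, array(0L, c(9, 10, 10))), "shapes")
})

test_that("jaccard equals D/(2 - D) on random mask pairs", {
  set.seed(14)
  for (rep in 1:50) {
    a <- array(as.integer(runif(6^3) < 0.4), c(6, 6, 6))
    b <- array(as.integer(runif(6^3) < 0.4), c(6, 6, 6))
    if (sum(a) + sum(b) == 0) next
    D <- dice(a, b)
    expect_lt(abs(jaccard_overlap(a, b) - D / (2 - D)), 1e-12)
    expect_lte(jaccard_overlap(a, b), D + 1e-15)
  }
})

test_that("sensitivity and PPV follow their definitions", {
  shape <- c(10, 10, 10)
  gt <- array(0L, shape); gt[1:4, 1:5, 1:5] <- 1L          # |Gt| = 100
  auto <- array(0L, shape)
  auto[1:2, 1:5, 1:4] <- 1L                                # 40 inside gt
  auto[6:10, 6:7, 6] <- 1L                                 # 10 outside
  expect_equal(sum(auto), 50)
  expect_equal(sum(gt * auto), 40)
  sp <- sensitivity_ppv(gt, auto)
  expect_equal(unname(sp), c(0.40, 0.80))

  half <- array(0L, shape); half[1:2, 1:5, 1:5] <- 1L      # auto subset of gt
  expect_equal(unname(sensitivity_ppv(gt, half)), c(0.5, 1.0))
  expect_equal(unname(sensitivity_ppv(gt, gt)), c(1, 1))
  expect_error(sensitivity_ppv(gt, array(0L, shape)), "PPV")
})

test_that("surface distance matches the all-pairs brute-force oracle", {
  # identical masks -> 0
  m <- ball_mask(c(12, 12, 12), c(6, 6, 6), 4)
  expect_equal(asd(m, m), 0)

  # two single-voxel masks three slices apart, 1 mm slice spacing
  a <- array(0L, c(10, 5, 5)); a[2, 3, 3] <- 1L
  b <- array(0L, c(10, 5, 5)); b[5, 3, 3] <- 1L
  expect_equal(asd(a, b, spacing = c(1, 1, 1)), 3.0)

  # random masks up to 20^3, anisotropic spacing
  set.seed(15)
  for (rep in 1:3) {
    g <- array(0L, c(16, 16, 16))
    g[4:9, 3:10, 5:12][runif(6 * 8 * 8) < 0.6] <- 1L
    h <- array(0L, c(16, 16, 16))
    h[6:12, 5:11, 4:10][runif(7 * 7 * 7) < 0.6] <- 1L
    if (sum(g) == 0 || sum(h) == 0) next
    sp <- c(2.0, 0.7, 0.7)
    expect_equal(asd(g, h, sp), brute_asd(g, h, sp), tolerance = 1e-9)
    expect_equal(asd(g, h, sp), asd(h, g, sp))
  }
  expect_error(asd(a, array(0L, c(10, 5, 5))), "nonempty")
})

test_that("50% consensus includes exact ties and is monotone", {
  shape <- c(4, 4, 4)
  m1 <- array(0L, shape); m1[1:2, 1:2, 1] <- 1L
  m2 <- array(0L, shape); m2[2:3, 1:2, 1] <- 1L
  m3 <- array(0L, shape); m3[2, 2, 1] <- 1L
  m4 <- array(0L, shape)

  cons <- consensus_mask(list(m1, m2, m3, m4))
  # voxel (2,1,1) marked by exactly 2 of 4 raters -> included
  expect_equal(cons$labels[2, 1, 1], 1L)
  # voxel (1,1,1) marked by 1 of 4 -> excluded
  expect_equal(cons$labels[1, 1, 1], 0L)
  # single rater -> identity
  expect_identical(consensus_mask(list(m1))$labels, m1)
  # adding an all-marking rater never removes consensus voxels
  allr <- array(1L, shape)
  cons5 <- consensus_mask(list(m1, m2, m3, m4, allr))
  expect_true(all(cons5$labels[cons$labels == 1L] == 1L))
  expect_error(consensus_mask(list(m1, array(0L, c(3, 4, 4)))), "shapes")
})

test_that("cohort evaluation aggregates with the sample-sd convention", {
  g1 <- ball_mask(c(10, 12, 12), c(5, 6, 6), 3)
  a1 <- g1
  g2 <- ball_mask(c(10, 12, 12), c(5, 6, 6), 3)
  a2 <- array(0L, dim(g2)); a2[g2 == 1] <- 1L
  a2[5, , ] <- 0L  # degrade one slice
  out <- evaluate_cohort(list(nodule_mask(a1), nodule_mask(a2)),
                         list(nodule_mask(g1), nodule_mask(g2)),
                         spacings = list(c(1, 1, 1)))
  expect_equal(nrow(out$per_case), 2)
  d <- out$per_case$dsc
  expect_equal(out$summary$mean[out$summary$metric == "dsc"], mean(d))
  expect_equal(out$summary$sd[out$summary$metric == "dsc"],
               sqrt(sum((d - mean(d))^2) / (2 - 1)))

  one <- evaluate_cohort(list(nodule_mask(a1)), list(nodule_mask(g1)))
  expect_equal(one$summary$mean[1], one$per_case$dsc[1])
  expect_error(evaluate_cohort(list(), list()), "empty")
  expect_error(evaluate_cohort(list(nodule_mask(a1)), list()), "length")
})
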