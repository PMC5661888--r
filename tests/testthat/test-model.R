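tiny9 <- model_config(input_size = 9, tiny = TRUE)

random_inputs <- function(B, size = 9, seed = 1) {
  set.seed(seed)
  list(x3 = array(rnorm(size * size * B * 3), c(size, size, B, 3)),
       x2 = array(rnorm(size * size * B * 2), c(size, size, B, 2)),
       y = sample(0:1, B, replace = TRUE))
}

test_that("softmax outputs normalise and PReLU has its limiting forms", {
  set.seed(10)
  p <- softmax(matrix(rnorm(40, sd = 4), 20, 2))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0 & p <= 1))

  x <- matrix(rnorm(50), 10, 5)
  relu <- cfcnn:::.prelu_forward(x, rep(0, 5))$out
  expect_equal(relu, pmax(x, 0))
  ident <- cfcnn:::.prelu_forward(x, rep(1, 5))$out
  expect_equal(ident, x)
})

test_that("loss reproduces hand-evaluated cases", {
  # perfect prediction, no regularisation
  expect_lt(loss_fn(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  # single sample, y = 1, p = 0.5
  expect_equal(loss_fn(0.5, 1), log(2), tolerance = 1e-12)
  # regulariser-only case: direct-sum oracle over the weight matrices
  m <- build_model(tiny9, seed = 3)
  lam <- 1e-3
  direct <- 0
  walk <- function(x) for (nm in names(x)) {
    if (is.list(x[[nm]])) walk(x[[nm]])
    else if (nm == "W") direct <<- direct + sum(abs(x[[nm]]))
  }
  walk(m$params)
  # data term is ~1e-7 after probability clamping; regulariser dominates
  expect_lt(abs(loss_fn(c(1, 0), c(1, 0), weights = m, lambda = lam) -
                  lam * direct), 1e-6)
  expect_error(loss_fn(0.5, 2), "labels")
})

test_that("learning-rate schedule follows inverse decay", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 6e-5)
  expect_equal(lr_schedule(10000, cfg), 6e-5 * 2^(-0.75), tolerance = 1e-12)
  ts <- unique(c(0:100, round(10^seq(2, 6, length.out = 30))))
  a <- lr_schedule(ts, cfg)
  expect_true(all(diff(a) < 0))
})

test_that("momentum SGD reproduces the two-step hand recursion", {
  cfg <- train_config(base_lr = 0.1, gamma = 0, momentum = 0.9)
  w <- list(w = 1)
  st <- list(t = 0L, V = list(w = 0))
  up1 <- sgd_step(w, list(w = 1), st, cfg)
  expect_equal(up1$state$V$w, -0.1)
  expect_equal(up1$weights$w, 0.9)
  up2 <- sgd_step(up1$weights, list(w = 1), up1$state, cfg)
  expect_equal(up2$state$V$w, -0.19)
  expect_equal(up2$weights$w, 0.71, tolerance = 1e-12)

  # momentum-free limit is plain gradient descent
  cfg0 <- train_config(base_lr = 0.1, gamma = 0, momentum = 0)
  up <- sgd_step(list(w = 2), list(w = 0.5), list(t = 0L, V = list(w = 0)), cfg0)
  expect_equal(up$weights$w, 2 - 0.1 * 0.5)

  # zero gradient, zero velocity -> unchanged
  upz <- sgd_step(list(w = 2), list(w = 0), list(t = 0L, V = list(w = 0)), cfg)
  expect_equal(upz$weights$w, 2)
  expect_error(sgd_step(list(w = 1), list(w = NaN),
                        list(t = 0L, V = list(w = 0)), cfg),
               "non-finite")
})

test_that("model builds deterministically with the hand-computed parameter count", {
  m1 <- build_model(tiny9, seed = 11)
  m2 <- build_model(tiny9, seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny9, seed = 12)
  expect_false(identical(m3$params, m1$params))

  # shape arithmetic: tiny preset filters (4,4),(8,8),(12,12), fc 32/16,
  # input 9 pools to 5 then 3 per axis
  conv_block <- function(cin, f) (9 * cin * f + f) + 2 * f + f  # W+b, BN, PReLU
  branch <- function(cin) {
    conv_block(cin, 4) + conv_block(4, 4) +
      conv_block(4, 8) + conv_block(8, 8) +
      conv_block(8, 12) + conv_block(12, 12) +
      (3 * 3 * 12 * 32 + 32 + 32)                      # FC + bias + PReLU
  }
  expected <- branch(3) + branch(2) +
    (64 * 16 + 16 + 16) +                              # fused FC
    (16 * 2 + 2)                                       # output layer
  expect_equal(count_parameters(m1), expected)
  expect_equal(unname(m1$config$stage_sizes), c(9, 5, 3))
})

test_that("forward probabilities are valid and batch-consistent", {
  m <- build_model(tiny9, seed = 4)
  v <- ct_volume(array(rnorm(5 * 30 * 30), c(5, 30, 30)))
  spec <- patch_spec(size_2d = 9, size_2d_large = 17)
  patches <- batch_patches(v, rbind(c(2, 10, 10), c(2, 15, 15), c(2, 10, 10)),
                           spec)
  p <- predict_batch(m, patches)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p[1], p[3])  # duplicated patch -> identical probability
  single <- predict_batch(m, patches[2])
  expect_equal(single, p[2], tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences end to end", {
  m <- build_model(tiny9, seed = 7)
  inp <- random_inputs(4, seed = 2)
  res <- model_gradients(m, inp$x3, inp$x2, inp$y, lambda = 0)

  leaves <- list()
  walk <- function(x, path) for (nm in names(x)) {
    if (is.list(x[[nm]])) walk(x[[nm]], c(path, nm))
    else leaves[[length(leaves) + 1]] <<- list(path = c(path, nm),
                                               n = length(x[[nm]]))
  }
  walk(m$params, character(0))

  set.seed(31)
  eps <- 1e-5
  for (k in 1:20) {
    leaf <- leaves[[sample(length(leaves), 1)]]
    i <- sample(leaf$n, 1)
    bump <- function(model, delta) {
      model$params[[leaf$path]][i] <- model$params[[leaf$path]][i] + delta
      model
    }
    num <- (model_gradients(bump(m, eps), inp$x3, inp$x2, inp$y, lambda = 0)$loss -
            model_gradients(bump(m, -eps), inp$x3, inp$x2, inp$y, lambda = 0)$loss) /
           (2 * eps)
    ana <- res$grads[[leaf$path]][i]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-4), 1e-3)
  }
})

test_that("uniform-pooling ablation shares the architecture but not the features", {
  central <- build_model(model_config(tiny = TRUE), seed = 5)
  uniform <- build_model(model_config(tiny = TRUE, pooling = "uniform_max"),
                         seed = 5)
  expect_equal(count_parameters(central), count_parameters(uniform))
  expect_identical(central$params, uniform$params)  # same init, same shapes
  expect_equal(uniform$plans$p1$n_out, 18)
  expect_equal(uniform$plans$p2$n_out, 9)
  set.seed(6)
  x <- matrix(rnorm(35 * 35), 35, 35)
  f_c <- central_pool_forward(x, central$plans$p1, central$plans$p1)$pooled
  f_u <- central_pool_forward(x, uniform$plans$p1, uniform$plans$p1)$pooled
  expect_false(isTRUE(all.equal(f_c, f_u)))
})

test_that("training is seeded, records history and reduces the loss", {
  ph <- generate_phantom(phantom_config(radius_vox = 4, noise_sd = 20,
                                        shape = c(16, 30, 30), seed = 8))
  spec <- patch_spec(size_2d = 9, size_2d_large = 17)
  wm <- build_weight_maps(ph$volume, ph$mask)
  ss <- sample_training_voxels(wm, fraction = 0.8, seed = 9)
  pairs <- batch_patches(ph$volume, as.matrix(ss[c("slice", "row", "col")]),
                         spec)
  val <- list(generate_phantom(phantom_config(radius_vox = 4, noise_sd = 20,
                                              shape = c(16, 30, 30), seed = 88)))
  cfg1 <- train_config(base_lr = 5e-3, batch_size = 64, max_epochs = 1,
                       patience = 5, seed = 3)
  mcfg <- model_config(input_size = 9, tiny = TRUE)
  m1 <- train(build_model(mcfg, seed = 21), pairs, ss$label, val, cfg1,
              spec = spec)
  expect_equal(nrow(m1$history), 1)
  expect_true(all(c("epoch", "mean_loss", "val_dsc", "lr") %in%
                    names(m1$history)))

  # same seed -> identical first-epoch loss
  m1b <- train(build_model(mcfg, seed = 21), pairs, ss$label, val, cfg1,
               spec = spec)
  expect_equal(m1$history$mean_loss[1], m1b$history$mean_loss[1])

  cfg3 <- train_config(base_lr = 5e-3, batch_size = 64, max_epochs = 3,
                       patience = 5, seed = 3)
  m3 <- train(build_model(mcfg, seed = 21), pairs, ss$label, val, cfg3,
              spec = spec)
  expect_lt(m3$history$mean_loss[3], m3$history$mean_loss[1])

  expect_error(train(build_model(mcfg, 1), list(), integer(0), val, cfg1),
               "empty")
  expect_error(train(build_model(mcfg, 1), pairs, ss$label, list(), cfg1),
               "validation")
})

test_that("checkpoints round trip through a single archive", {
  m <- build_model(tiny9, seed = 2)
  st <- optimizer_state(m)
  f <- file.path(withr::local_tempdir(), "model.ckpt")
  save_checkpoint(m, f, state = st, train_cfg = train_config())
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  expect_equal(attr(m2, "optimizer_state")$t, 0L)
})
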