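#' Network architecture configuration
#'
#' The network has two branches of identical structure (unshared weights):
#' three blocks of two zero-padded 3 x 3 convolutions, each followed by
#' batch normalisation and PReLU, with a central pooling stage after the
#' first and second block (35 -> 18 -> 9 for the default input), then a
#' fully connected layer per branch; branch outputs are concatenated, pass
#' a fused fully connected layer and a linear 2-unit output with softmax.
#'
#' @param input_size In-plane patch width (default 35).
#' @param channels_3d,channels_2d Input channels of the two branches.
#' @param conv_filters List of three length-2 vectors: filter counts of the
#'   two convolutions in each block.
#' @param kernel_size Convolution kernel width (odd; only 3 supported).
#' @param fc_branch,fc_fused Fully connected widths.
#' @param n_classes Output classes (2).
#' @param prelu_init Initial PReLU negative-side slope `a_j` (0.25).
#' @param lambda_l1 1-norm regularisation strength on conv/FC weights
#'   (5e-4).
#' @param pooling `"central"` or `"uniform_max"` (the traditional
#'   max-pooling ablation; odd stage sizes use a trailing width-1 window,
#'   i.e. ceil-mode 2/2 pooling, so both variants share all map sizes).
#' @param tiny Shrink filters and FC widths to a desk-scale preset.
#' @return Object of class `model_config`.
#' @export
model_config <- function(input_size = 35L, channels_3d = 3L, channels_2d = 2L,
                         conv_filters = list(c(36L, 36L), c(72L, 72L), c(108L, 108L)),
                         kernel_size = 3L, fc_branch = 256L, fc_fused = 128L,
                         n_classes = 2L, prelu_init = 0.25, lambda_l1 = 5e-4,
                         pooling = c("central", "uniform_max"), tiny = FALSE) {
  pooling <- match.arg(pooling)
  if (isTRUE(tiny)) {
    conv_filters <- list(c(4L, 4L), c(8L, 8L), c(12L, 12L))
    fc_branch <- 32L; fc_fused <- 16L
  }
  if (as.integer(kernel_size) != 3L)
    stop("model_config: only 3 x 3 convolution kernels are supported")
  stopifnot(lambda_l1 >= 0, length(conv_filters) == 3L,
            all(vapply(conv_filters, length, 0L) == 2L))
  s1 <- solve_kernel_counts(input_size)$n_out
  if (input_size < 2L || s1 < 2L)
    stop("model_config: input size too small for two pooling stages")
  s2 <- solve_kernel_counts(s1)$n_out
  structure(list(input_size = as.integer(input_size),
                 channels_3d = as.integer(channels_3d),
                 channels_2d = as.integer(channels_2d),
                 conv_filters = lapply(conv_filters, as.integer),
                 kernel_size = 3L, fc_branch = as.integer(fc_branch),
                 fc_fused = as.integer(fc_fused),
                 n_classes = as.integer(n_classes),
                 prelu_init = prelu_init, lambda_l1 = lambda_l1,
                 pooling = pooling, tiny = isTRUE(tiny),
                 stage_sizes = c(as.integer(input_size), s1, s2)),
            class = "model_config")
}

#' Training configuration
#'
#' Momentum SGD with inverse-decay learning rate
#' `alpha_t = base_lr * (1 + gamma t)^(-power)`.
#'
#' @param base_lr Base learning rate `alpha_0` (published value 6e-5).
#' @param gamma,power Inverse-decay parameters (1e-4, 0.75).
#' @param momentum Momentum `mu` in [0, 1) (0.9).
#' @param batch_size Mini-batch size (128).
#' @param max_epochs Epoch budget (21; validation DSC selects the best).
#' @param patience Early-stop patience on validation DSC.
#' @param seed Integer seed controlling init-independent shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(base_lr = 6e-5, gamma = 1e-4, power = 0.75,
                         momentum = 0.9, batch_size = 128L, max_epochs = 21L,
                         patience = 3L, seed = 1L) {
  stopifnot(base_lr > 0, momentum >= 0, momentum < 1, batch_size >= 1)
  structure(list(base_lr = base_lr, gamma = gamma, power = power,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' @param t Iteration number (>= 0).
#' @param cfg A [train_config].
#' @return `base_lr * (1 + gamma t)^(-power)`; strictly decreasing in `t`
#'   for positive `gamma`.
#' @export
lr_schedule <- function(t, cfg) {
  stopifnot(all(t >= 0))
  cfg$base_lr * (1 + cfg$gamma * t)^(-cfg$power)
}

# ---- parameter initialisation --------------------------------------------

.xavier <- function(nin, nout, dims) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

.init_conv <- function(c_in, f, prelu_init) {
  list(W = .xavier(9 * c_in, 9 * f, c(9 * c_in, f)),
       b = numeric(f), gamma = rep(1, f), beta = numeric(f),
       a = rep(prelu_init, f))
}

.init_fc <- function(d_in, d_out, prelu_init, activation = TRUE) {
  l <- list(W = .xavier(d_in, d_out, c(d_in, d_out)), b = numeric(d_out))
  if (activation) l$a <- rep(prelu_init, d_out)
  l
}

.init_branch <- function(c_in, cfg) {
  f <- cfg$conv_filters
  s2 <- cfg$stage_sizes[3]
  list(conv1a = .init_conv(c_in, f[[1]][1], cfg$prelu_init),
       conv1b = .init_conv(f[[1]][1], f[[1]][2], cfg$prelu_init),
       conv2a = .init_conv(f[[1]][2], f[[2]][1], cfg$prelu_init),
       conv2b = .init_conv(f[[2]][1], f[[2]][2], cfg$prelu_init),
       conv3a = .init_conv(f[[2]][2], f[[3]][1], cfg$prelu_init),
       conv3b = .init_conv(f[[3]][1], f[[3]][2], cfg$prelu_init),
       fc = .init_fc(s2 * s2 * f[[3]][2], cfg$fc_branch, cfg$prelu_init))
}

.conv_names <- c("conv1a", "conv1b", "conv2a", "conv2b", "conv3a", "conv3b")

.init_branch_buffers <- function(cfg) {
  f <- unlist(cfg$conv_filters)
  bufs <- lapply(f[c(1, 2, 3, 4, 5, 6)],
                 function(k) list(rm = numeric(k), rv = rep(1, k)))
  names(bufs) <- .conv_names
  bufs
}

# ceil-mode uniform 2/2 plan used by the "uniform_max" model variant
.uniform_plan_ceil <- function(O) {
  ord <- c(rep(2L, O %/% 2L), if (O %% 2L == 1L) 1L)
  n1 <- sum(ord == 1L); n2 <- sum(ord == 2L)
  .finish_plan(ord, list(n1 = n1, n2 = n2, n3 = 0L, r = 0L))
}

.model_plans <- function(cfg) {
  mk <- if (cfg$pooling == "central") pooling_plan else .uniform_plan_ceil
  list(p1 = mk(cfg$stage_sizes[1]), p2 = mk(cfg$stage_sizes[2]))
}

#' Build the two-branch network
#'
#' Weights are initialised with the Xavier (Glorot uniform) scheme, PReLU
#' slopes at `prelu_init`, batch-norm scale/shift at 1/0; deterministic
#' given `seed`.
#'
#' @param config A [model_config].
#' @param seed Integer seed for initialisation.
#' @return Object of class `cfcnn_model` with fields `config`, `params`
#'   (nested weight list), `buffers` (batch-norm running statistics) and
#'   `plans` (pooling plans of the two stages).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  params <- .with_seed(seed, list(
    b3 = .init_branch(config$channels_3d, config),
    b2 = .init_branch(config$channels_2d, config),
    fused = .init_fc(2L * config$fc_branch, config$fc_fused, config$prelu_init),
    out = .init_fc(config$fc_fused, config$n_classes, config$prelu_init,
                   activation = FALSE)))
  structure(list(config = config, params = params,
                 buffers = list(b3 = .init_branch_buffers(config),
                                b2 = .init_branch_buffers(config)),
                 plans = .model_plans(config), seed = as.integer(seed)),
            class = "cfcnn_model")
}

#' @export
print.cfcnn_model <- function(x, ...) {
  cat(sprintf("<cfcnn_model> input %d, pooling %s, stages %s, %d parameters\n",
              x$config$input_size, x$config$pooling,
              paste(x$config$stage_sizes, collapse = " -> "),
              count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A `cfcnn_model`.
#' @return Total number of trainable scalars (conv/FC weights and biases,
#'   batch-norm scale/shift, PReLU slopes).
#' @export
count_parameters <- function(model) {
  n <- 0L
  walk <- function(x) for (v in x) if (is.list(v)) walk(v) else n <<- n + length(v)
  walk(model$params)
  n
}

# ---- im2col convolution ---------------------------------------------------

.im2col_cache <- new.env(parent = emptyenv())

# Gather indices into the sentinel vector c(0, as.vector(x)) for a "same"
# zero-padded 3 x 3 convolution on x of shape (H, W, B, C): out-of-bounds
# taps read the sentinel zero at position 1.
.conv_idx <- function(H, W, C, B) {
  key <- paste(H, W, C, B, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  ij <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H))   # output pixels
  plane <- matrix(0L, H * W, 9L)
  valid <- matrix(FALSE, H * W, 9L)
  o <- 0L
  for (dj in -1:1) for (di in -1:1) {
    o <- o + 1L
    r2 <- ij[, 1] + di; c2 <- ij[, 2] + dj
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    plane[, o] <- ifelse(ok, r2 + (c2 - 1L) * H, 0L)
    valid[, o] <- ok
  }
  HW <- H * W
  rowadd <- rep((0:(B - 1L)) * HW, each = HW)
  idx <- plane[rep(seq_len(HW), B), rep(seq_len(9L), C)]
  vbig <- valid[rep(seq_len(HW), B), rep(seq_len(9L), C)]
  idx <- idx + rowadd  # recycles down columns
  for (c in seq_len(C))
    idx[, 9L * (c - 1L) + 1:9] <- idx[, 9L * (c - 1L) + 1:9] + (c - 1L) * (HW * B)
  idx[!vbig] <- 0L
  idx <- idx + 1L      # sentinel at 1
  storage.mode(idx) <- "integer"
  ci <- list(idx = idx, H = H, W = W, C = C, B = B, n = HW * B * C)
  .im2col_cache[[key]] <- ci
  ci
}

# Reference (im2col) implementation, kept as an independent check of the
# compiled direct convolution. x: (H, W, B, C) -> (H, W, B, F).
.conv_forward_ref <- function(x, Wm, b) {
  d <- dim(x)
  ci <- .conv_idx(d[1], d[2], d[4], d[3])
  xv <- c(0, x)
  col <- xv[ci$idx]
  dim(col) <- dim(ci$idx)
  y <- col %*% Wm
  f <- ncol(Wm)
  for (k in seq_len(f)) y[, k] <- y[, k] + b[k]
  array(y, c(ci$H, ci$W, ci$B, f))
}

# Compiled direct 3x3 "same" convolution and its exact adjoint.
.conv_forward <- function(x, Wm, b) {
  .conv3x3_forward_cpp(x, dim(x), Wm, b)
}

.conv_backward <- function(dy, x, Wm) {
  .conv3x3_backward_cpp(dy, x, dim(x), Wm)
}

# ---- batch normalisation (per channel = last dim) -------------------------

.bn_eps <- 1e-5
.bn_momentum <- 0.1

.bn_forward <- function(x, gamma, beta, buf, mode) {
  d <- dim(x); C <- d[length(d)]
  m <- prod(d) / C
  xm <- x; dim(xm) <- c(m, C)
  if (mode == "eval") {
    # fold normalisation + affine into one scale/shift per channel
    istd <- 1 / sqrt(buf$rv + .bn_eps)
    sc <- gamma * istd
    sh <- beta - buf$rm * sc
    y <- xm
    for (c in seq_len(C)) y[, c] <- xm[, c] * sc[c] + sh[c]
    dim(y) <- d
    return(list(out = y, cache = NULL, buf = buf))
  }
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc^2)
  buf$rm <- (1 - .bn_momentum) * buf$rm + .bn_momentum * mu
  buf$rv <- (1 - .bn_momentum) * buf$rv + .bn_momentum * v
  istd <- 1 / sqrt(v + .bn_eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  dim(y) <- d
  list(out = y, cache = list(xhat = xhat, istd = istd, m = m, d = d),
       buf = buf)
}

.bn_backward <- function(dy, cache, gamma) {
  d <- cache$d; C <- d[length(d)]
  dym <- dy; dim(dym) <- c(cache$m, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, `*`)
  m <- cache$m
  t1 <- sweep(dxhat, 2L, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
  dx <- sweep(t1 - t2, 2L, cache$istd, `*`)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- PReLU (per channel = last dim of arrays; per column of matrices) -----

.prelu_forward <- function(x, a) {
  d <- dim(x); C <- d[length(d)]
  n <- prod(d) / C
  xm <- x; dim(xm) <- c(n, C)
  y <- xm
  for (c in seq_len(C)) {
    v <- xm[, c]
    neg <- v < 0
    v[neg] <- a[c] * v[neg]
    y[, c] <- v
  }
  dim(y) <- d
  list(out = y, cache = list(xm = xm, d = d))
}

.prelu_backward <- function(dy, cache, a) {
  d <- cache$d; C <- d[length(d)]
  n <- prod(d) / C
  dym <- dy; dim(dym) <- c(n, C)
  dx <- dym
  da <- numeric(C)
  for (c in seq_len(C)) {
    v <- cache$xm[, c]
    g <- dym[, c]
    neg <- v < 0
    da[c] <- sum(g[neg] * v[neg])
    g[neg] <- a[c] * g[neg]
    dx[, c] <- g
  }
  dim(dx) <- d
  list(dx = dx, da = da)
}

# ---- batched central pooling over (H, W, B, C) ----------------------------

.pool_hw_forward <- function(x, row_plan, col_plan) {
  d <- dim(x)  # H W B C
  xt <- aperm(x, c(2L, 1L, 3L, 4L))
  dim(xt) <- c(d[2], d[1] * d[3] * d[4])
  cp <- .pool_first_dim(xt, col_plan)
  Wc <- col_plan$n_out
  x1 <- array(cp$out, c(Wc, d[1], d[3], d[4]))
  x1 <- aperm(x1, c(2L, 1L, 3L, 4L))          # H, W', B, C
  m1 <- x1; dim(m1) <- c(d[1], Wc * d[3] * d[4])
  rp <- .pool_first_dim(m1, row_plan)
  Hr <- row_plan$n_out
  out <- array(rp$out, c(Hr, Wc, d[3], d[4]))
  list(out = out,
       cache = list(col_arg = cp$arg, row_arg = rp$arg, d = d,
                    Wc = Wc, Hr = Hr))
}

.pool_hw_backward <- function(dy, cache) {
  d <- cache$d
  dym <- dy; dim(dym) <- c(cache$Hr, cache$Wc * d[3] * d[4])
  g1 <- .unpool_first_dim(dym, cache$row_arg, d[1])       # H x (W' B C)
  g1 <- array(g1, c(d[1], cache$Wc, d[3], d[4]))
  g1 <- aperm(g1, c(2L, 1L, 3L, 4L))                       # W' H B C
  dim(g1) <- c(cache$Wc, d[1] * d[3] * d[4])
  g0 <- .unpool_first_dim(g1, cache$col_arg, d[2])         # W x (H B C)
  g0 <- array(g0, c(d[2], d[1], d[3], d[4]))
  aperm(g0, c(2L, 1L, 3L, 4L))
}

# ---- flatten / fully connected --------------------------------------------

.flatten_forward <- function(x) {
  d <- dim(x)  # H W B C
  xt <- aperm(x, c(1L, 2L, 4L, 3L))  # H W C B
  dim(xt) <- c(d[1] * d[2] * d[4], d[3])
  list(out = t(xt), d = d)
}

.flatten_backward <- function(dy, d) {
  g <- t(dy)
  dim(g) <- c(d[1], d[2], d[4], d[3])
  aperm(g, c(1L, 2L, 4L, 3L))
}

.fc_forward <- function(x, Wm, b) {
  y <- x %*% Wm
  for (k in seq_len(ncol(y))) y[, k] <- y[, k] + b[k]
  y
}

.fc_backward <- function(dy, x, Wm) {
  list(dW = crossprod(x, dy), db = colSums(dy), dx = tcrossprod(dy, Wm))
}

#' Numerically stable softmax over rows
#'
#' @param logits Matrix (samples x classes).
#' @return Matrix of row-normalised probabilities.
#' @export
softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- full network forward / backward --------------------------------------

.branch_forward <- function(pb, bufs, x, plans, mode) {
  cache <- list()
  h <- x
  stage <- 0L
  for (nm in .conv_names) {
    ly <- pb[[nm]]
    cv <- .conv_forward(h, ly$W, ly$b)
    bn <- .bn_forward(cv, ly$gamma, ly$beta, bufs[[nm]], mode)
    bufs[[nm]] <- bn$buf
    pr <- .prelu_forward(bn$out, ly$a)
    cache[[nm]] <- list(x_in = h, bn = bn$cache, pr = pr$cache)
    h <- pr$out
    stage <- stage + 1L
    if (stage == 2L || stage == 4L) {
      plan <- if (stage == 2L) plans$p1 else plans$p2
      pl <- .pool_hw_forward(h, plan, plan)
      cache[[paste0("pool", stage / 2L)]] <- pl$cache
      h <- pl$out
    }
  }
  fl <- .flatten_forward(h)
  cache$flatten_d <- fl$d
  cache$fc_in <- fl$out
  z <- .fc_forward(fl$out, pb$fc$W, pb$fc$b)
  pr <- .prelu_forward(z, pb$fc$a)
  cache$fc_pr <- pr$cache
  list(out = pr$out, cache = cache, bufs = bufs)
}

.branch_backward <- function(pb, cache, dout) {
  g <- list()
  pr <- .prelu_backward(dout, cache$fc_pr, pb$fc$a)
  fcb <- .fc_backward(pr$dx, cache$fc_in, pb$fc$W)
  g$fc <- list(W = fcb$dW, b = fcb$db, a = pr$da)
  dh <- .flatten_backward(fcb$dx, cache$flatten_d)
  for (stage in c(6L, 5L, 4L, 3L, 2L, 1L)) {
    if (stage == 4L) dh <- .pool_hw_backward(dh, cache$pool2)
    if (stage == 2L) dh <- .pool_hw_backward(dh, cache$pool1)
    nm <- .conv_names[stage]
    ly <- pb[[nm]]; cc <- cache[[nm]]
    pr <- .prelu_backward(dh, cc$pr, ly$a)
    bn <- .bn_backward(pr$dx, cc$bn, ly$gamma)
    cv <- .conv_backward(bn$dx, cc$x_in, ly$W)
    g[[nm]] <- list(W = cv$dW, b = cv$db, gamma = bn$dgamma, beta = bn$dbeta,
                    a = pr$da)
    dh <- cv$dx
  }
  g
}

.model_forward <- function(model, x3, x2, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  f3 <- .branch_forward(model$params$b3, model$buffers$b3, x3, model$plans, mode)
  f2 <- .branch_forward(model$params$b2, model$buffers$b2, x2, model$plans, mode)
  concat <- cbind(f3$out, f2$out)
  z8 <- .fc_forward(concat, model$params$fused$W, model$params$fused$b)
  pr8 <- .prelu_forward(z8, model$params$fused$a)
  logits <- .fc_forward(pr8$out, model$params$out$W, model$params$out$b)
  probs <- softmax(logits)
  list(probs = probs, logits = logits,
       cache = list(f3 = f3, f2 = f2, concat = concat, pr8 = pr8$cache,
                    f8 = pr8$out),
       buffers = list(b3 = f3$bufs, b2 = f2$bufs))
}

# Collect the 1-norm of conv/FC weight matrices (biases, BN and PReLU
# parameters excluded).
.l1_weights <- function(params) {
  s <- 0
  walk <- function(x) {
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v)) walk(v) else if (nm == "W") s <<- s + sum(abs(v))
    }
  }
  walk(params)
  s
}

#' Cross-entropy loss with 1-norm regularisation
#'
#' `L = -(1/N) sum[y log p + (1 - y) log(1 - p)] + lambda * sum |W|`,
#' probabilities clamped at 1e-7 to avoid `log(0)`. The regulariser runs
#' over convolutional and fully connected weight matrices only.
#'
#' @param probabilities Predicted nodule probability per sample (vector),
#'   or a samples x 2 matrix of class probabilities (column 2 = nodule).
#' @param labels Integer labels in {0, 1}.
#' @param weights Optional `cfcnn_model` (or its `params` list) supplying
#'   the weights for the 1-norm term.
#' @param lambda Regularisation strength.
#' @return Scalar loss.
#' @export
loss_fn <- function(probabilities, labels, weights = NULL, lambda = 0) {
  p <- if (is.matrix(probabilities)) probabilities[, 2L] else as.numeric(probabilities)
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("loss_fn: labels must be in {0, 1}")
  stopifnot(length(p) == length(y), length(p) >= 1L)
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  ce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  reg <- 0
  if (!is.null(weights) && lambda > 0) {
    params <- if (inherits(weights, "cfcnn_model")) weights$params else weights
    reg <- lambda * .l1_weights(params)
  }
  ce + reg
}

#' Loss and exact parameter gradients for one mini-batch
#'
#' Runs the network in training mode (batch statistics) and backpropagates
#' the cross-entropy + 1-norm objective through every layer, including the
#' central pooling argmax routing.
#'
#' @param model A `cfcnn_model`.
#' @param x3 Array `(size, size, batch, channels_3d)`: tri-slice patches.
#' @param x2 Array `(size, size, batch, channels_2d)`: multi-scale patches.
#' @param labels Integer vector in {0, 1}, length batch.
#' @param lambda 1-norm strength; defaults to the model's `lambda_l1`.
#' @return List: `loss`, `probs` (batch x 2), `grads` (same nesting as
#'   `model$params`) and `buffers` (updated batch-norm running statistics).
#' @export
model_gradients <- function(model, x3, x2, labels, lambda = NULL) {
  if (is.null(lambda)) lambda <- model$config$lambda_l1
  y <- as.integer(labels)
  B <- dim(x3)[3]
  stopifnot(length(y) == B, all(y %in% c(0L, 1L)))
  fw <- .model_forward(model, x3, x2, mode = "train")
  loss <- loss_fn(fw$probs, y, weights = model, lambda = lambda)
  Y <- cbind(1 - y, y)
  dlogits <- (fw$probs - Y) / B
  ob <- .fc_backward(dlogits, fw$cache$f8, model$params$out$W)
  g_out <- list(W = ob$dW, b = ob$db)
  pr8 <- .prelu_backward(ob$dx, fw$cache$pr8, model$params$fused$a)
  fb <- .fc_backward(pr8$dx, fw$cache$concat, model$params$fused$W)
  g_fused <- list(W = fb$dW, b = fb$db, a = pr8$da)
  nb <- model$config$fc_branch
  g_b3 <- .branch_backward(model$params$b3, fw$cache$f3$cache,
                           fb$dx[, seq_len(nb), drop = FALSE])
  g_b2 <- .branch_backward(model$params$b2, fw$cache$f2$cache,
                           fb$dx[, nb + seq_len(nb), drop = FALSE])
  grads <- list(b3 = g_b3, b2 = g_b2, fused = g_fused, out = g_out)
  if (lambda > 0) grads <- .add_l1_grad(grads, model$params, lambda)
  list(loss = loss, probs = fw$probs, grads = grads, buffers = fw$buffers)
}

.add_l1_grad <- function(grads, params, lambda) {
  for (nm in names(grads)) {
    if (is.list(grads[[nm]]) && !is.null(names(grads[[nm]])) &&
        !is.null(grads[[nm]]$W)) {
      grads[[nm]]$W <- grads[[nm]]$W + lambda * sign(params[[nm]]$W)
    } else if (is.list(grads[[nm]])) {
      grads[[nm]] <- .add_l1_grad(grads[[nm]], params[[nm]], lambda)
    }
  }
  grads
}

# ---- optimiser ------------------------------------------------------------

.tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, .tree_map, f = f) else f(x)
}

.tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- .tree_map2(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

.check_finite_tree <- function(x, path = "params") {
  if (is.list(x)) {
    for (nm in names(x)) .check_finite_tree(x[[nm]], paste(path, nm, sep = "$"))
  } else if (any(!is.finite(x))) {
    stop("non-finite gradient in ", path)
  }
  invisible(TRUE)
}

#' Initialise optimiser state
#'
#' @param model A `cfcnn_model`.
#' @return List with iteration counter `t = 0` and zero velocity `V`
#'   matching the parameter tree.
#' @export
optimizer_state <- function(model) {
  list(t = 0L, V = .tree_map(model$params, function(x) x * 0))
}

#' One momentum-SGD update
#'
#' `V <- mu V - alpha grad`, `W <- W + V`, with `alpha` from
#' [lr_schedule()] at the state's current iteration; the iteration counter
#' then increments.
#'
#' @param weights Parameter tree (e.g. `model$params`).
#' @param gradient Gradient tree of the same shape.
#' @param state Optimiser state from [optimizer_state()].
#' @param cfg A [train_config].
#' @return List `weights`, `state` after the update.
#' @export
sgd_step <- function(weights, gradient, state, cfg) {
  .check_finite_tree(gradient, "grad")
  alpha <- lr_schedule(state$t, cfg)
  state$V <- .tree_map2(state$V, gradient,
                        function(v, g) cfg$momentum * v - alpha * g)
  weights <- .tree_map2(weights, state$V, `+`)
  state$t <- state$t + 1L
  list(weights = weights, state = state)
}

# ---- patch stacking and prediction ----------------------------------------

# list of patch_pair -> list(x3 = (s, s, N, c3), x2 = (s, s, N, c2))
.stack_patches <- function(patches) {
  stopifnot(length(patches) > 0L)
  d3 <- dim(patches[[1]]$three_d)  # c3, s, s
  d2 <- dim(patches[[1]]$two_d)
  n <- length(patches)
  a3 <- vapply(patches, function(p) p$three_d, patches[[1]]$three_d)
  a2 <- vapply(patches, function(p) p$two_d, patches[[1]]$two_d)
  dim(a3) <- c(d3, n); dim(a2) <- c(d2, n)
  list(x3 = aperm(a3, c(2L, 3L, 4L, 1L)), x2 = aperm(a2, c(2L, 3L, 4L, 1L)))
}

#' Predict nodule probabilities for patch pairs
#'
#' Generic so that plug-in classifiers (e.g. a ground-truth oracle used to
#' test the segmentation pipeline) can stand in for the network.
#'
#' @param model Classifier object.
#' @param patches List of `patch_pair`s.
#' @param ... Method-specific arguments.
#' @return Numeric vector of nodule probabilities, one per patch.
#' @export
predict_batch <- function(model, patches, ...) UseMethod("predict_batch")

#' @rdname predict_batch
#' @param batch_size Forward-pass chunk size.
#' @export
predict_batch.cfcnn_model <- function(model, patches, batch_size = 128L, ...) {
  if (length(patches) == 0L) return(numeric(0))
  st <- .stack_patches(patches)
  n <- dim(st$x3)[3]
  p <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fw <- .model_forward(model,
                         st$x3[, , i:j, , drop = FALSE],
                         st$x2[, , i:j, , drop = FALSE], mode = "eval")
    p[i:j] <- fw$probs[, 2L]
    i <- j + 1L
  }
  p
}

# ---- training -------------------------------------------------------------

#' Train the network with momentum SGD and epoch-wise validation
#'
#' Shuffled mini-batch SGD on labelled patch pairs; after every epoch the
#' model segments each validation phantom end-to-end (via [segment()]) and
#' the mean validation DSC is recorded. The weights with the best
#' validation DSC are returned. Deterministic given `cfg$seed`.
#'
#' @param model A `cfcnn_model`.
#' @param samples List of `patch_pair`s.
#' @param labels Integer vector in {0, 1}, one per sample.
#' @param val_phantoms Nonempty list of `phantom_sample`s for validation.
#' @param cfg A [train_config].
#' @param threshold Probability threshold for validation segmentation.
#' @param spec [patch_spec] used when segmenting validation phantoms.
#' @param verbose Print per-epoch progress.
#' @return The trained `cfcnn_model`, with a `history` data.frame
#'   (`epoch`, `mean_loss`, `val_dsc`, `lr`) attached.
#' @export
train <- function(model, samples, labels, val_phantoms, cfg = train_config(),
                  threshold = 0.5, spec = patch_spec(), verbose = FALSE) {
  if (length(samples) == 0L) stop("train: empty training set")
  if (length(val_phantoms) == 0L) stop("train: validation set must be nonempty")
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(samples), all(labels %in% c(0L, 1L)))
  st <- .stack_patches(samples)
  n <- length(samples)
  state <- optimizer_state(model)
  best <- list(dsc = -Inf, params = model$params, buffers = model$buffers)
  hist <- data.frame()
  stale <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- .with_seed(cfg$seed + epoch, sample.int(n))
    losses <- c()
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1L, n)
      b <- ord[i:j]
      res <- model_gradients(model,
                             st$x3[, , b, , drop = FALSE],
                             st$x2[, , b, , drop = FALSE],
                             labels[b])
      model$buffers <- res$buffers
      up <- sgd_step(model$params, res$grads, state, cfg)
      model$params <- up$weights
      state <- up$state
      losses <- c(losses, res$loss)
      i <- j + 1L
    }
    dscs <- vapply(val_phantoms, function(ph) {
      out <- tryCatch(segment(model, ph$volume, ph$start_box,
                              threshold = threshold, spec = spec),
                      error = function(e) NULL)
      if (is.null(out)) 0 else dice(ph$mask, out$mask)
    }, numeric(1))
    vdsc <- mean(dscs)
    hist <- rbind(hist, data.frame(epoch = epoch, mean_loss = mean(losses),
                                   val_dsc = vdsc,
                                   lr = lr_schedule(state$t, cfg)))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val DSC %.4f", epoch,
                      mean(losses), vdsc))
    if (vdsc > best$dsc) {
      best <- list(dsc = vdsc, params = model$params, buffers = model$buffers)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$buffers <- best$buffers
  model$history <- hist
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint archives weights, configs and (optionally) optimiser
#' state in a single file.
#'
#' @param model A `cfcnn_model`.
#' @param path Checkpoint file path.
#' @param state Optional optimiser state.
#' @param train_cfg Optional [train_config].
#' @return `path` invisibly ([save_checkpoint()]); the restored model
#'   ([load_checkpoint()]), with `state`/`train_cfg` attached as attributes
#'   when present.
#' @export
save_checkpoint <- function(model, path, state = NULL, train_cfg = NULL) {
  saveRDS(list(model = model, state = state, train_cfg = train_cfg,
               format = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- ck$model
  attr(m, "optimizer_state") <- ck$state
  attr(m, "train_config") <- ck$train_cfg
  m
}
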