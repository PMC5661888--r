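# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# Brute-force central-pooling oracle: max over each rectangular window
# formed by the row/column segments of the two plans.
brute_pool <- function(x, row_plan, col_plan) {
  out <- matrix(0, row_plan$n_out, col_plan$n_out)
  for (i in seq_len(row_plan$n_out))
    for (j in seq_len(col_plan$n_out))
      out[i, j] <- max(x[row_plan$starts[i]:row_plan$ends[i],
                         col_plan$starts[j]:col_plan$ends[j]])
  out
}

# Natural interpolating cubic spline on the uniform grid 1..n, evaluated at
# xq, by solving the classical tridiagonal second-derivative system with
# base solve() -- independent of stats::splinefun.
natural_spline_oracle <- function(y, xq) {
  n <- length(y)
  M <- numeric(n)                       # second derivatives, M[1] = M[n] = 0
  if (n > 2) {
    k <- n - 2
    A <- diag(4, k)
    if (k > 1) {
      A[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- 1
      A[cbind(seq_len(k - 1) + 1, seq_len(k - 1))] <- 1
    }
    rhs <- 6 * (y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)])
    M[2:(n - 1)] <- solve(A, rhs)
  }
  vapply(xq, function(q) {
    i <- min(max(floor(q), 1), n - 1)
    t <- q - i
    b <- (y[i + 1] - y[i]) - (2 * M[i] + M[i + 1]) / 6
    y[i] + b * t + (M[i] / 2) * t^2 + ((M[i + 1] - M[i]) / 6) * t^3
  }, numeric(1))
}

# O(n^2) brute-force Euclidean distance of every cell to the nearest source.
brute_edt <- function(src) {
  src <- as.matrix(src)
  pts <- which(src, arr.ind = TRUE)
  out <- matrix(0, nrow(src), ncol(src))
  for (i in seq_len(nrow(src))) for (j in seq_len(ncol(src)))
    out[i, j] <- sqrt(min((pts[, 1] - i)^2 + (pts[, 2] - j)^2))
  out
}

# All-pairs brute-force average surface distance with an independently
# computed 6-neighbourhood surface.
brute_asd <- function(g, a, spacing) {
  surface <- function(m) {
    d <- dim(m)
    idx <- which(m == 1, arr.ind = TRUE)
    keep <- apply(idx, 1, function(v) {
      for (k in 1:3) for (s in c(-1, 1)) {
        w <- v; w[k] <- w[k] + s
        if (any(w < 1) || any(w > d)) return(TRUE)
        if (m[w[1], w[2], w[3]] == 0) return(TRUE)
      }
      FALSE
    })
    idx[keep, , drop = FALSE]
  }
  sg <- sweep(surface(g), 2, spacing, `*`)
  sa <- sweep(surface(a), 2, spacing, `*`)
  dmin <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      sqrt(min(colSums((t(q) - p[i, ])^2))), numeric(1))
  }
  (mean(dmin(sg, sa)) + mean(dmin(sa, sg))) / 2
}

# Binary ball mask inside a given array shape (1-based centre).
ball_mask <- function(shape, center, radius) {
  d2 <- outer(outer((seq_len(shape[1]) - center[1])^2,
                    (seq_len(shape[2]) - center[2])^2, `+`),
              (seq_len(shape[3]) - center[3])^2, `+`)
  array(as.integer(d2 <= radius^2), shape)
}

# 26-connectivity check of a 3-D binary mask by BFS over the voxel list.
is_connected_26 <- function(mask) {
  pts <- which(mask == 1, arr.ind = TRUE)
  n <- nrow(pts)
  if (n <= 1) return(TRUE)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (f in frontier) {
      adj <- which(!seen &
                     abs(pts[, 1] - pts[f, 1]) <= 1 &
                     abs(pts[, 2] - pts[f, 2]) <= 1 &
                     abs(pts[, 3] - pts[f, 3]) <= 1)
      seen[adj] <- TRUE
      nxt <- c(nxt, adj)
    }
    frontier <- nxt
  }
  all(seen)
}

# A classifier scripted by an arbitrary probability volume; registered so
# package-internal generic dispatch finds it.
probability_classifier <- function(prob) {
  structure(list(prob = prob), class = "probability_classifier")
}
predict_batch.probability_classifier <- function(model, patches, ...) {
  vapply(patches, function(p) {
    v <- p$target + 1L
    model$prob[v[1], v[2], v[3]]
  }, numeric(1))
}
registerS3method("predict_batch", "probability_classifier",
                 predict_batch.probability_classifier,
                 envir = asNamespace("cfcnn"))

# Small constant-intensity volume helper
flat_volume <- function(shape = c(6L, 20L, 20L), value = 0,
                        spacing = c(1, 1, 1)) {
  ct_volume(array(value, shape), spacing = spacing, volume_id = "flat")
}
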