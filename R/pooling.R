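#' Kernel-count look-up table for central pooling
#'
#' Central pooling halves an axis of length `O` using 1-D max-pooling kernels
#' of sizes 1, 2 and 3. Base counts `(floor(O/8), floor(O/4), floor(O/8))`
#' leave a residual of `r` uncovered positions; this table assigns, for each
#' residual `r` in 0..7, how many extra kernels of each size are added so
#' that the column covers exactly `r` positions.
#'
#' @return 3 x 8 integer matrix; rows are kernel sizes `s = 1..3`, columns
#'   residuals `r = 0..7` (dimnames `s1..s3` / `r0..r7`).
#' @examples
#' L <- kernel_lookup_table()
#' colSums(L * 1:3)  # each column covers exactly its residual
#' @export
kernel_lookup_table <- function() {
  L <- matrix(c(
    # r: 0  1  2  3  4  5  6  7
         0, 1, 0, 1, 0, 0, 0, 0,   # s = 1
         0, 0, 1, 1, 2, 1, 3, 2,   # s = 2
         0, 0, 0, 0, 0, 1, 0, 1),  # s = 3
    nrow = 3, byrow = TRUE,
    dimnames = list(paste0("s", 1:3), paste0("r", 0:7)))
  storage.mode(L) <- "integer"
  stopifnot(identical(as.integer(colSums(L * 1:3)), 0:7))
  L
}

#' Solve the central-pooling kernel counts for an axis
#'
#' Determines how many size-1, size-2 and size-3 max-pooling kernels tile an
#' axis of length `O` such that (i) kernel lengths sum to `O`, (ii) the
#' pooled axis has about `O/2` positions and (iii) about half of all kernels
#' have size 2. Base counts are `(floor(O/8), floor(O/4), floor(O/8))`; the
#' residual `r = O - (n1 + 2 n2 + 3 n3)` of uncovered positions is
#' distributed via [kernel_lookup_table()].
#'
#' @param O Axis length, integer >= 1.
#' @return List with integer fields `n1`, `n2`, `n3` (kernel counts),
#'   `r` (residual) and `n_out = n1 + n2 + n3` (pooled length).
#' @examples
#' solve_kernel_counts(9)   # n1 = 2, n2 = 2, n3 = 1
#' solve_kernel_counts(35)  # pools 35 -> 18
#' @export
solve_kernel_counts <- function(O) {
  O <- as.integer(O)[1]
  if (is.na(O) || O < 1L) stop("solve_kernel_counts: O must be an integer >= 1")
  base1 <- O %/% 8L
  base2 <- O %/% 4L
  base3 <- O %/% 8L
  r <- O - (base1 + 2L * base2 + 3L * base3)
  stopifnot(r >= 0L, r <= 7L)
  L <- kernel_lookup_table()
  n1 <- base1 + L[1L, r + 1L]
  n2 <- base2 + L[2L, r + 1L]
  n3 <- base3 + L[3L, r + 1L]
  stopifnot(n1 + 2L * n2 + 3L * n3 == O)
  list(n1 = n1, n2 = n2, n3 = n3, r = r, n_out = n1 + n2 + n3)
}

#' Lay kernels out symmetrically along the axis
#'
#' Larger kernels are placed outermost and the size-1 kernels contiguous in
#' the centre, so pooling keeps full resolution at the patch centre — the
#' voxel being classified. Each size's count is split between the two
#' halves; with the default `bias = "left"`, an odd count of size-3 kernels
#' puts its extra kernel on the low-index side and an odd count of size-2
#' kernels on the high-index side. This alternation reproduces the
#' canonical layout `{3, 2, 1, 1, 2}` for counts (2, 2, 1) and guarantees
#' that the centre window of every odd-length plan with `n1 > 0` has size
#' 1; `bias = "right"` mirrors the layout.
#'
#' @param n1,n2,n3 Kernel counts, non-negative, not all zero.
#' @param bias Which half absorbs the odd-count extras (see above).
#' @return Integer vector of kernel sizes in axis order.
#' @examples
#' build_kernel_order(2, 2, 1)  # 3 2 1 1 2
#' @export
build_kernel_order <- function(n1, n2, n3, bias = c("left", "right")) {
  bias <- match.arg(bias)
  n <- vapply(list(n1, n2, n3), function(x) as.integer(x)[1], integer(1))
  if (anyNA(n) || any(n < 0L)) stop("build_kernel_order: counts must be >= 0")
  if (sum(n) == 0L) stop("build_kernel_order: at least one kernel is required")
  if (bias == "left") {
    l3 <- ceiling(n[3] / 2); l2 <- floor(n[2] / 2)
  } else {
    l3 <- floor(n[3] / 2); l2 <- ceiling(n[2] / 2)
  }
  as.integer(c(rep(3L, l3), rep(2L, l2), rep(1L, n[1]),
               rep(2L, n[2] - l2), rep(3L, n[3] - l3)))
}

#' Build the full pooling plan for one axis
#'
#' @param O Axis length.
#' @param bias Passed to [build_kernel_order()].
#' @return Object of class `pooling_plan`: fields `O`, `n1`, `n2`, `n3`,
#'   `r`, `order` (kernel sizes), `starts`/`ends` (1-based inclusive window
#'   extents) and `n_out`.
#' @examples
#' pooling_plan(35)$n_out  # 18
#' @export
pooling_plan <- function(O, bias = "left") {
  k <- solve_kernel_counts(O)
  ord <- build_kernel_order(k$n1, k$n2, k$n3, bias = bias)
  .finish_plan(ord, k)
}

.finish_plan <- function(ord, counts) {
  ends <- cumsum(ord)
  starts <- ends - ord + 1L
  structure(list(O = as.integer(sum(ord)), n1 = counts$n1, n2 = counts$n2,
                 n3 = counts$n3, r = counts$r, order = ord,
                 starts = as.integer(starts), ends = as.integer(ends),
                 n_out = length(ord)),
            class = "pooling_plan")
}

#' @export
print.pooling_plan <- function(x, ...) {
  cat(sprintf("<pooling_plan> O=%d -> %d windows (n1=%d, n2=%d, n3=%d, r=%d)\n  order: %s\n",
              x$O, x$n_out, x$n1, x$n2, x$n3, x$r,
              paste(x$order, collapse = " ")))
  invisible(x)
}

#' Uniform 2/2 max-pooling plan (ablation variant)
#'
#' Builds a plan of `O/2` size-2 kernels so [central_pool_forward()]
#' reproduces traditional 2 x 2, stride-2 max pooling. Used for the
#' uniform-pooling ablation of the network.
#'
#' @param O Even axis length.
#' @return A `pooling_plan` of all-size-2 kernels.
#' @export
as_uniform_max_pool <- function(O) {
  O <- as.integer(O)[1]
  if (is.na(O) || O < 2L || O %% 2L != 0L)
    stop("as_uniform_max_pool: O must be a positive even integer")
  ord <- rep(2L, O %/% 2L)
  .finish_plan(ord, list(n1 = 0L, n2 = O %/% 2L, n3 = 0L, r = 0L))
}

# Internal: 1-D max pooling along the FIRST dimension of a matrix.
# Returns out (n_out x K) and arg (n_out x K): the input row supplying each
# max. Ties resolve to the lowest row index (strict > comparison).
.pool_first_dim <- function(m, plan) {
  stopifnot(nrow(m) == plan$O)
  K <- ncol(m)
  out <- matrix(0, plan$n_out, K)
  arg <- matrix(0L, plan$n_out, K)
  for (t in seq_len(plan$n_out)) {
    s0 <- plan$starts[t]; s1 <- plan$ends[t]
    v <- m[s0, ]
    a <- rep.int(s0, K)
    if (s1 > s0) for (rr in (s0 + 1L):s1) {
      w <- m[rr, ]
      upd <- w > v
      if (any(upd)) { v[upd] <- w[upd]; a[upd] <- rr }
    }
    out[t, ] <- v
    arg[t, ] <- a
  }
  list(out = out, arg = arg)
}

# Internal: adjoint of .pool_first_dim.
.unpool_first_dim <- function(up, arg, O) {
  g <- matrix(0, O, ncol(up))
  off <- (col(up) - 1L) * O
  idx <- as.vector(arg + off)
  g[idx] <- g[idx] + as.vector(up)  # windows are disjoint: no index repeats
  g
}

#' Central pooling forward pass on a 2-D feature map
#'
#' Applies the plan's contiguous, non-overlapping 1-D max windows first
#' along the columns within each row, then along the rows (the composition
#' equals a max over the rectangular window formed by the two segments).
#' The returned argmax map records, per output cell, the input coordinate
#' that supplied the maximum, enabling an exact backward pass.
#'
#' @param x Numeric matrix of shape `(row_plan$O, col_plan$O)`.
#' @param row_plan,col_plan `pooling_plan`s for the two axes.
#' @return List: `pooled` (`row_out x col_out` matrix), `arg_row`/`arg_col`
#'   (integer matrices of the same shape, 1-based input coordinates).
#' @examples
#' p <- as_uniform_max_pool(2)
#' central_pool_forward(matrix(1:4, 2, 2), p, p)$pooled  # global max 4
#' @export
central_pool_forward <- function(x, row_plan, col_plan) {
  stopifnot(inherits(row_plan, "pooling_plan"), inherits(col_plan, "pooling_plan"))
  x <- as.matrix(x)
  if (nrow(x) != row_plan$O || ncol(x) != col_plan$O)
    stop("central_pool_forward: map is ", nrow(x), " x ", ncol(x),
         " but plans expect ", row_plan$O, " x ", col_plan$O)
  # column pooling (within each row): pool first dim of t(x)
  cp <- .pool_first_dim(t(x), col_plan)
  inter <- t(cp$out)            # nrow(x) x col_out
  inter_argcol <- t(cp$arg)     # source column per (row, out_col)
  # row pooling
  rp <- .pool_first_dim(inter, row_plan)
  pooled <- rp$out              # row_out x col_out
  arg_row <- rp$arg             # source row in `inter` == source input row
  # compose the column argmax through the chosen row
  arg_col <- matrix(0L, nrow(pooled), ncol(pooled))
  for (u in seq_len(ncol(pooled)))
    arg_col[, u] <- inter_argcol[arg_row[, u], u]
  list(pooled = pooled, arg_row = arg_row, arg_col = arg_col)
}

#' Central pooling backward pass
#'
#' Routes each upstream gradient value to the input position recorded in the
#' forward argmax map; all other positions receive zero. Because windows are
#' non-overlapping, no input position is written twice (asserted).
#'
#' @param upstream Gradient w.r.t. the pooled map (`row_out x col_out`).
#' @param argmax The `arg_row`/`arg_col` pair (or full list) returned by
#'   [central_pool_forward()].
#' @param input_shape Length-2 integer, shape of the original feature map.
#' @return Gradient matrix of shape `input_shape`.
#' @export
central_pool_backward <- function(upstream, argmax, input_shape) {
  upstream <- as.matrix(upstream)
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 2L)
  ar <- argmax$arg_row; ac <- argmax$arg_col
  if (is.null(ar) || is.null(ac))
    stop("central_pool_backward: argmax must carry arg_row and arg_col")
  if (!all(dim(upstream) == dim(ar)))
    stop("central_pool_backward: upstream shape does not match the argmax map")
  idx <- (as.vector(ac) - 1L) * input_shape[1] + as.vector(ar)
  if (anyDuplicated(idx))
    stop("central_pool_backward: overlapping windows detected")
  g <- matrix(0, input_shape[1], input_shape[2])
  g[idx] <- as.vector(upstream)
  g
}
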