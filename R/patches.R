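#' Patch extraction specification
#'
#' Geometry of the two network inputs built for every target voxel: a
#' tri-slice `n_slices x size_2d x size_2d` patch for the 3-D branch and a
#' two-channel multi-scale patch (a `size_2d_large` crop rescaled down to
#' `size_2d`, stacked with the native `size_2d` crop) for the 2-D branch.
#'
#' @param size_2d Odd in-plane patch width (native scale), default 35.
#' @param size_2d_large Odd width of the large crop, default 65.
#' @param n_slices Odd number of adjacent slices in the 3-D patch, default 3.
#' @param spline_order Interpolation order for the rescale; only 3 (cubic)
#'   is supported.
#' @param normalize_2d Z-score each 2-D channel independently (the 3-D patch
#'   is always z-scored jointly).
#' @return Object of class `patch_spec`.
#' @export
patch_spec <- function(size_2d = 35L, size_2d_large = 65L, n_slices = 3L,
                       spline_order = 3L, normalize_2d = TRUE) {
  size_2d <- as.integer(size_2d); size_2d_large <- as.integer(size_2d_large)
  n_slices <- as.integer(n_slices)
  if (size_2d %% 2L == 0L || size_2d_large %% 2L == 0L || n_slices %% 2L == 0L)
    stop("patch_spec: sizes and slice count must be odd")
  if (size_2d_large <= size_2d)
    stop("patch_spec: size_2d_large must exceed size_2d")
  if (as.integer(spline_order) != 3L)
    stop("patch_spec: only third-order (cubic) spline rescaling is supported")
  structure(list(size_2d = size_2d, size_2d_large = size_2d_large,
                 n_slices = n_slices, pad_mode = "reflect",
                 spline_order = 3L, normalize_2d = isTRUE(normalize_2d)),
            class = "patch_spec")
}

#' Reflect out-of-range indices back into 1..n
#'
#' Symmetric (edge-repeating) reflection: index 0 maps to 1, index n+1 to n.
#' Used for all border handling in patch extraction.
#'
#' @param idx Integer vector of (possibly out-of-range) 1-based indices.
#' @param n Axis length.
#' @return Integer vector of in-range indices.
#' @export
reflect_index <- function(idx, n) {
  n <- as.integer(n)
  if (n == 1L) return(rep.int(1L, length(idx)))
  j <- (as.integer(idx) - 1L) %% (2L * n)
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  j + 1L
}

# z-score a numeric array jointly; all zeros when sd degenerates. The
# threshold is relative to the patch magnitude so that constant patches
# that picked up rounding noise (e.g. through spline rescaling) still
# count as degenerate.
.zscore <- function(x) {
  m <- mean(x)
  s <- stats::sd(as.vector(x))
  if (!is.finite(s) || s <= 1e-10 * max(1, abs(m))) {
    x[] <- 0
    attr(x, "x_mean") <- m; attr(x, "x_std") <- 0
    return(x)
  }
  y <- (x - m) / s
  attr(y, "x_mean") <- m; attr(y, "x_std") <- s
  y
}

# Cache of spline resize operators keyed by "n_in->n_out".
.resize_cache <- new.env(parent = emptyenv())

#' Cubic-spline resampling operator
#'
#' Natural interpolating cubic splines reduce 1-D resampling on a fixed grid
#' to a linear map; this returns the `n_out x n_in` matrix that evaluates
#' the spline through `n` samples at `n_out` equally spaced query points
#' spanning the same extent (endpoints aligned). Separable application
#' (`M %*% P %*% t(M)`) rescales a 2-D patch.
#'
#' @param n_in,n_out Input and output sample counts.
#' @return `n_out x n_in` dense matrix (cached across calls).
#' @export
spline_resize_matrix <- function(n_in, n_out) {
  key <- paste0(n_in, "->", n_out)
  if (!is.null(.resize_cache[[key]])) return(.resize_cache[[key]])
  xq <- seq(1, n_in, length.out = n_out)
  M <- matrix(0, n_out, n_in)
  basis <- numeric(n_in)
  for (i in seq_len(n_in)) {
    basis[] <- 0; basis[i] <- 1
    f <- stats::splinefun(seq_len(n_in), basis, method = "natural")
    M[, i] <- f(xq)
  }
  .resize_cache[[key]] <- M
  M
}

.check_voxel <- function(volume, voxel) {
  voxel <- as.integer(voxel)
  if (length(voxel) != 3L) stop("voxel must be a (slice, row, col) triple")
  d <- dim(volume$voxels)
  if (any(voxel < 0L) || any(voxel >= d))
    stop("voxel (", paste(voxel, collapse = ", "),
         ") lies outside the volume of shape ",
         paste(d, collapse = " x "))
  voxel
}

#' Extract the tri-slice 3-D patch for a target voxel
#'
#' Crops `n_slices` adjacent slices centred on the voxel (preceding /
#' current / subsequent for the default of 3), each `size_2d x size_2d`,
#' with reflect border handling on every axis, then z-scores all voxels of
#' the patch jointly: `f(x) = (x - x_mean) / x_std`. A constant patch
#' (zero standard deviation) returns all zeros.
#'
#' @param volume A [ct_volume].
#' @param voxel 0-based (slice, row, col) coordinate inside the volume.
#' @param spec A [patch_spec].
#' @return Numeric array `n_slices x size_2d x size_2d` with attributes
#'   `x_mean`, `x_std`.
#' @export
extract_3d_patch <- function(volume, voxel, spec = patch_spec()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(spec, "patch_spec"))
  voxel <- .check_voxel(volume, voxel)
  d <- dim(volume$voxels)
  hw <- spec$size_2d %/% 2L
  hs <- spec$n_slices %/% 2L
  sl <- reflect_index(voxel[1] + 1L + (-hs:hs), d[1])
  rw <- reflect_index(voxel[2] + 1L + (-hw:hw), d[2])
  cl <- reflect_index(voxel[3] + 1L + (-hw:hw), d[3])
  patch <- volume$voxels[sl, rw, cl, drop = FALSE]
  dim(patch) <- c(spec$n_slices, spec$size_2d, spec$size_2d)
  .zscore(patch)
}

# Crop one axial window (reflect-padded) from a slice, 0-based centre.
.crop_2d <- function(volume, voxel, width) {
  d <- dim(volume$voxels)
  h <- width %/% 2L
  rw <- reflect_index(voxel[2] + 1L + (-h:h), d[2])
  cl <- reflect_index(voxel[3] + 1L + (-h:h), d[3])
  m <- volume$voxels[voxel[1] + 1L, rw, cl, drop = FALSE]
  dim(m) <- c(width, width)
  m
}

#' Extract the two-channel multi-scale 2-D patch
#'
#' Channel 1 is the `size_2d_large` axial crop downscaled to
#' `size_2d x size_2d` by third-order spline interpolation; channel 2 is the
#' native `size_2d` crop. Each channel is z-scored independently when
#' `spec$normalize_2d` is `TRUE`.
#'
#' @inheritParams extract_3d_patch
#' @return Numeric array `2 x size_2d x size_2d`.
#' @export
extract_2d_multiscale_patch <- function(volume, voxel, spec = patch_spec()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(spec, "patch_spec"))
  voxel <- .check_voxel(volume, voxel)
  large <- .crop_2d(volume, voxel, spec$size_2d_large)
  native <- .crop_2d(volume, voxel, spec$size_2d)
  M <- spline_resize_matrix(spec$size_2d_large, spec$size_2d)
  rescaled <- M %*% large %*% t(M)
  if (spec$normalize_2d) {
    rescaled <- .zscore(rescaled)
    native <- .zscore(native)
  }
  out <- array(0, c(2L, spec$size_2d, spec$size_2d))
  out[1L, , ] <- rescaled
  out[2L, , ] <- native
  out
}

#' Build the full patch pair for one target voxel
#'
#' @inheritParams extract_3d_patch
#' @return Object of class `patch_pair`: `three_d` (z-scored tri-slice
#'   patch), `two_d` (2-channel multi-scale patch), `target` (the 0-based
#'   voxel), `x_mean` / `x_std` (normalisation constants of the 3-D patch).
#' @export
extract_patch_pair <- function(volume, voxel, spec = patch_spec()) {
  p3 <- extract_3d_patch(volume, voxel, spec)
  p2 <- extract_2d_multiscale_patch(volume, voxel, spec)
  structure(list(three_d = p3, two_d = p2, target = as.integer(voxel),
                 x_mean = attr(p3, "x_mean"), x_std = attr(p3, "x_std")),
            class = "patch_pair")
}

#' Extract patch pairs for a list of voxels
#'
#' Order-preserving; identical to calling [extract_patch_pair()] per voxel.
#' An empty input yields an empty list.
#'
#' @param volume A [ct_volume].
#' @param voxels Integer matrix with one 0-based (slice, row, col) row per
#'   voxel, or a list of such triples.
#' @param spec A [patch_spec].
#' @return List of `patch_pair` objects.
#' @export
batch_patches <- function(volume, voxels, spec = patch_spec()) {
  if (is.list(voxels)) {
    if (length(voxels) == 0L) return(list())
    voxels <- do.call(rbind, voxels)
  }
  if (is.null(voxels) || NROW(voxels) == 0L) return(list())
  voxels <- matrix(as.integer(voxels), ncol = 3L)
  lapply(seq_len(nrow(voxels)), function(i)
    extract_patch_pair(volume, voxels[i, ], spec))
}
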