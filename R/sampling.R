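# ---- exact Euclidean distance transform (separable lower-envelope) -------
# Squared-distance transform of a 1-D cost vector f: d[i] = min_j f[j] + (i-j)^2.
.dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  if (n > 1L) for (q in 2:n) {
    s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact 2-D Euclidean distance transform
#'
#' Distance (in voxel units) from every cell of a binary matrix to its
#' nearest `TRUE` cell, computed with the separable lower-envelope
#' algorithm (two 1-D passes of squared-distance parabolic envelopes).
#'
#' @param src Logical matrix of source cells (at least one `TRUE`).
#' @return Numeric matrix of Euclidean distances (0 at sources).
#' @export
distance_transform_2d <- function(src) {
  src <- as.matrix(src)
  if (!any(src)) stop("distance_transform_2d: no source cells")
  big <- 1e15
  f <- ifelse(src, 0, big)
  # pass over rows of each column, then over columns of each row
  g <- apply(f, 2L, .dt1d)
  d2 <- t(apply(g, 1L, .dt1d))
  sqrt(pmin(d2, big))
}

#' Expand a slice's nodule bounding box
#'
#' Tight bounding box of the nodule voxels on one slice, grown by
#' `margin` voxels on every side and clipped to the image plane. The
#' expanded box is the candidate region for weighted training-voxel
#' sampling.
#'
#' @param mask_slice Binary matrix (rows x cols) with >= 1 nodule voxel.
#' @param slice_index 0-based slice index recorded in the returned box.
#' @param margin Expansion in voxels per side (default 8).
#' @return A [bounding_box_2d].
#' @export
expand_box <- function(mask_slice, slice_index = 0L, margin = 8L) {
  mask_slice <- as.matrix(mask_slice)
  idx <- which(mask_slice != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("expand_box: slice contains no nodule voxels")
  margin <- as.integer(margin)
  box <- bounding_box_2d(slice_index,
                         max(min(idx[, 1]) - 1L - margin, 0L),
                         max(idx[, 1]) + margin,
                         max(min(idx[, 2]) - 1L - margin, 0L),
                         max(idx[, 2]) + margin)
  clip_box(box, dim(mask_slice))
}

#' Distance-based sampling weights for nodule voxels
#'
#' Each nodule voxel `i` inside the box receives
#' `PW_i = exp(-min_j d(i, j)) / Z` where `j` runs over the non-nodule
#' voxels of the box and `d` is the 2-D Euclidean distance in voxel units;
#' `Z` normalises the weights to sum 1. Edge voxels (close to background)
#' therefore carry the largest weights.
#'
#' @param mask_slice Binary matrix for the slice.
#' @param box The expanded [bounding_box_2d] (see [expand_box()]).
#' @return Matrix of the box's shape: weights at nodule voxels, 0 elsewhere.
#' @export
compute_nodule_weights <- function(mask_slice, box) {
  sub <- as.matrix(mask_slice)[.box_rows(box), .box_cols(box), drop = FALSE]
  if (!any(sub != 0) || all(sub != 0))
    stop("compute_nodule_weights: box must contain both classes")
  d <- distance_transform_2d(sub == 0)
  w <- matrix(0, nrow(sub), ncol(sub))
  nod <- sub != 0
  w[nod] <- exp(-d[nod])
  w / sum(w)
}

#' Intensity-modulated weights for background voxels
#'
#' Each non-nodule voxel `i` inside the box receives
#' `NW_i = I_i * exp(-min_j d(i, j)) / Z` with `j` over the nodule voxels.
#' `I_i` is the CT intensity min-max normalised to [0, 1] over the box,
#' which suppresses the dark lung field so sampling favours bright,
#' nodule-adjacent structures (wall, vessels). A constant-intensity box
#' sets all `I_i = 1` (weights become purely distance-based).
#'
#' @param mask_slice Binary matrix for the slice.
#' @param intensity_slice Numeric matrix of CT intensities, same shape.
#' @param box The expanded [bounding_box_2d].
#' @return Matrix of the box's shape: weights at background voxels, 0
#'   elsewhere.
#' @export
compute_background_weights <- function(mask_slice, intensity_slice, box) {
  rows <- .box_rows(box); cols <- .box_cols(box)
  sub <- as.matrix(mask_slice)[rows, cols, drop = FALSE]
  if (!any(sub != 0) || all(sub != 0))
    stop("compute_background_weights: box must contain both classes")
  ints <- as.matrix(intensity_slice)[rows, cols, drop = FALSE]
  rng <- range(ints)
  I <- if (rng[2] > rng[1]) (ints - rng[1]) / (rng[2] - rng[1])
       else matrix(1, nrow(sub), ncol(sub))
  d <- distance_transform_2d(sub != 0)
  w <- matrix(0, nrow(sub), ncol(sub))
  bg <- sub == 0
  w[bg] <- I[bg] * exp(-d[bg])
  s <- sum(w)
  if (s <= 0) stop("compute_background_weights: all background weights are zero")
  w / s
}

#' Per-slice weight map for training-voxel sampling
#'
#' @param mask_slice,intensity_slice Binary / intensity matrices of a slice.
#' @param slice_index 0-based slice index.
#' @param volume_id Identifier carried into sampled coordinates.
#' @param margin Box expansion per side.
#' @return Object of class `weight_map`: `slice_index`, `expanded_box`,
#'   `pw`, `nw` (box-shaped weight matrices, each summing to 1) and
#'   `volume_id`.
#' @export
weight_map <- function(mask_slice, intensity_slice, slice_index = 0L,
                       volume_id = "volume", margin = 8L) {
  box <- expand_box(mask_slice, slice_index, margin)
  structure(list(slice_index = as.integer(slice_index), expanded_box = box,
                 pw = compute_nodule_weights(mask_slice, box),
                 nw = compute_background_weights(mask_slice, intensity_slice, box),
                 volume_id = volume_id),
            class = "weight_map")
}

#' Weight maps for every nodule-bearing slice of a volume
#'
#' @param volume A [ct_volume].
#' @param mask The paired [nodule_mask].
#' @param margin Box expansion per side.
#' @return List of [weight_map]s, one per slice with nodule voxels.
#' @export
build_weight_maps <- function(volume, mask, margin = 8L) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "nodule_mask"))
  slices <- which(apply(mask$labels, 1L, sum) > 0L)
  lapply(slices, function(s)
    weight_map(mask$labels[s, , ], volume$voxels[s, , ],
               slice_index = s - 1L, volume_id = volume$volume_id,
               margin = margin))
}

# round half away from zero (positive arguments)
.round_half_up <- function(x) floor(x + 0.5)

#' Sample balanced training voxels from weight maps
#'
#' Per slice, `round(fraction x nodule count)` nodule voxels are drawn
#' without replacement with probability proportional to `pw`, and the same
#' number of background voxels proportional to `nw`, giving exactly
#' balanced class labels. Draws are reproducible given `seed`.
#'
#' @param maps List of [weight_map]s.
#' @param fraction Fraction of each slice's nodule voxels to draw
#'   (default 0.40).
#' @param seed Integer seed.
#' @return Object of class `sample_set`: a data.frame with columns
#'   `volume_id`, `slice`, `row`, `col` (0-based) and `label` (1 nodule /
#'   0 background); attribute `warnings` records any clamped draws.
#' @export
sample_training_voxels <- function(maps, fraction = 0.40, seed = 1L) {
  if (inherits(maps, "weight_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L, fraction > 0, fraction <= 1)
  warns <- character(0)
  out <- .with_seed(seed, lapply(maps, function(m) {
    box <- m$expanded_box
    pidx <- which(m$pw > 0)
    nidx <- which(m$nw > 0)
    n_draw <- .round_half_up(fraction * length(pidx))
    if (n_draw < 1L) n_draw <- 1L
    if (n_draw > length(pidx)) n_draw <- length(pidx)
    n_bg <- n_draw
    if (n_bg > length(nidx)) {
      warns <<- c(warns, sprintf("%s slice %d: background clamped to %d",
                                 m$volume_id, m$slice_index, length(nidx)))
      n_bg <- length(nidx)
      n_draw <- n_bg  # keep labels balanced
    }
    ps <- pidx[sample.int(length(pidx), n_draw, prob = m$pw[pidx])]
    ns <- nidx[sample.int(length(nidx), n_bg, prob = m$nw[nidx])]
    nr <- nrow(m$pw)
    to_coord <- function(ii) cbind(row = box$row_start + (ii - 1L) %% nr,
                                   col = box$col_start + (ii - 1L) %/% nr)
    pc <- to_coord(ps); nc <- to_coord(ns)
    data.frame(volume_id = m$volume_id, slice = m$slice_index,
               row = c(pc[, 1], nc[, 1]), col = c(pc[, 2], nc[, 2]),
               label = rep(c(1L, 0L), c(n_draw, n_bg)))
  }))
  ss <- do.call(rbind, out)
  rownames(ss) <- NULL
  structure(ss, class = c("sample_set", "data.frame"),
            warnings = warns, seed = as.integer(seed))
}
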