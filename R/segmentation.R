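# 8- (or 4-) connected component labelling of a binary matrix; two-pass
# queue flood fill, deterministic label order (first foreground cell in
# column-major order gets label 1).
.label_components <- function(m, connectivity = 8L) {
  m <- as.matrix(m) != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  for (start in which(m)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (v - 1L) %% nr + 1L
      cc <- (v - 1L) %/% nr + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- cc + dc[k]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          w <- (c2 - 1L) * nr + r2
          if (m[w] && lab[w] == 0L) {
            lab[w] <- cur
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  lab
}

#' Classify every voxel of a bounding box on one slice
#'
#' Extracts the patch pair of each voxel inside the box, scores it with the
#' classifier and thresholds the probabilities (`p >= threshold` is
#' nodule). Voxels outside the box are 0.
#'
#' @param model Classifier accepted by [predict_batch()].
#' @param volume A [ct_volume].
#' @param box A [bounding_box_2d] (its `slice_index` selects the slice).
#' @param threshold Probability threshold, default 0.5 (inclusive).
#' @param spec A [patch_spec].
#' @return Binary matrix of the full slice plane.
#' @export
classify_slice <- function(model, volume, box, threshold = 0.5,
                           spec = patch_spec()) {
  d <- dim(volume$voxels)
  if (box$slice_index < 0L || box$slice_index >= d[1])
    stop("classify_slice: slice ", box$slice_index, " outside volume")
  box <- clip_box(box, d)
  rows <- box$row_start:(box$row_stop - 1L)
  cols <- box$col_start:(box$col_stop - 1L)
  vox <- cbind(box$slice_index,
               rep(rows, times = length(cols)),
               rep(cols, each = length(rows)))
  patches <- batch_patches(volume, vox, spec)
  p <- predict_batch(model, patches)
  out <- matrix(0L, d[2], d[3])
  out[cbind(vox[, 2] + 1L, vox[, 3] + 1L)] <- as.integer(p >= threshold)
  out
}

#' Keep the single connected component relevant to the nodule
#'
#' Components are labelled with in-plane 8-connectivity. On the starting
#' slice the component whose centroid is nearest the bounding-box centre is
#' kept; on propagated slices, the one nearest the preceding slice's kept
#' centroid. Ties go to the larger component, then to the lower first
#' linear index. An empty mask is returned unchanged (it feeds the
#' propagation stop rule).
#'
#' @param candidate Binary slice matrix.
#' @param context `"starting"` or `"propagated"` (documentation of intent;
#'   both use `reference`).
#' @param reference Numeric (row, col), 0-based, continuous: box centre or
#'   preceding centroid.
#' @param connectivity 8 (default) or 4.
#' @return List: `mask` (single-component binary matrix), `centroid`
#'   (0-based numeric (row, col) or `NULL`), `area` (voxel count).
#' @export
select_component <- function(candidate, context = c("starting", "propagated"),
                             reference, connectivity = 8L) {
  context <- match.arg(context)
  m <- as.matrix(candidate)
  if (!any(m != 0))
    return(list(mask = m * 0L, centroid = NULL, area = 0L))
  lab <- .label_components(m, connectivity)
  ks <- seq_len(max(lab))
  stats <- lapply(ks, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    list(centroid = c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1),
         area = nrow(idx), first = min(which(lab == k)))
  })
  dists <- vapply(stats, function(s)
    sqrt(sum((s$centroid - as.numeric(reference))^2)), numeric(1))
  areas <- vapply(stats, `[[`, numeric(1), "area")
  firsts <- vapply(stats, `[[`, numeric(1), "first")
  best <- order(dists, -areas, firsts)[1]
  keep <- lab == ks[best]
  list(mask = matrix(as.integer(keep), nrow(m), ncol(m)),
       centroid = stats[[best]]$centroid,
       area = stats[[best]]$area)
}

.box_center <- function(box) {
  c((box$row_start + box$row_stop - 1) / 2,
    (box$col_start + box$col_stop - 1) / 2)
}

#' Segment a nodule in 3-D by bidirectional slice propagation
#'
#' The starting slice is classified inside the user box and reduced to one
#' connected component. The same box is then applied to preceding and
#' subsequent slices independently; propagation in a direction stops when
#' the selected component is empty (`empty_slice`), when its area falls
#' below 30% of the preceding kept slice's area (`area_ratio`; the
#' violating slice is excluded, strict `<`), or at the volume boundary
#' (`volume_end`). The starting slice itself is exempt from the area rule.
#'
#' @param model Classifier accepted by [predict_batch()].
#' @param volume A [ct_volume].
#' @param start_box A [bounding_box_2d] on the starting slice.
#' @param threshold Probability threshold.
#' @param spec A [patch_spec].
#' @param connectivity In-plane component connectivity.
#' @return Object of class `segmentation_result`: `mask` ([nodule_mask]),
#'   `per_slice_area` (named integer vector, names are 0-based slice
#'   indices), `stop_reason_up` / `stop_reason_down` and `start_box`.
#' @export
propagate <- function(model, volume, start_box, threshold = 0.5,
                      spec = patch_spec(), connectivity = 8L) {
  d <- dim(volume$voxels)
  box <- clip_box(start_box, d)
  cand <- classify_slice(model, volume, box, threshold, spec)
  sel <- select_component(cand, "starting", .box_center(box), connectivity)
  if (sel$area == 0L) {
    vox <- sum(cand)
    stop("propagate: no nodule voxel detected on the starting slice (",
         vox, " raw positives before component selection)")
  }
  out <- array(0L, d)
  out[box$slice_index + 1L, , ] <- sel$mask
  areas <- stats::setNames(sel$area, box$slice_index)

  run_dir <- function(step) {
    prev_area <- sel$area
    prev_centroid <- sel$centroid
    s <- box$slice_index + step
    while (s >= 0L && s < d[1]) {
      b <- bounding_box_2d(s, box$row_start, box$row_stop,
                           box$col_start, box$col_stop)
      cnd <- classify_slice(model, volume, b, threshold, spec)
      sl <- select_component(cnd, "propagated", prev_centroid, connectivity)
      if (sl$area == 0L) return(list(reason = "empty_slice"))
      if (sl$area < 0.30 * prev_area) return(list(reason = "area_ratio"))
      out[s + 1L, , ] <<- sl$mask
      areas[as.character(s)] <<- sl$area
      prev_area <- sl$area
      prev_centroid <- sl$centroid
      s <- s + step
    }
    list(reason = "volume_end")
  }
  down <- run_dir(-1L)
  up <- run_dir(+1L)
  areas <- areas[order(as.integer(names(areas)))]
  structure(list(mask = nodule_mask(out),
                 per_slice_area = areas,
                 stop_reason_up = up$reason,
                 stop_reason_down = down$reason,
                 start_box = box),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d voxels on %d slices (stop: down=%s, up=%s)\n",
              sum(x$mask$labels), length(x$per_slice_area),
              x$stop_reason_down, x$stop_reason_up))
  invisible(x)
}

#' Full segmentation pipeline for one nodule
#'
#' Thin wrapper around [propagate()]: classify inside the box, select the
#' relevant component, propagate in both directions, and return the 3-D
#' mask in volume coordinates.
#'
#' @inheritParams propagate
#' @return A `segmentation_result` (see [propagate()]).
#' @export
segment <- function(model, volume, start_box, threshold = 0.5,
                    spec = patch_spec(), connectivity = 8L) {
  propagate(model, volume, start_box, threshold, spec, connectivity)
}

#' Ground-truth oracle classifier
#'
#' A plug-in classifier whose predicted probability is the ground-truth
#' label of the target voxel (1 inside the mask, 0 outside). Used to test
#' the segmentation pipeline independently of network quality.
#'
#' @param mask A [nodule_mask].
#' @return Object of class `oracle_classifier` usable with
#'   [predict_batch()], [classify_slice()] and [segment()].
#' @export
oracle_classifier <- function(mask) {
  stopifnot(inherits(mask, "nodule_mask"))
  structure(list(mask = mask), class = "oracle_classifier")
}

#' @rdname predict_batch
#' @export
predict_batch.oracle_classifier <- function(model, patches, ...) {
  vapply(patches, function(p) {
    v <- p$target + 1L
    as.numeric(model$mask$labels[v[1], v[2], v[3]])
  }, numeric(1))
}

#' Constant-probability classifier
#'
#' Assigns the same probability to every voxel; useful for exercising
#' threshold and error paths.
#'
#' @param p Probability in [0, 1].
#' @return Object of class `constant_classifier`.
#' @export
constant_classifier <- function(p) {
  stopifnot(p >= 0, p <= 1)
  structure(list(p = p), class = "constant_classifier")
}

#' @rdname predict_batch
#' @export
predict_batch.constant_classifier <- function(model, patches, ...) {
  rep(model$p, length(patches))
}
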