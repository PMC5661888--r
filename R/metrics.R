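# Accept nodule_mask objects or raw binary arrays.
.mask_arr <- function(x) {
  a <- if (inherits(x, "nodule_mask")) x$labels else as.array(x)
  if (!all(a %in% c(0, 1))) stop("mask values must be binary {0,1}")
  a
}

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks have different shapes: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |Gt intersect Auto| / (|Gt| + |Auto|)`, volumes counted in
#' voxels.
#'
#' @param gt,auto Binary masks ([nodule_mask] or arrays) of equal shape; at
#'   least one must be nonempty.
#' @return Fraction in [0, 1].
#' @export
dice <- function(gt, auto) {
  g <- .mask_arr(gt); a <- .mask_arr(auto)
  .check_same_shape(g, a)
  vg <- sum(g); va <- sum(a)
  if (vg + va == 0) stop("dice: both masks are empty, metric undefined")
  2 * sum(g * a) / (vg + va)
}

#' Jaccard overlap
#'
#' `O = |Gt intersect Auto| / |Gt union Auto|`.
#'
#' @inheritParams dice
#' @return Fraction in [0, 1].
#' @export
jaccard_overlap <- function(gt, auto) {
  g <- .mask_arr(gt); a <- .mask_arr(auto)
  .check_same_shape(g, a)
  inter <- sum(g * a)
  uni <- sum(g) + sum(a) - inter
  if (uni == 0) stop("jaccard_overlap: both masks are empty, metric undefined")
  inter / uni
}

#' Sensitivity and positive predictive value
#'
#' `SEN = |Gt intersect Auto| / |Gt|`, `PPV = |Gt intersect Auto| / |Auto|`.
#'
#' @inheritParams dice
#' @return Named numeric vector `c(sen = ..., ppv = ...)`.
#' @export
sensitivity_ppv <- function(gt, auto) {
  g <- .mask_arr(gt); a <- .mask_arr(auto)
  .check_same_shape(g, a)
  if (sum(g) == 0) stop("sensitivity_ppv: empty ground truth, SEN undefined")
  if (sum(a) == 0) stop("sensitivity_ppv: empty automatic mask, PPV undefined")
  inter <- sum(g * a)
  c(sen = inter / sum(g), ppv = inter / sum(a))
}

# Surface voxels: mask voxels with at least one background 6-neighbour
# (voxels on the array border count as surface).
.surface_voxels <- function(m) {
  d <- dim(m)
  p <- array(0L, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nmin <- pmin(p[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)],
               p[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)],
               p[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)],
               p[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)],
               p[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]],
               p[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)])
  which(core == 1L & nmin == 0L, arr.ind = TRUE)
}

# mean over rows of the minimum cross-distance to pts2 (mm coordinates)
.mean_min_dist <- function(pts1, pts2) {
  t2 <- t(pts2)
  mins <- vapply(seq_len(nrow(pts1)), function(i) {
    sqrt(min(colSums((t2 - pts1[i, ])^2)))
  }, numeric(1))
  mean(mins)
}

#' Symmetric average surface distance (mm)
#'
#' Surfaces are the mask voxels with a background 6-neighbour; distances
#' are between voxel centres, scaled anisotropically by the spacing. The
#' result is the mean of the two directed mean minimum surface distances.
#'
#' @param gt,auto Nonempty binary masks of equal shape.
#' @param spacing Numeric length-3, mm per axis (slice, row, col).
#' @return ASD in millimetres (0 for identical masks).
#' @export
asd <- function(gt, auto, spacing = c(1, 1, 1)) {
  g <- .mask_arr(gt); a <- .mask_arr(auto)
  .check_same_shape(g, a)
  if (sum(g) == 0 || sum(a) == 0)
    stop("asd: both masks must be nonempty")
  spacing <- as.numeric(spacing)
  sg <- sweep(.surface_voxels(g), 2L, spacing, `*`)
  sa <- sweep(.surface_voxels(a), 2L, spacing, `*`)
  (.mean_min_dist(sg, sa) + .mean_min_dist(sa, sg)) / 2
}

#' Fuse rater masks with the 50% consensus criterion
#'
#' A voxel enters the consensus ground truth when at least half of the
#' raters marked it (a voxel marked by exactly 50% is included).
#'
#' @param rater_masks List of >= 1 binary masks of equal shape.
#' @return A [nodule_mask].
#' @export
consensus_mask <- function(rater_masks) {
  stopifnot(length(rater_masks) >= 1L)
  arrs <- lapply(rater_masks, .mask_arr)
  for (a in arrs) .check_same_shape(arrs[[1]], a)
  total <- Reduce(`+`, arrs)
  nodule_mask(total * 2L >= length(arrs))
}

#' Per-case and aggregate segmentation metrics
#'
#' Computes DSC, Jaccard overlap, SEN, PPV and ASD per case plus a
#' mean +/- sd summary (sample sd, n - 1 denominator).
#'
#' @param results List of automatic masks ([nodule_mask] /
#'   `segmentation_result` objects).
#' @param gts List of ground-truth masks, same length.
#' @param spacings List of spacing triples (or a single triple reused for
#'   all cases).
#' @param ids Optional case identifiers.
#' @return List with `per_case` (data.frame, one row per case) and
#'   `summary` (data.frame with `mean` and `sd` per metric).
#' @export
evaluate_cohort <- function(results, gts, spacings = list(c(1, 1, 1)), ids = NULL) {
  if (length(results) == 0L) stop("evaluate_cohort: empty result list")
  if (length(results) != length(gts))
    stop("evaluate_cohort: results and ground truths differ in length")
  if (!is.list(spacings) || is.numeric(spacings)) spacings <- list(spacings)
  if (length(spacings) == 1L) spacings <- rep(spacings, length(results))
  if (is.null(ids)) ids <- sprintf("case_%03d", seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    auto <- results[[i]]
    if (inherits(auto, "segmentation_result")) auto <- auto$mask
    sp <- sensitivity_ppv(gts[[i]], auto)
    data.frame(id = ids[i],
               dsc = dice(gts[[i]], auto),
               jaccard = jaccard_overlap(gts[[i]], auto),
               sen = sp[["sen"]], ppv = sp[["ppv"]],
               asd_mm = asd(gts[[i]], auto, spacings[[i]]))
  })
  per_case <- do.call(rbind, rows)
  rownames(per_case) <- NULL
  metrics <- c("dsc", "jaccard", "sen", "ppv", "asd_mm")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_case[[m]]), numeric(1)),
    sd = vapply(metrics, function(m)
      if (nrow(per_case) > 1L) stats::sd(per_case[[m]]) else NA_real_,
      numeric(1)))
  rownames(summary) <- NULL
  list(per_case = per_case, summary = summary)
}
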