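#' CT volume container
#'
#' Bundles a 3-D intensity array with its physical voxel spacing. The package
#' uses a single axis convention everywhere: arrays are indexed
#' `(slice, row, col)`, 0-based half-open intervals for all boxes, and the
#' axial plane is `(row, col)`.
#'
#' @param voxels 3-D numeric array indexed (slice, row, col), HU-like units.
#' @param spacing Numeric length-3, mm per axis (slice, row, col); all > 0.
#' @param volume_id Character identifier.
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `volume_id`.
#' @examples
#' v <- ct_volume(array(0, c(4, 8, 8)), spacing = c(2, 0.7, 0.7))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), volume_id = "volume") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("ct_volume: voxel data must be 3-D, got ", length(dim(voxels)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: spacing must be 3 positive reals (mm)")
  if (dim(voxels)[1] < 1L) stop("ct_volume: volume needs at least one slice")
  structure(list(voxels = voxels, spacing = spacing,
                 volume_id = as.character(volume_id)[1]),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume '%s'> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$volume_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Binary nodule mask aligned to a CT volume
#'
#' @param labels 3-D array of 0/1 values, same shape as its volume.
#' @param rater_id Optional character tag for the annotating rater.
#' @return An object of class `nodule_mask` with fields `labels` (integer
#'   0/1 array) and `rater_id`.
#' @export
nodule_mask <- function(labels, rater_id = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("nodule_mask: labels must be 3-D")
  u <- unique(as.vector(labels))
  if (!all(u %in% c(0, 1)))
    stop("nodule_mask: labels must be binary {0,1}")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels,
                 rater_id = if (is.null(rater_id)) NULL else as.character(rater_id)[1]),
            class = "nodule_mask")
}

#' @export
print.nodule_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<nodule_mask%s> %d x %d x %d, %d foreground voxels\n",
              if (is.null(x$rater_id)) "" else paste0(" rater=", x$rater_id),
              d[1], d[2], d[3], sum(x$labels)))
  invisible(x)
}

#' 2-D bounding box on one axial slice
#'
#' Coordinates are 0-based and half-open: the box covers rows
#' `row_start .. row_stop - 1` and likewise for columns.
#'
#' @param slice_index 0-based slice index.
#' @param row_start,row_stop,col_start,col_stop Integers, half-open extents.
#' @return An object of class `bounding_box_2d`.
#' @export
bounding_box_2d <- function(slice_index, row_start, row_stop, col_start, col_stop) {
  v <- vapply(list(slice_index, row_start, row_stop, col_start, col_stop),
              function(x) as.integer(x)[1], integer(1))
  if (anyNA(v)) stop("bounding_box_2d: all coordinates must be integers")
  if (v[2] >= v[3] || v[4] >= v[5])
    stop("bounding_box_2d: start must be < stop on both axes")
  if (v[2] < 0L || v[4] < 0L || v[1] < 0L)
    stop("bounding_box_2d: coordinates are 0-based and must be non-negative")
  structure(list(slice_index = v[1], row_start = v[2], row_stop = v[3],
                 col_start = v[4], col_stop = v[5]),
            class = "bounding_box_2d")
}

#' @export
print.bounding_box_2d <- function(x, ...) {
  cat(sprintf("<bounding_box_2d> slice %d, rows [%d, %d), cols [%d, %d)\n",
              x$slice_index, x$row_start, x$row_stop, x$col_start, x$col_stop))
  invisible(x)
}

#' Read a CT volume or mask from NIfTI
#'
#' The first array axis of the stored image is taken as the slice axis, so
#' in-memory data follows the package's (slice, row, col) convention.
#'
#' @param path Path to a 3-D `.nii` / `.nii.gz` file.
#' @param volume_id Identifier for the returned volume; defaults to the
#'   file name without extension.
#' @return A [ct_volume].
#' @export
read_volume <- function(path, volume_id = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("read_volume: expected 3-D data, got ", length(dim(arr)),
         "-D in ", path)
  sp <- as.numeric(RNifti::pixdim(img))[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("read_volume: non-positive voxel spacing in ", path)
  if (is.null(volume_id))
    volume_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  ct_volume(arr, spacing = sp, volume_id = volume_id)
}

#' Write a CT volume to NIfTI
#'
#' @param volume A [ct_volume].
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @param datatype NIfTI storage type; `"double"` for intensities,
#'   `"uint8"` is appropriate for masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  stopifnot(inherits(volume, "ct_volume"))
  if (!dir.exists(dirname(path)))
    stop("write_volume: directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a nodule mask to NIfTI (8-bit)
#'
#' @param mask A [nodule_mask].
#' @param volume The paired [ct_volume] supplying spacing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, volume, path) {
  stopifnot(inherits(mask, "nodule_mask"), inherits(volume, "ct_volume"))
  write_volume(ct_volume(mask$labels, volume$spacing, volume$volume_id),
               path, datatype = "uint8")
}

#' Read a nodule mask from NIfTI
#'
#' @param path Path to a binary NIfTI file.
#' @param rater_id Optional rater tag.
#' @return A [nodule_mask].
#' @export
read_mask <- function(path, rater_id = NULL) {
  v <- read_volume(path)
  nodule_mask(v$voxels != 0, rater_id = rater_id)
}

#' Clip a bounding box to an image plane
#'
#' @param box A [bounding_box_2d].
#' @param shape Volume shape, length-3 integer (slice, row, col) or length-2
#'   (row, col) plane shape.
#' @return The clipped [bounding_box_2d]. A box with no overlap is an error.
#' @export
clip_box <- function(box, shape) {
  stopifnot(inherits(box, "bounding_box_2d"))
  shape <- as.integer(shape)
  if (length(shape) == 3L) {
    if (box$slice_index >= shape[1])
      stop("clip_box: slice index ", box$slice_index, " outside volume")
    plane <- shape[2:3]
  } else if (length(shape) == 2L) {
    plane <- shape
  } else stop("clip_box: shape must have length 2 or 3")
  rs <- max(box$row_start, 0L); re <- min(box$row_stop, plane[1])
  cs <- max(box$col_start, 0L); ce <- min(box$col_stop, plane[2])
  if (rs >= re || cs >= ce)
    stop("clip_box: box does not overlap the image plane")
  bounding_box_2d(box$slice_index, rs, re, cs, ce)
}

#' Serialize a bounding box to a JSON sidecar
#'
#' Layout: `{"slice": i, "row": [start, stop], "col": [start, stop]}`,
#' all 0-based half-open.
#'
#' @param box A [bounding_box_2d].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_bbox <- function(box, path) {
  stopifnot(inherits(box, "bounding_box_2d"))
  jsonlite::write_json(
    list(slice = box$slice_index,
         row = c(box$row_start, box$row_stop),
         col = c(box$col_start, box$col_stop)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a bounding box from its JSON sidecar
#'
#' @param path Path written by [write_bbox()].
#' @return A [bounding_box_2d].
#' @export
read_bbox <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  bounding_box_2d(j$slice, j$row[1], j$row[2], j$col[1], j$col[2])
}

# Internal: 1-based R index ranges for a box.
.box_rows <- function(box) (box$row_start + 1L):box$row_stop
.box_cols <- function(box) (box$col_start + 1L):box$col_stop
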