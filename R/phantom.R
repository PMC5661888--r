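# Run expr with a private, restored RNG state seeded deterministically.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Synthetic nodule phantom configuration
#'
#' Describes one CT-like phantom: an ellipsoidal (spherical in voxel units)
#' nodule embedded in a dark lung field, with variants mirroring the
#' clinically distinct nodule classes: `isolated` (solid sphere),
#' `juxtapleural` (touching a bright pleural wall slab), `cavitary`
#' (internal air cavity, which stays inside the ground-truth mask),
#' `calcific` (bright calcified core) and `ggo` (ground-glass opacity:
#' reduced nodule/lung contrast). Intensities are HU-like.
#'
#' @param nodule_kind One of `"isolated"`, `"juxtapleural"`, `"cavitary"`,
#'   `"calcific"`, `"ggo"`.
#' @param radius_vox Nodule radius in voxels (applied on all axes).
#' @param center 0-based (slice, row, col) centre; default volume centre.
#' @param lung_level,nodule_level,wall_level,calcific_level Mean intensities
#'   of lung field, solid nodule, pleural wall and calcification.
#' @param contrast_scale Fraction in (0, 1] scaling the nodule/lung contrast
#'   for `ggo` phantoms.
#' @param cavity_radius_frac Cavity radius as a fraction of `radius_vox`.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param vessel Add a vessel cylinder touching the nodule.
#' @param shape Volume shape (slice, row, col).
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed; phantoms are deterministic given the config.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(nodule_kind = c("isolated", "juxtapleural", "cavitary",
                                           "calcific", "ggo"),
                           radius_vox = 6, center = NULL,
                           lung_level = -800, nodule_level = 60,
                           wall_level = 250, calcific_level = 500,
                           contrast_scale = 0.25, cavity_radius_frac = 0.45,
                           noise_sd = 30, vessel = FALSE,
                           shape = c(24L, 48L, 48L),
                           spacing = c(2.0, 0.7, 0.7), seed = 1L) {
  nodule_kind <- match.arg(nodule_kind)
  shape <- as.integer(shape)
  if (is.null(center)) center <- shape %/% 2L
  center <- as.integer(center)
  stopifnot(length(shape) == 3L, length(center) == 3L, radius_vox > 0,
            noise_sd >= 0, contrast_scale > 0, contrast_scale <= 1,
            cavity_radius_frac > 0, cavity_radius_frac < 1)
  structure(list(nodule_kind = nodule_kind, radius_vox = radius_vox,
                 center = center, lung_level = lung_level,
                 nodule_level = nodule_level, wall_level = wall_level,
                 calcific_level = calcific_level,
                 contrast_scale = contrast_scale,
                 cavity_radius_frac = cavity_radius_frac,
                 noise_sd = noise_sd, vessel = isTRUE(vessel),
                 shape = shape, spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Squared voxel distance of every voxel to a 0-based centre point.
.dist2_grid <- function(shape, center) {
  ds <- (seq_len(shape[1]) - 1L - center[1])^2
  dr <- (seq_len(shape[2]) - 1L - center[2])^2
  dc <- (seq_len(shape[3]) - 1L - center[3])^2
  outer(outer(ds, dr, `+`), dc, `+`)
}

#' Generate one synthetic nodule phantom
#'
#' Deterministic given the config (including its seed). The ground-truth
#' mask is the full nodule sphere; for cavitary phantoms the internal cavity
#' voxels remain part of the mask, matching the convention that a cavity
#' belongs to the nodule.
#'
#' @param config A [phantom_config].
#' @return Object of class `phantom_sample`: fields `volume` ([ct_volume]),
#'   `mask` ([nodule_mask]), `start_box` ([bounding_box_2d] on the central
#'   nodule slice) and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  shape <- config$shape; ctr <- config$center; r <- config$radius_vox
  if (any(ctr - ceiling(r) < 0L) || any(ctr + ceiling(r) > shape - 1L))
    stop("generate_phantom: nodule (centre ", paste(ctr, collapse = ","),
         ", radius ", r, ") does not fit inside the volume")
  d2 <- .dist2_grid(shape, ctr)
  sphere <- d2 <= r^2
  vol <- array(config$lung_level, shape)

  nod_level <- if (config$nodule_kind == "ggo")
    config$lung_level + (config$nodule_level - config$lung_level) * config$contrast_scale
  else config$nodule_level
  vol[sphere] <- nod_level

  if (config$nodule_kind == "calcific") {
    core <- d2 <= (0.5 * r)^2
    vol[core] <- config$calcific_level
  }
  if (config$nodule_kind == "cavitary") {
    cavity <- d2 <= (config$cavity_radius_frac * r)^2
    vol[cavity] <- config$lung_level          # air-like cavity, mask keeps it
  }
  if (config$nodule_kind == "juxtapleural") {
    wall_from <- ctr[3] + 1L + floor(r) + 1L  # first 1-based column after the sphere
    if (wall_from > shape[3])
      stop("generate_phantom: no room for the pleural wall slab")
    vol[, , wall_from:shape[3]] <- config$wall_level
  }
  if (config$vessel) {
    # cylinder along the row axis, tangent to the nodule at its central slice
    vr <- max(1, r / 4)
    off <- (seq_len(shape[1]) - 1L - ctr[1])^2
    cc2 <- (seq_len(shape[3]) - 1L - (ctr[3] - ceiling(r) - floor(vr)))^2
    cyl <- outer(outer(off, rep(0, shape[2]), `+`), cc2, `+`) <= vr^2
    vol[cyl & !sphere] <- config$nodule_level
  }
  if (config$noise_sd > 0)
    vol <- vol + .with_seed(config$seed,
                            array(stats::rnorm(prod(shape), 0, config$noise_sd), shape))

  mask <- nodule_mask(sphere)
  volume <- ct_volume(vol, spacing = config$spacing,
                      volume_id = sprintf("phantom_%s_seed%d",
                                          config$nodule_kind, config$seed))
  structure(list(volume = volume, mask = mask,
                 start_box = .phantom_start_box(mask, ctr, shape),
                 config = config),
            class = "phantom_sample")
}

# Tight bbox of the mask on its central slice, grown by a 3-voxel margin.
.phantom_start_box <- function(mask, ctr, shape, margin = 3L) {
  sl <- ctr[1] + 1L
  m <- mask$labels[sl, , ]
  idx <- which(m == 1L, arr.ind = TRUE)
  stopifnot(nrow(idx) > 0L)
  clip_box(bounding_box_2d(sl - 1L,
                           min(idx[, 1]) - 1L - margin, max(idx[, 1]) + margin,
                           min(idx[, 2]) - 1L - margin, max(idx[, 2]) + margin),
           shape)
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> kind=%s radius=%.1f vox, %d mask voxels\n",
              x$config$nodule_kind, x$config$radius_vox, sum(x$mask$labels)))
  invisible(x)
}

#' Generate a cohort of phantoms
#'
#' Kinds are drawn from `kind_mix`, radii jittered uniformly in
#' [0.85, 1.2] x the base radius and centres jittered by up to 2 voxels
#' in-plane (1 slice axially), all from a single stream seeded by `seed`;
#' phantom `i` then uses noise seed `seed + i`.
#'
#' @param n Number of phantoms (>= 1).
#' @param kind_mix Named numeric vector of kind proportions (sums to 1),
#'   e.g. `c(isolated = 0.5, juxtapleural = 0.5)`.
#' @param base_config Template [phantom_config].
#' @param seed Integer seed for the cohort stream.
#' @return List of `phantom_sample` objects with `volume_id`s
#'   `phantom_001, ...`.
#' @export
generate_cohort <- function(n, kind_mix = c(isolated = 1),
                            base_config = phantom_config(), seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("generate_cohort: n must be >= 1")
  if (length(kind_mix) == 0L || is.null(names(kind_mix)))
    stop("generate_cohort: kind_mix must be a named proportion vector")
  if (abs(sum(kind_mix) - 1) > 1e-8)
    stop("generate_cohort: kind_mix proportions must sum to 1")
  draws <- .with_seed(seed, {
    kinds <- sample(names(kind_mix), n, replace = TRUE, prob = kind_mix)
    rad <- base_config$radius_vox * stats::runif(n, 0.85, 1.2)
    js <- sample(-1:1, n, replace = TRUE)
    jr <- sample(-2:2, n, replace = TRUE)
    jc <- sample(-2:2, n, replace = TRUE)
    list(kinds = kinds, rad = rad, js = js, jr = jr, jc = jc)
  })
  lapply(seq_len(n), function(i) {
    cfg <- base_config
    cfg$nodule_kind <- draws$kinds[i]
    cfg$radius_vox <- draws$rad[i]
    cfg$center <- base_config$center + c(draws$js[i], draws$jr[i], draws$jc[i])
    cfg$seed <- as.integer(seed + i)
    # keep the jittered nodule inside the volume
    rc <- ceiling(cfg$radius_vox)
    cfg$center <- pmin(pmax(cfg$center, rc), cfg$shape - 1L - rc)
    s <- generate_phantom(cfg)
    s$volume$volume_id <- sprintf("phantom_%03d", i)
    s
  })
}
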