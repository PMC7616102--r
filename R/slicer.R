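## Plane slicing and supervised dataset generation.
##
## A plane pose places a square sampling grid inside the normalized [-1, 1]
## brain frame: pixel (row j, col i) maps to t + u_i * R[,1] + v_j * R[,2],
## with u (image x) along columns, v (image y) along rows, both spanning
## [-extent, extent] at half-pixel centers, and R[,3] the plane normal.
## Intensities are sampled from the voxel grid by trilinear interpolation.

#' Slice sampling geometry
#'
#' @param size_px output image side in pixels (>= 16; default 128, the input
#'   size of the pose-regression network).
#' @param extent_units half-width of the sampled square in normalized units
#'   (default 1: the plane spans the full normalized brain frame).
#' @param fill_value intensity (on the [0, 1] image scale) for sample points
#'   outside the volume grid.
#' @return an object of class `slice_spec`.
#' @export
slice_spec <- function(size_px = 128L, extent_units = 1, fill_value = 0) {
  stopifnot(size_px >= 16, extent_units > 0, fill_value >= 0, fill_value <= 1)
  structure(list(size_px = as.integer(size_px), extent_units = extent_units,
                 fill_value = fill_value),
            class = "slice_spec")
}

pose_row <- function(pose) {
  c(pose$translation, pose$rotation[, 1], pose$rotation[, 2])
}

#' Extract a 2D slice at an arbitrary plane pose
#'
#' @param vol a `us_volume`.
#' @param pose a [pose6d()] in the volume's normalized frame.
#' @param spec a [slice_spec()].
#' @return `size_px` x `size_px` numeric matrix in `[0, 1]` (rows = image y,
#'   columns = image x). A plane entirely outside the volume returns a
#'   constant `fill_value` image.
#' @export
extract_slice <- function(vol, pose, spec = slice_spec()) {
  img <- extract_slices(vol, list(pose), spec)
  img[, , 1]
}

#' @rdname extract_slice
#' @param poses list of poses (batch form).
#' @return [extract_slices()]: a `size_px` x `size_px` x `n` array.
#' @export
extract_slices <- function(vol, poses, spec = slice_spec()) {
  stopifnot(inherits(vol, "us_volume"), inherits(spec, "slice_spec"))
  pm <- do.call(rbind, lapply(poses, pose_row))
  raw <- extract_slices_cpp(as.numeric(vol$voxels), as.integer(dim(vol$voxels)),
                            vol$spacing, vol$origin, vol$center_mm,
                            vol$mm_per_unit, pm, spec$size_px,
                            spec$extent_units, spec$fill_value * 255)
  array(raw / 255, dim = c(spec$size_px, spec$size_px, length(poses)))
}

#' Fraction of a plane's sample grid inside the brain mask
#'
#' Used to reject candidate planes with poor overlap with the volume during
#' random-pose sampling.
#'
#' @inheritParams extract_slice
#' @param n_grid side of the sample grid used for the overlap estimate
#'   (defaults to the slice resolution; a coarser grid is a cheap estimate).
#' @return fraction in `[0, 1]`.
#' @export
in_volume_fraction <- function(vol, pose, spec = slice_spec(), n_grid = NULL) {
  if (is.null(n_grid)) n_grid <- spec$size_px
  slice_mask_fraction_cpp(as.numeric(vol$mask), as.integer(dim(vol$mask)),
                          vol$spacing, vol$origin, vol$center_mm,
                          vol$mm_per_unit, pose_row(pose),
                          spec$extent_units, as.integer(n_grid))
}

#' Dataset sampling configuration
#'
#' Defaults follow the acquisition protocol the package emulates: 20699
#' random-orientation planes per volume plus 1330 planes densely sampled
#' around the annotated standard plane (22029 images per volume in total).
#' Near-plane sampling uses per-axis translation offsets within 0.001
#' normalized units and rotations up to 1.9 degrees; the coarse steps (0.1
#' units, 7.9 degrees) that the random acquisition grid used are kept for
#' reference in `random_trans_step` / `random_rot_step` but random poses are
#' drawn continuously (uniform translations, uniform SO(3) rotations) with a
#' minimum-overlap rejection rule standing in for the unquantified "fixed
#' range" of the acquisition.
#'
#' @param n_random random-orientation plane count.
#' @param n_near_sp near-standard-plane count.
#' @param trans_range max |t| per axis, normalized units.
#' @param near_trans_step per-axis translation bound for near-plane sampling
#'   (normalized units).
#' @param near_rot_step rotation-angle bound for near-plane sampling, degrees.
#' @param random_trans_step,random_rot_step legacy coarse acquisition steps
#'   (reference values; not applied when sampling continuously).
#' @param min_overlap minimum in-mask fraction for accepted random planes.
#' @param seed RNG seed for dataset generation.
#' @return an object of class `sampling_config`.
#' @export
sampling_config <- function(n_random = 20699L, n_near_sp = 1330L,
                            trans_range = 0.35, near_trans_step = 0.001,
                            near_rot_step = 1.9, random_trans_step = 0.1,
                            random_rot_step = 7.9, min_overlap = 0.5,
                            seed = 1L) {
  stopifnot(n_random >= 0, n_near_sp >= 0, trans_range > 0,
            near_trans_step > 0, near_rot_step > 0,
            min_overlap >= 0, min_overlap <= 1)
  structure(list(n_random = as.integer(n_random), n_near_sp = as.integer(n_near_sp),
                 trans_range = trans_range, near_trans_step = near_trans_step,
                 near_rot_step = near_rot_step,
                 random_trans_step = random_trans_step,
                 random_rot_step = random_rot_step, min_overlap = min_overlap,
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Read a sampling configuration from YAML
#'
#' Recognized keys mirror the arguments of [sampling_config()]; missing keys
#' take the defaults.
#'
#' @param path YAML file path.
#' @return a `sampling_config`.
#' @export
read_sampling_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(sampling_config))
  do.call(sampling_config, x[intersect(names(x), known)])
}

#' Draw a random plane pose
#'
#' Translations are uniform in `[-trans_range, trans_range]` per axis;
#' rotations are uniform on SO(3) (random unit quaternions). When a volume is
#' supplied, candidates are rejected until the plane's in-mask fraction
#' reaches `min_overlap`; sampling fails with an explanatory error after
#' `max_tries` rejections. Uses R's global RNG stream.
#'
#' @param config a [sampling_config()].
#' @param vol optional `us_volume` for overlap rejection.
#' @param spec slice geometry used for the overlap estimate.
#' @param max_tries rejection cap per accepted pose.
#' @return a [pose6d()].
#' @export
sample_random_pose <- function(config = sampling_config(), vol = NULL,
                               spec = slice_spec(), max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    pose <- pose6d(runif(3, -config$trans_range, config$trans_range),
                   random_rotations(1))
    if (is.null(vol) || config$min_overlap <= 0) return(pose)
    frac <- in_volume_fraction(vol, pose, spec, n_grid = 24L)
    if (frac >= config$min_overlap) return(pose)
  }
  stop(sprintf(paste0("failed to draw a pose with in-volume fraction >= %.2f ",
                      "after %d tries; loosen min_overlap or trans_range"),
               config$min_overlap, max_tries), call. = FALSE)
}

#' Draw a pose near a base pose
#'
#' Applies a small uniform perturbation: the translation moves by an
#' independent uniform offset within `near_trans_step` per axis, and the
#' rotation is composed (on the right) with a rotation about a uniformly
#' random axis by an angle uniform in `[0, near_rot_step]` degrees. The
#' geodesic distance to the base rotation therefore never exceeds
#' `near_rot_step`.
#'
#' @param base a [pose6d()].
#' @param config a [sampling_config()].
#' @return a [pose6d()].
#' @export
sample_near_pose <- function(base, config = sampling_config()) {
  dt <- runif(3, -config$near_trans_step, config$near_trans_step)
  ax <- rnorm(3)
  ang <- runif(1, 0, config$near_rot_step)
  pose6d(base$translation + dt, base$rotation %*% rot_axis_angle(ax, ang))
}

#' Generate a supervised slice dataset from a volume
#'
#' Draws `n_random` random-orientation poses (overlap-rejected) and
#' `n_near_sp` poses around the standard-plane annotation, extracts the
#' slices, writes them as 8-bit grayscale PNGs, and writes a CSV manifest
#' with one row per image: `path, tag, tx, ty, tz, r00..r22` (rotation in
#' row-major order). The whole dataset is reproducible from `config$seed`.
#'
#' @param vol a `us_volume`.
#' @param config a [sampling_config()].
#' @param spec a [slice_spec()].
#' @param out_dir output directory (created if needed); images go to
#'   `out_dir/images/`, the manifest to `out_dir/manifest.csv`.
#' @param sp_pose standard-plane pose (defaults to `vol$sp_pose`); required
#'   when `n_near_sp > 0`.
#' @param write_images write PNG files (default `TRUE`); with `FALSE` only
#'   the manifest is written and image paths still refer to the not-written
#'   files.
#' @return the manifest as a data.frame, invisibly; the path of the manifest
#'   is attached as `attr(*, "path")`.
#' @export
generate_dataset <- function(vol, config = sampling_config(),
                             spec = slice_spec(), out_dir,
                             sp_pose = vol$sp_pose, write_images = TRUE) {
  stopifnot(inherits(vol, "us_volume"))
  if (config$n_near_sp > 0 && is.null(sp_pose)) {
    stop("volume has no standard-plane pose but n_near_sp > 0", call. = FALSE)
  }
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)

  poses <- with_seed(config$seed, {
    c(lapply(seq_len(config$n_random), function(i)
        sample_random_pose(config, vol, spec)),
      lapply(seq_len(config$n_near_sp), function(i)
        sample_near_pose(sp_pose, config)))
  })
  tags <- rep(c("random", "near_sp"), c(config$n_random, config$n_near_sp))
  n <- length(poses)
  paths <- file.path("images", sprintf("slice_%06d.png", seq_len(n)))

  if (write_images && n > 0) {
    chunk <- 256L
    for (lo in seq(1L, n, by = chunk)) {
      hi <- min(lo + chunk - 1L, n)
      imgs <- extract_slices(vol, poses[lo:hi], spec)
      for (i in lo:hi) {
        png::writePNG(imgs[, , i - lo + 1L],
                      target = file.path(out_dir, paths[i]))
      }
    }
  }

  rot <- do.call(rbind, lapply(poses, function(p) as.numeric(t(p$rotation))))
  colnames(rot) <- paste0("r", c(t(outer(0:2, 0:2, paste0))))
  tr <- do.call(rbind, lapply(poses, `[[`, "translation"))
  manifest <- data.frame(path = paths, tag = tags,
                         tx = tr[, 1], ty = tr[, 2], tz = tr[, 3], rot,
                         stringsAsFactors = FALSE)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  attr(manifest, "path") <- mpath
  invisible(manifest)
}

#' Build an in-memory slice dataset
#'
#' Same sampling protocol as [generate_dataset()] (and identical poses for
#' the same seed) but keeps the slices in memory instead of writing PNGs —
#' convenient for training runs and cross-validation that do not need an
#' on-disk dataset.
#'
#' @inheritParams generate_dataset
#' @return a list with `images` (size_px x size_px x n array in `[0, 1]`),
#'   `poses` (list of [pose6d()]), `tags` and `volume_id`.
#' @export
make_pose_dataset <- function(vol, config = sampling_config(),
                              spec = slice_spec(), sp_pose = vol$sp_pose) {
  stopifnot(inherits(vol, "us_volume"))
  if (config$n_near_sp > 0 && is.null(sp_pose)) {
    stop("volume has no standard-plane pose but n_near_sp > 0", call. = FALSE)
  }
  poses <- with_seed(config$seed, {
    c(lapply(seq_len(config$n_random), function(i)
        sample_random_pose(config, vol, spec)),
      lapply(seq_len(config$n_near_sp), function(i)
        sample_near_pose(sp_pose, config)))
  })
  list(images = extract_slices(vol, poses, spec), poses = poses,
       tags = rep(c("random", "near_sp"), c(config$n_random, config$n_near_sp)),
       volume_id = vol$id)
}

#' Read a dataset manifest
#'
#' @param path manifest CSV path (or a dataset directory containing
#'   `manifest.csv`).
#' @return data.frame with columns `path, tag, tx, ty, tz, r00..r22`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(m, "path") <- path
  m
}

#' Poses stored in a manifest
#'
#' @param manifest a manifest data.frame (see [read_manifest()]).
#' @return list of [pose6d()] objects.
#' @export
manifest_poses <- function(manifest) {
  rn <- paste0("r", c(t(outer(0:2, 0:2, paste0))))
  lapply(seq_len(nrow(manifest)), function(i) {
    R <- matrix(as.numeric(manifest[i, rn]), 3, 3, byrow = TRUE)
    pose6d(as.numeric(manifest[i, c("tx", "ty", "tz")]), R)
  })
}

#' Intensity augmentation (brightness / contrast / saturation jitter)
#'
#' Applies, in order: brightness scaling `img * b`, contrast blending toward
#' the image mean `(img - mean) * c + mean`, and saturation jitter. Factors
#' are drawn uniformly from the given `[lo, hi]` ranges using R's global RNG.
#' On single-channel ultrasound images the saturation jitter is an exact
#' no-op (an image is its own grayscale), so the knob exists but defaults to
#' degenerate; it takes effect only in an opt-in 3-channel mode
#' (`dim(image)` = H x W x 3). Output is clipped to `[0, 1]`.
#'
#' @param image matrix (or H x W x 3 array) with values in `[0, 1]`.
#' @param brightness,contrast,saturation length-2 non-negative factor ranges;
#'   a degenerate range at 1 disables that jitter.
#' @return augmented image, same shape, in `[0, 1]`.
#' @export
augment_image <- function(image, brightness = c(0.5, 1.5),
                          contrast = c(0.5, 1.5), saturation = c(1, 1)) {
  for (rng in list(brightness, contrast, saturation)) {
    if (length(rng) != 2 || any(rng < 0) || rng[2] < rng[1]) {
      stop("jitter ranges must be non-negative [lo, hi] pairs", call. = FALSE)
    }
  }
  b <- runif(1, brightness[1], brightness[2])
  cf <- runif(1, contrast[1], contrast[2])
  sf <- runif(1, saturation[1], saturation[2])
  out <- image * b
  out <- (out - mean(out)) * cf + mean(out)
  if (length(dim(image)) == 3 && dim(image)[3] == 3 && sf != 1) {
    gray <- (out[, , 1] + out[, , 2] + out[, , 3]) / 3
    for (ch in 1:3) out[, , ch] <- gray + sf * (out[, , ch] - gray)
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
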