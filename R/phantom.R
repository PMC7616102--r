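## Synthetic fetal-brain phantom volumes.
##
## The phantom stands in for real 3D ultrasound acquisitions: a bright
## ellipsoidal skull shell around darker brain tissue, an echogenic falx
## midline, two hypoechoic lateral-ventricle bodies, a small cavum septum
## pellucidum (CSP) box, and a cerebellum-like mass. Structure sizes scale
## with a gestational-age-like parameter. Every phantom carries named
## fiducials, a brain mask, and a designated transventricular-like standard
## plane pose, so registration and pose-regression pipelines can be exercised
## with exact ground truth.

#' Phantom generation parameters
#'
#' @param ga_scale unitless size/shape parameter emulating gestational age.
#'   `ga_scale = 1` gives a brain of roughly 36 x 28 x 24 mm; the supported
#'   range is `[0.4, 1.3]` (structures must fit the grid, checked at build
#'   time). Real mid-trimester brains are larger; the phantom is deliberately
#'   desk-scale.
#' @param grid_shape integer length-3, voxels per axis (each >= 32).
#' @param spacing_mm isotropic voxel size in mm (default 0.5, matching common
#'   isotropically resampled fetal ultrasound volumes).
#' @param noise_level multiplicative speckle amplitude as a fraction of local
#'   intensity (0 disables noise). Speckle is modeled as uniform
#'   multiplicative noise; this exercises the pipeline but is not a physical
#'   ultrasound speckle model.
#' @param texture amplitude of the smooth parenchymal texture field (0
#'   disables it): brain-interior intensities are modulated by a fixed,
#'   seed-determined sum of 3D sinusoids with millimetre-scale wavelengths,
#'   emulating the inhomogeneous speckle texture of brain tissue.
#' @param attenuation lateral depth-attenuation strength in `[0, 1)`: voxel
#'   intensities are scaled linearly from 1 on the proximal (+x) side of the
#'   grid down to `1 - attenuation` on the distal side, emulating the
#'   intensity falloff across the midline seen when the probe is lateral to
#'   the fetal head.
#' @param seed integer RNG seed; phantoms are bit-reproducible given the seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(ga_scale = 1, grid_shape = c(96, 96, 96),
                         spacing_mm = 0.5, noise_level = 0.15,
                         texture = 0.5, attenuation = 0.5, seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 32),
            spacing_mm > 0, noise_level >= 0, ga_scale > 0,
            texture >= 0, attenuation >= 0, attenuation < 1)
  if (ga_scale < 0.4 || ga_scale > 1.3) {
    stop("ga_scale outside the supported range [0.4, 1.3]", call. = FALSE)
  }
  structure(list(ga_scale = ga_scale, grid_shape = as.integer(grid_shape),
                 spacing_mm = spacing_mm, noise_level = noise_level,
                 texture = texture, attenuation = attenuation,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Nominal per-structure intensities on the 0-255 scale (noise-free values).
phantom_intensities <- function() {
  c(background = 10, skull = 250, brain = 80, midline = 180,
    ventricle = 20, csp = 30, cerebellum = 170)
}

# Structure geometry in mm offsets from the grid center, all scaled by
# ga_scale. Semi-axis order is (x = lateral, y = anterior-posterior,
# z = inferior-superior).
phantom_geometry <- function(ga) {
  list(
    skull_semi = ga * c(14, 18, 12),
    shell_mm = 1.5,
    vent_center = list(left = ga * c(4.5, -5, 1), right = ga * c(-4.5, -5, 1)),
    vent_semi = list(left = 1.15 * ga * c(2.5, 5.5, 2.5),
                     right = ga * c(2.5, 5.5, 2.5)),
    csp_half = ga * c(1.5, 1.5, 1.5),
    csp_center = ga * c(0, 5.5, 0),
    cereb_center = ga * c(0, -6, -7),
    cereb_semi = ga * c(6, 3.5, 2.5),
    midline_half_mm = 0.5
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a synthetic fetal-brain phantom volume
#'
#' Constructs the voxel grid, anatomy, brain mask, named fiducials and the
#' standard-plane pose described in [phantom_spec()]. The brain mask is the
#' full skull ellipsoid (shell included); the normalized `[-1, 1]` pose frame
#' is anchored to the mask bounding box (its center maps to the origin, its
#' half-extents to one normalized unit per axis), making poses independent of
#' physical brain size.
#'
#' The standard plane emulates the transventricular plane: an axial-ish plane
#' tilted 8 degrees about the lateral axis, passing through the ventricle
#' bodies and the CSP.
#'
#' @param spec a [phantom_spec()].
#' @param id optional volume identifier string.
#' @return an object of class `us_volume`: a list with `voxels` (3D array,
#'   0-255), `spacing` (mm), `origin` (mm), `mask` (logical array),
#'   `fiducials` (data.frame `label,x_mm,y_mm,z_mm`), `center_mm`,
#'   `mm_per_unit`, `sp_pose` ([pose6d()]) and `id`.
#' @export
make_phantom <- function(spec = phantom_spec(), id = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  ga <- spec$ga_scale
  geo <- phantom_geometry(ga)
  ints <- phantom_intensities()
  n <- spec$grid_shape
  sp <- rep(spec$spacing_mm, 3)
  half_extent <- (n - 1) * sp / 2
  if (any(geo$skull_semi + 2 * sp > half_extent)) {
    stop("grid too small to contain the skull ellipsoid at this ga_scale",
         call. = FALSE)
  }
  origin <- c(0, 0, 0)
  center <- origin + (n - 1) * sp / 2

  # voxel center coordinates relative to the grid center, mm
  xs <- (seq_len(n[1]) - 1) * sp[1] - center[1]
  ys <- (seq_len(n[2]) - 1) * sp[2] - center[2]
  zs <- (seq_len(n[3]) - 1) * sp[3] - center[3]
  X <- array(rep(xs, times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(ys, each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(zs, each = n[1] * n[2]), dim = n)

  ell <- function(ctr, semi) {
    ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
      ((Z - ctr[3]) / semi[3])^2 <= 1
  }
  outer_e <- ell(c(0, 0, 0), geo$skull_semi)
  inner_e <- ell(c(0, 0, 0), pmax(geo$skull_semi - geo$shell_mm, 0.5))

  vox <- array(ints[["background"]], dim = n)
  vox[outer_e] <- ints[["skull"]]
  vox[inner_e] <- ints[["brain"]]
  vox[inner_e & abs(X) <= geo$midline_half_mm] <- ints[["midline"]]
  vox[inner_e & ell(geo$cereb_center, geo$cereb_semi)] <- ints[["cerebellum"]]
  vox[inner_e & ell(geo$vent_center$left, geo$vent_semi$left)] <- ints[["ventricle"]]
  vox[inner_e & ell(geo$vent_center$right, geo$vent_semi$right)] <- ints[["ventricle"]]
  csp_box <- abs(X - geo$csp_center[1]) <= geo$csp_half[1] &
    abs(Y - geo$csp_center[2]) <= geo$csp_half[2] &
    abs(Z - geo$csp_center[3]) <= geo$csp_half[3]
  vox[inner_e & csp_box] <- ints[["csp"]]

  # parenchymal texture: a smooth multiplicative field built from a few fixed
  # 3D sinusoids (wavelengths of a few mm, orientations/phases drawn once
  # from the seed). Real brain tissue is not homogeneous on ultrasound; the
  # texture gives slices position- and orientation-dependent appearance
  # everywhere, not only at the discrete structures.
  if (spec$texture > 0) {
    waves <- with_seed(spec$seed + 1L, {
      lapply(1:4, function(i) {
        k <- rnorm(3)
        list(k = 2 * pi * k / sqrt(sum(k^2)) / runif(1, 3, 8), # wavelength 3-8 mm
             phase = runif(1, 0, 2 * pi))
      })
    })
    tex <- 0
    for (w in waves) {
      tex <- tex + sin(w$k[1] * X + w$k[2] * Y + w$k[3] * Z + w$phase)
    }
    vox[inner_e] <- vox[inner_e] * (1 + spec$texture * tex[inner_e] / 2)
  }

  # depth attenuation: the probe sits lateral to the head, so intensity falls
  # off across the midline toward the distal (here -x) hemisphere. Besides
  # realism this makes the pose identifiable: without it the phantom would be
  # nearly mirror-symmetric about the midline and a slice would be almost
  # indistinguishable from its mirrored counterpart.
  if (spec$attenuation > 0) {
    # lateral ramp spans the brain, 0 at its proximal (+x) edge to 1 distal
    a1 <- geo$skull_semi[1]
    depth <- pmin(pmax((a1 - X) / (2 * a1), 0), 1)
    vox <- vox * (1 - spec$attenuation * depth)
    # milder axial (beam-direction) gain ramp along z, as left by imperfect
    # time-gain compensation. Together the two ramps leave no 180-degree
    # rotation of the volume photometrically neutral, so plane orientation is
    # identifiable from shading alone.
    a3 <- geo$skull_semi[3]
    axial <- pmin(pmax((a3 - Z) / (2 * a3), 0), 1)
    vox <- vox * (1 - 0.6 * spec$attenuation * axial)
  }

  if (spec$noise_level > 0) {
    noise <- with_seed(spec$seed, runif(length(vox), -1, 1))
    vox <- vox * (1 + spec$noise_level * noise)
    vox[vox < 0] <- 0
    vox[vox > 255] <- 255
  }

  mask <- outer_e
  fid_local <- rbind(
    csp = geo$csp_center,
    ventricle_left = geo$vent_center$left,
    ventricle_right = geo$vent_center$right,
    cerebellum = geo$cereb_center,
    midline_anterior = c(0, 0.85 * geo$skull_semi[2], 0),
    midline_posterior = c(0, -0.85 * geo$skull_semi[2], 0)
  )
  fiducials <- data.frame(label = rownames(fid_local),
                          x_mm = fid_local[, 1] + center[1],
                          y_mm = fid_local[, 2] + center[2],
                          z_mm = fid_local[, 3] + center[3],
                          row.names = NULL)

  vol <- us_volume(vox, spacing = sp, origin = origin, mask = mask,
                   fiducials = fiducials, id = id)

  # transventricular-like standard plane: tilted axial plane through the
  # ventricle bodies and CSP
  sp_z_mm <- 0.5 * ga
  t_norm <- c(0, 0, sp_z_mm) / vol$mm_per_unit
  vol$sp_pose <- pose6d(t_norm, rot_x(8))
  vol
}

#' Construct a volume object
#'
#' Low-level constructor used by [make_phantom()] and the volume readers.
#' The normalized-frame anchors (`center_mm`, `mm_per_unit`) are derived from
#' the mask bounding box unless supplied.
#'
#' @param voxels 3D numeric array (0-255 intensity scale).
#' @param spacing length-3 positive mm per voxel.
#' @param origin length-3 mm position of voxel `[1,1,1]`.
#' @param mask logical array of the same shape (brain region).
#' @param fiducials data.frame with columns `label,x_mm,y_mm,z_mm` (may be
#'   empty).
#' @param sp_pose optional [pose6d()] standard-plane annotation.
#' @param id optional identifier.
#' @param center_mm,mm_per_unit optional normalized-frame anchors.
#' @return an object of class `us_volume`.
#' @export
us_volume <- function(voxels, spacing, origin = c(0, 0, 0), mask = NULL,
                      fiducials = NULL, sp_pose = NULL, id = NULL,
                      center_mm = NULL, mm_per_unit = NULL) {
  stopifnot(length(dim(voxels)) == 3, length(spacing) == 3, all(spacing > 0),
            length(origin) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(voxels))
  stopifnot(all(dim(mask) == dim(voxels)))
  if (is.null(fiducials)) {
    fiducials <- data.frame(label = character(), x_mm = numeric(),
                            y_mm = numeric(), z_mm = numeric())
  }
  upper <- origin + (dim(voxels) - 1) * spacing
  if (nrow(fiducials) > 0) {
    pts <- as.matrix(fiducials[, c("x_mm", "y_mm", "z_mm")])
    ok <- pts >= matrix(origin, nrow(pts), 3, byrow = TRUE) &
      pts <= matrix(upper, nrow(pts), 3, byrow = TRUE)
    if (!all(ok)) {
      stop("fiducial(s) outside the voxel grid's physical bounds: ",
           paste(fiducials$label[!apply(ok, 1, all)], collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(center_mm) || is.null(mm_per_unit)) {
    bb <- mask_bbox_mm(mask, spacing, origin)
    if (is.null(center_mm)) center_mm <- (bb$lo + bb$hi) / 2
    if (is.null(mm_per_unit)) mm_per_unit <- pmax((bb$hi - bb$lo) / 2, 1e-6)
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), mask = mask,
                 fiducials = fiducials, center_mm = as.numeric(center_mm),
                 mm_per_unit = as.numeric(mm_per_unit), sp_pose = sp_pose,
                 id = id),
            class = "us_volume")
}

mask_bbox_mm <- function(mask, spacing, origin) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty", call. = FALSE)
  lo <- (apply(idx, 2, min) - 1) * spacing + origin
  hi <- (apply(idx, 2, max) - 1) * spacing + origin
  list(lo = lo, hi = hi)
}

#' @export
print.us_volume <- function(x, ...) {
  cat(sprintf("<us_volume%s> %s voxels @ %s mm, %d fiducials, mask %.1f%%%s\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              nrow(x$fiducials), 100 * mean(x$mask),
              if (is.null(x$sp_pose)) "" else ", SP annotated"))
  invisible(x)
}

#' Convert between normalized and physical coordinates of a volume
#'
#' The normalized frame maps the mask bounding box to `[-1, 1]` per axis.
#'
#' @param vol a `us_volume`.
#' @param pts n x 3 matrix (or length-3 vector) of points.
#' @return matrix (or vector) of converted points.
#' @export
norm_to_mm <- function(vol, pts) {
  v <- !is.matrix(pts)
  if (v) pts <- matrix(pts, 1)
  out <- sweep(sweep(pts, 2, vol$mm_per_unit, `*`), 2, vol$center_mm, `+`)
  if (v) out[1, ] else out
}

#' @rdname norm_to_mm
#' @export
mm_to_norm <- function(vol, pts) {
  v <- !is.matrix(pts)
  if (v) pts <- matrix(pts, 1)
  out <- sweep(sweep(pts, 2, vol$center_mm, `-`), 2, vol$mm_per_unit, `/`)
  if (v) out[1, ] else out
}

#' Apply a known similarity transform to a phantom
#'
#' Produces a misaligned copy of a volume: the image content is moved by the
#' transform (the output voxel at physical point x holds the input volume
#' interpolated at \eqn{T^{-1}(x)}), the mask is moved the same way
#' (nearest-fraction threshold at 0.5), and the fiducials and standard-plane
#' pose are transformed *analytically* — point positions are mapped exactly
#' by \eqn{x \mapsto s R x + t} with no interpolation error. The normalized
#' frame anchors are recomputed from the transformed mask.
#'
#' @param vol a `us_volume`.
#' @param transform a [similarity_transform()] mapping the input volume's
#'   physical frame to the output frame.
#' @param seed RNG seed for the optional fresh speckle.
#' @param noise_level optional extra multiplicative speckle applied after
#'   resampling (default 0).
#' @return a transformed `us_volume` on the same voxel grid. If part of the
#'   brain mask is pushed outside the grid a warning is raised and the result
#'   carries `attr(*, "cropped") = TRUE`.
#' @export
perturb_phantom <- function(vol, transform, seed = 1L, noise_level = 0) {
  stopifnot(inherits(vol, "us_volume"), inherits(transform, "similarity_transform"))
  out <- resample_volume(vol, transform, reference = vol)
  n_expect <- sum(vol$mask) * transform$scale^3
  n_got <- sum(out$mask)
  if (n_got < 0.97 * n_expect) {
    warning("transform moved part of the brain outside the voxel grid; content cropped")
    attr(out, "cropped") <- TRUE
  }
  if (noise_level > 0) {
    noise <- with_seed(seed, runif(length(out$voxels), -1, 1))
    out$voxels <- pmin(pmax(out$voxels * (1 + noise_level * noise), 0), 255)
  }
  if (!is.null(vol$sp_pose)) {
    # transform the annotated plane analytically: position via the point map,
    # orientation via the rotation part (scale does not affect orientation)
    p_mm <- transform_points(transform, norm_to_mm(vol, vol$sp_pose$translation))
    out$sp_pose <- pose6d(mm_to_norm(out, p_mm),
                          transform$rotation %*% vol$sp_pose$rotation)
  }
  out$id <- vol$id
  out
}

## ---- volume I/O -------------------------------------------------------------

#' Read and write volumes
#'
#' A volume is stored as a set of sibling files sharing a path prefix:
#' `<prefix>_vol.nii.gz` and `<prefix>_mask.nii.gz` (NIfTI, spacing in the
#' header), `<prefix>_fiducials.csv` (columns `label,x_mm,y_mm,z_mm`,
#' 3D-Slicer-compatible column subset) and `<prefix>_meta.json` (origin,
#' normalized-frame anchors, standard-plane pose, id).
#'
#' @param vol a `us_volume`.
#' @param prefix path prefix (directories must exist).
#' @return [write_volume()]: `prefix`, invisibly; [read_volume()]: a
#'   `us_volume`.
#' @export
write_volume <- function(vol, prefix) {
  img <- RNifti::asNifti(vol$voxels, pixdim = vol$spacing)
  RNifti::writeNifti(img, paste0(prefix, "_vol.nii.gz"))
  mimg <- RNifti::asNifti(array(as.numeric(vol$mask), dim(vol$mask)),
                          pixdim = vol$spacing)
  RNifti::writeNifti(mimg, paste0(prefix, "_mask.nii.gz"))
  write_fiducials(vol$fiducials, paste0(prefix, "_fiducials.csv"))
  meta <- list(spacing = vol$spacing, origin = vol$origin,
               center_mm = vol$center_mm, mm_per_unit = vol$mm_per_unit,
               id = vol$id)
  if (!is.null(vol$sp_pose)) {
    meta$sp_translation <- vol$sp_pose$translation
    meta$sp_rotation <- as.numeric(vol$sp_pose$rotation) # column-major
  }
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(prefix)
}

#' @rdname write_volume
#' @export
read_volume <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, "_vol.nii.gz"))
  vox <- array(as.numeric(img), dim = dim(img))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  mask_path <- paste0(prefix, "_mask.nii.gz")
  mask <- if (file.exists(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    array(as.numeric(m) > 0.5, dim = dim(m))
  } else NULL
  fid_path <- paste0(prefix, "_fiducials.csv")
  fiducials <- if (file.exists(fid_path)) read_fiducials(fid_path) else NULL
  sp_pose <- if (!is.null(meta$sp_translation)) {
    pose6d(as.numeric(meta$sp_translation),
           matrix(as.numeric(meta$sp_rotation), 3, 3))
  } else NULL
  us_volume(vox, spacing = as.numeric(meta$spacing),
            origin = as.numeric(meta$origin), mask = mask,
            fiducials = fiducials, sp_pose = sp_pose,
            id = if (is.null(meta$id)) NULL else meta$id,
            center_mm = as.numeric(meta$center_mm),
            mm_per_unit = as.numeric(meta$mm_per_unit))
}

#' @rdname write_volume
#' @param fiducials data.frame with columns `label,x_mm,y_mm,z_mm`.
#' @param path CSV path.
#' @export
write_fiducials <- function(fiducials, path) {
  utils::write.csv(fiducials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_fiducials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) {
    stop("fiducial CSV must have columns label,x_mm,y_mm,z_mm", call. = FALSE)
  }
  df[, need]
}
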