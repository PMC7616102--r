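## Fiducial-based similarity registration (7 degrees of freedom: rotation,
## translation, uniform scale) and the registration-quality metrics.

#' Similarity (7-DOF) transform
#'
#' Maps physical points between volume frames as \eqn{x \mapsto s R x + t}
#' with uniform scale `s > 0`, proper rotation `R`, and translation `t` (mm).
#'
#' @param scale positive scalar.
#' @param rotation 3x3 rotation matrix.
#' @param translation_mm length-3 numeric, mm.
#' @return an object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3),
                                 translation_mm = c(0, 0, 0)) {
  stopifnot(length(scale) == 1, is.finite(scale), length(translation_mm) == 3)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  assert_rotation(rotation)
  structure(list(scale = as.numeric(scale), rotation = rotation,
                 translation_mm = as.numeric(translation_mm)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.4f, rotation %.2f deg, t = (%s) mm\n",
              x$scale, geodesic_error_deg(diag(3), x$rotation),
              paste(sprintf("%.2f", x$translation_mm), collapse = ", ")))
  invisible(x)
}

#' Apply, invert and compose similarity transforms
#'
#' @param transform,a,b `similarity_transform` objects.
#' @param pts n x 3 matrix (or length-3 vector) of mm points.
#' @return [transform_points()]: transformed points; [invert_transform()] the
#'   inverse transform; [compose_transforms()] the composition `a` after `b`
#'   (i.e. `x -> a(b(x))`).
#' @export
transform_points <- function(transform, pts) {
  v <- !is.matrix(pts)
  if (v) pts <- matrix(pts, 1)
  out <- transform$scale * pts %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation_mm, `+`)
  if (v) out[1, ] else out
}

#' @rdname transform_points
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  similarity_transform(1 / transform$scale, Rt,
                       -(1 / transform$scale) * as.numeric(Rt %*% transform$translation_mm))
}

#' @rdname transform_points
#' @export
compose_transforms <- function(a, b) {
  similarity_transform(a$scale * b$scale, a$rotation %*% b$rotation,
                       a$scale * as.numeric(a$rotation %*% b$translation_mm) +
                         a$translation_mm)
}

match_fiducials <- function(a, b) {
  common <- intersect(a$label, b$label)
  if (length(common) < length(union(a$label, b$label))) {
    missing <- setdiff(union(a$label, b$label), common)
    stop("fiducial labels do not match between sets: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  list(a = as.matrix(a[match(common, a$label), c("x_mm", "y_mm", "z_mm")]),
       b = as.matrix(b[match(common, b$label), c("x_mm", "y_mm", "z_mm")]),
       labels = common)
}

#' Closed-form least-squares similarity fit from matched fiducials
#'
#' Estimates the 7-DOF similarity transform minimizing
#' \eqn{\sum_i \| s R m_i + t - f_i \|^2} over matched landmark pairs, using
#' the closed-form construction: centroids, cross-covariance SVD with
#' determinant-corrected rotation, variance-ratio scale. At least 3
#' non-collinear matched points are required for a unique fit.
#'
#' @param moving,fixed fiducial data.frames (`label,x_mm,y_mm,z_mm`); labels
#'   are matched by name, so point order is irrelevant.
#' @return a `similarity_transform` mapping moving to fixed coordinates, with
#'   the post-fit residual RMS (mm) attached as `attr(*, "rms_mm")`.
#' @export
fit_similarity <- function(moving, fixed) {
  m <- match_fiducials(moving, fixed)
  M <- m$a; F <- m$b
  n <- nrow(M)
  if (n < 3) stop("at least 3 matched fiducials are required", call. = FALSE)
  mu_m <- colMeans(M); mu_f <- colMeans(F)
  Mc <- sweep(M, 2, mu_m); Fc <- sweep(F, 2, mu_f)
  C <- crossprod(Fc, Mc) / n  # cross-covariance fixed x moving
  sv <- svd(C)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12)) {
    stop("fiducial configuration is collinear; similarity fit is not unique",
         call. = FALSE)
  }
  s3 <- sign(det(sv$u) * det(sv$v))
  if (s3 == 0) s3 <- 1
  D <- diag(c(1, 1, s3))
  R <- sv$u %*% D %*% t(sv$v)
  var_m <- sum(Mc^2) / n
  scale <- sum(diag(diag(sv$d) %*% D)) / var_m
  t_mm <- mu_f - scale * as.numeric(R %*% mu_m)
  tf <- similarity_transform(scale, R, t_mm)
  resid <- transform_points(tf, M) - F
  attr(tf, "rms_mm") <- sqrt(mean(rowSums(resid^2)))
  tf
}

#' RMS distance between matched fiducial sets
#'
#' The root mean square of the Euclidean distances between identically
#' labelled landmarks — the standard registration-accuracy metric reported
#' in mm. Labels are matched by name; a mismatch raises an error naming the
#' offending labels.
#'
#' @inheritParams fit_similarity
#' @param a,b fiducial data.frames.
#' @return RMS landmark distance in mm.
#' @export
fiducial_rms <- function(a, b) {
  m <- match_fiducials(a, b)
  sqrt(mean(rowSums((m$a - m$b)^2)))
}

#' Masked intensity RMS between two volumes on a shared grid
#'
#' The root mean square of voxelwise intensity differences (0-255 scale)
#' restricted to a mask. The mask restriction keeps the score about the brain
#' anatomy rather than the shape of the ultrasound cone. Both volumes must
#' already live on the same grid (use [resample_volume()] first).
#'
#' @param vol_a,vol_b `us_volume` objects on identical grids.
#' @param mask logical array on that grid; defaults to `vol_a$mask`.
#' @return intensity RMS score.
#' @export
intensity_rms <- function(vol_a, vol_b, mask = NULL) {
  if (!all(dim(vol_a$voxels) == dim(vol_b$voxels))) {
    stop("volumes are not on a shared grid; resample first", call. = FALSE)
  }
  if (is.null(mask)) mask <- vol_a$mask
  stopifnot(all(dim(mask) == dim(vol_a$voxels)))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  d <- vol_a$voxels[mask] - vol_b$voxels[mask]
  sqrt(mean(d^2))
}

#' Resample a volume under a similarity transform
#'
#' Returns the volume's content moved by `transform`, sampled onto the
#' reference volume's grid: the output voxel at physical point `x` holds the
#' input interpolated (trilinearly) at \eqn{T^{-1}(x)}. The mask is moved the
#' same way and re-binarized at 0.5; fiducials are transformed analytically
#' (exact point map, no interpolation), with any landmark leaving the
#' reference grid dropped with a warning.
#'
#' @param vol a `us_volume`.
#' @param transform a `similarity_transform` mapping `vol`'s frame to the
#'   reference frame.
#' @param reference a `us_volume` defining the output grid (defaults to
#'   `vol`).
#' @param fill intensity for samples outside the input grid (default 0).
#' @return a `us_volume` on the reference grid.
#' @export
resample_volume <- function(vol, transform, reference = vol, fill = 0) {
  stopifnot(inherits(vol, "us_volume"), inherits(transform, "similarity_transform"))
  inv <- invert_transform(transform)
  A <- inv$scale * inv$rotation
  b <- inv$translation_mm
  dims <- dim(vol$voxels)
  rdims <- dim(reference$voxels)
  vox <- resample_affine_cpp(as.numeric(vol$voxels), as.integer(dims),
                             vol$spacing, vol$origin, as.integer(rdims),
                             reference$spacing, reference$origin,
                             as.numeric(A), b, fill)
  vox <- array(vox, dim = rdims)
  mk <- resample_affine_cpp(as.numeric(vol$mask), as.integer(dims),
                            vol$spacing, vol$origin, as.integer(rdims),
                            reference$spacing, reference$origin,
                            as.numeric(A), b, 0)
  mk <- array(mk > 0.5, dim = rdims)
  fid <- vol$fiducials
  if (nrow(fid) > 0) {
    pts <- transform_points(transform, as.matrix(fid[, c("x_mm", "y_mm", "z_mm")]))
    upper <- reference$origin + (rdims - 1) * reference$spacing
    ok <- apply(pts >= matrix(reference$origin, nrow(pts), 3, byrow = TRUE) &
                  pts <= matrix(upper, nrow(pts), 3, byrow = TRUE), 1, all)
    if (!all(ok)) {
      warning("fiducial(s) transformed outside the reference grid dropped: ",
              paste(fid$label[!ok], collapse = ", "))
    }
    fid <- data.frame(label = fid$label[ok], x_mm = pts[ok, 1],
                      y_mm = pts[ok, 2], z_mm = pts[ok, 3])
  }
  if (any(mk)) {
    us_volume(vox, spacing = reference$spacing, origin = reference$origin,
              mask = mk, fiducials = fid, id = vol$id)
  } else {
    # transform moved the whole mask off the reference grid; keep the
    # analytically transformed normalized-frame anchors so the volume stays
    # usable
    warning("transformed mask is empty on the reference grid")
    us_volume(vox, spacing = reference$spacing, origin = reference$origin,
              mask = mk, fiducials = fid, id = vol$id,
              center_mm = transform_points(transform, vol$center_mm),
              mm_per_unit = transform$scale * vol$mm_per_unit)
  }
}

#' Read and write similarity transforms as JSON
#'
#' Format: `{"scale": s, "rotation_matrix": [[..],[..],[..]],
#' "translation_mm": [..]}` with the rotation in row-major nested arrays.
#'
#' @param transform a `similarity_transform`.
#' @param path file path.
#' @return [read_transform()]: a `similarity_transform`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(scale = transform$scale,
         rotation_matrix = apply(transform$rotation, 1, function(r) r,
                                 simplify = FALSE),
         translation_mm = transform$translation_mm),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(x$scale,
                       if (is.matrix(x$rotation_matrix)) x$rotation_matrix
                       else do.call(rbind, x$rotation_matrix),
                       as.numeric(x$translation_mm))
}

#' Register one volume to another and report quality metrics
#'
#' Convenience driver: fits the fiducial similarity transform from `moving`
#' to `fixed`, resamples `moving` onto the fixed grid, and reports pre- and
#' post-registration fiducial RMS plus masked intensity RMS.
#'
#' @param moving,fixed `us_volume` objects with matching fiducial labels.
#' @return a list with `transform`, `registered` (resampled volume) and
#'   `report` (named numerics: `fiducial_rms_pre/post`,
#'   `intensity_rms_pre/post`, `fit_rms`).
#' @export
register_volumes <- function(moving, fixed) {
  tf <- fit_similarity(moving$fiducials, fixed$fiducials)
  reg <- resample_volume(moving, tf, reference = fixed)
  report <- c(
    fiducial_rms_pre = fiducial_rms(moving$fiducials, fixed$fiducials),
    fiducial_rms_post = fiducial_rms(reg$fiducials, fixed$fiducials),
    intensity_rms_pre = intensity_rms(fixed, moving, fixed$mask),
    intensity_rms_post = intensity_rms(fixed, reg, fixed$mask),
    fit_rms = attr(tf, "rms_mm")
  )
  list(transform = tf, registered = reg, report = report)
}
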