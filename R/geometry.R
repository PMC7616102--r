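#' @useDynLib planepose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif sd setNames
NULL

.DEG <- 180 / pi

## ---- validation helpers -----------------------------------------------------

#' Test whether a matrix is a proper rotation
#'
#' A proper rotation matrix is orthonormal (\eqn{R^T R = I}) with determinant
#' +1. Tolerance refers to the maximum absolute deviation of \eqn{R^T R} from
#' the identity and of \eqn{\det R} from 1.
#'
#' @param m a 3x3 numeric matrix.
#' @param tol numeric tolerance (default `1e-6`).
#' @return `TRUE` or `FALSE`.
#' @export
is_rotation_matrix <- function(m, tol = 1e-6) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)) || !all(is.finite(m))) {
    return(FALSE)
  }
  max(abs(crossprod(m) - diag(3))) < tol && abs(det(m) - 1) < tol
}

assert_rotation <- function(m, arg = "rotation") {
  if (!is_rotation_matrix(m, tol = 1e-5)) {
    stop(sprintf("'%s' is not a valid rotation matrix (orthonormal, det +1)", arg),
         call. = FALSE)
  }
  invisible(m)
}

## ---- axis-angle / Euler constructors ---------------------------------------

#' Rotation about a coordinate axis or arbitrary axis
#'
#' Convenience constructors for rotation matrices. Angles are given in
#' degrees; internally all trigonometry is done in radians. The coordinate
#' frame is right-handed with rows/columns indexed x, y, z.
#'
#' @param angle_deg rotation angle in degrees.
#' @param axis for [rot_axis_angle()], a length-3 numeric axis (need not be
#'   normalized, must be nonzero).
#' @return a 3x3 rotation matrix.
#' @export
rot_x <- function(angle_deg) rot_axis_angle(c(1, 0, 0), angle_deg)

#' @rdname rot_x
#' @export
rot_y <- function(angle_deg) rot_axis_angle(c(0, 1, 0), angle_deg)

#' @rdname rot_x
#' @export
rot_z <- function(angle_deg) rot_axis_angle(c(0, 0, 1), angle_deg)

#' @rdname rot_x
#' @export
rot_axis_angle <- function(axis, angle_deg) {
  stopifnot(length(axis) == 3, all(is.finite(axis)))
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be nonzero", call. = FALSE)
  u <- axis / n
  th <- angle_deg / .DEG
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Euler-angle display helper
#'
#' Converts a rotation matrix to intrinsic z-y-x (yaw, pitch, roll) Euler
#' angles in degrees, and back. These are display/interchange helpers only:
#' all pose mathematics in this package operates on rotation matrices or
#' quaternions, never on Euler angles (which are discontinuous and
#' gimbal-locked, the reason the 6D representation exists).
#'
#' @param R a rotation matrix.
#' @param angles_deg numeric length-3 vector `(yaw_z, pitch_y, roll_x)` in
#'   degrees.
#' @return [matrix_to_euler_deg()]: length-3 numeric; [euler_deg_to_matrix()]:
#'   a 3x3 rotation matrix.
#' @export
matrix_to_euler_deg <- function(R) {
  assert_rotation(R)
  pitch <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(pitch)) > 1e-9) {
    yaw <- atan2(R[2, 1], R[1, 1])
    roll <- atan2(R[3, 2], R[3, 3])
  } else { # gimbal lock: fold roll into yaw
    yaw <- atan2(-R[1, 2], R[2, 2])
    roll <- 0
  }
  c(yaw = yaw, pitch = pitch, roll = roll) * .DEG
}

#' @rdname matrix_to_euler_deg
#' @export
euler_deg_to_matrix <- function(angles_deg) {
  stopifnot(length(angles_deg) == 3)
  rot_z(angles_deg[1]) %*% rot_y(angles_deg[2]) %*% rot_x(angles_deg[3])
}

## ---- 6D rotation representation --------------------------------------------

#' Decode the continuous 6D rotation representation
#'
#' The 6-vector `r = (r1..r6)` encodes a rotation as two unnormalized 3D
#' vectors `a = (r1,r2,r3)` and `b = (r4,r5,r6)`. Decoding is a Gram-Schmidt
#' construction: the first column of the rotation is `a` normalized, the
#' second is `b` orthogonalized against the first and normalized, and the
#' third is their cross product. This map is continuous and surjective onto
#' SO(3), which is what makes the 6D encoding suitable as a regression
#' target, unlike Euler angles or quaternions.
#'
#' The construction is smooth everywhere on the valid domain (no branching),
#' so an analytic gradient exists; [rot6d_backward()] implements it for the
#' network training code.
#'
#' @param r numeric length-6 vector.
#' @return a 3x3 rotation matrix.
#' @seealso [matrix_to_rot6d()] for the (non-unique) inverse encoding.
#' @export
rot6d_to_matrix <- function(r) {
  stopifnot(length(r) == 6)
  if (!all(is.finite(r))) {
    stop("invalid 6D rotation representation: non-finite entries", call. = FALSE)
  }
  a <- r[1:3]
  b <- r[4:6]
  na <- sqrt(sum(a^2))
  if (na < 1e-12) {
    stop("invalid 6D rotation representation: first 3-vector is zero", call. = FALSE)
  }
  c1 <- a / na
  w <- b - sum(c1 * b) * c1
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) {
    stop("invalid 6D rotation representation: vectors are parallel or second is zero",
         call. = FALSE)
  }
  c2 <- w / nw
  c3 <- c(c1[2] * c2[3] - c1[3] * c2[2],
          c1[3] * c2[1] - c1[1] * c2[3],
          c1[1] * c2[2] - c1[2] * c2[1])
  cbind(c1, c2, c3, deparse.level = 0)
}

#' Encode a rotation matrix as a 6D representation
#'
#' The canonical encoding is simply the first two columns of the matrix;
#' decoding with [rot6d_to_matrix()] recovers the original matrix exactly (up
#' to floating point).
#'
#' @param R a 3x3 rotation matrix.
#' @return numeric length-6 vector.
#' @export
matrix_to_rot6d <- function(R) {
  assert_rotation(R)
  c(R[, 1], R[, 2])
}

#' Gradient of the 6D decoding (for network training)
#'
#' Given the upstream gradient `dR` of some scalar loss with respect to the
#' decoded rotation matrix, returns the gradient with respect to the raw
#' 6-vector. Used by the pose-regression training loop; exposed so the chain
#' rule can be verified against numerical differentiation.
#'
#' @param r numeric length-6 vector (the raw encoding).
#' @param dR 3x3 matrix of upstream gradients dL/dR.
#' @return numeric length-6 gradient dL/dr.
#' @keywords internal
#' @export
rot6d_backward <- function(r, dR) {
  a <- r[1:3]; b <- r[4:6]
  na <- sqrt(sum(a^2))
  c1 <- a / na
  d <- sum(c1 * b)
  w <- b - d * c1
  nw <- sqrt(sum(w^2))
  c2 <- w / nw
  g1 <- dR[, 1]; g2 <- dR[, 2]; g3 <- dR[, 3]
  # c3 = c1 x c2: route g3 into c1 and c2
  gc1 <- g1 + cross3(c2, g3)
  gc2 <- g2 + cross3(g3, c1)
  # c2 = w/|w|
  gw <- (gc2 - c2 * sum(c2 * gc2)) / nw
  # w = b - (c1.b) c1
  gb <- gw - c1 * sum(c1 * gw)
  gc1 <- gc1 - (d * gw + b * sum(c1 * gw))
  # c1 = a/|a|
  ga <- (gc1 - c1 * sum(c1 * gc1)) / na
  c(ga, gb)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## ---- quaternions ------------------------------------------------------------

#' Quaternion utilities
#'
#' Unit quaternions are stored as length-4 numeric vectors in scalar-first
#' order `(s, x, y, z)`. `q` and `-q` represent the same rotation; functions
#' that compare rotations account for this sign ambiguity.
#'
#' @param q,q1,q2 unit quaternions, scalar-first.
#' @param R a 3x3 rotation matrix.
#' @return [quat_from_matrix()] returns a unit quaternion with non-negative
#'   scalar part; [quat_to_matrix()] a rotation matrix; [quat_mul()] the
#'   Hamilton product `q1 * q2`; [quat_conj()] the conjugate (inverse for unit
#'   quaternions).
#' @export
quat_from_matrix <- function(R) {
  assert_rotation(R)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' @rdname quat_from_matrix
#' @export
quat_to_matrix <- function(q) {
  stopifnot(length(q) == 4)
  q <- q / sqrt(sum(q^2))
  s <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + s * z), 2 * (x * z - s * y),
           2 * (x * y - s * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + s * x),
           2 * (x * z + s * y), 2 * (y * z - s * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' @rdname quat_from_matrix
#' @export
quat_mul <- function(q1, q2) {
  s1 <- q1[1]; v1 <- q1[2:4]
  s2 <- q2[1]; v2 <- q2[2:4]
  c(s1 * s2 - sum(v1 * v2), s1 * v2 + s2 * v1 + cross3(v1, v2))
}

#' @rdname quat_from_matrix
#' @export
quat_conj <- function(q) c(q[1], -q[2:4])

#' Uniformly random rotations
#'
#' Samples rotations uniformly on SO(3) by normalizing 4-dimensional Gaussian
#' draws to unit quaternions. Uses R's global RNG stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param n number of rotations.
#' @return a single 3x3 matrix if `n == 1`, otherwise a list of matrices.
#' @export
random_rotations <- function(n = 1) {
  out <- lapply(seq_len(n), function(i) {
    q <- rnorm(4)
    quat_to_matrix(q / sqrt(sum(q^2)))
  })
  if (n == 1) out[[1]] else out
}

## ---- angular distances ------------------------------------------------------

#' Geodesic distance between two rotations, in degrees
#'
#' The geodesic (angular) distance is the rotation angle of the relative
#' rotation \eqn{R'' = R_{pred}^{-1} R_{gt}}, computed as
#' \eqn{\arccos((\mathrm{tr}(R'') - 1)/2)}. The trace argument is clamped to
#' \eqn{[-1, 1]} to guard against floating-point drift near 0 and 180
#' degrees. The distance is symmetric in its arguments and left-invariant:
#' rotating both poses by a common rotation leaves it unchanged.
#'
#' @param R_pred,R_gt 3x3 rotation matrices.
#' @return angle in degrees, in `[0, 180]`.
#' @export
geodesic_error_deg <- function(R_pred, R_gt) {
  rel <- crossprod(R_pred, R_gt) # t(R_pred) %*% R_gt
  tr <- rel[1, 1] + rel[2, 2] + rel[3, 3]
  acos(max(-1, min(1, (tr - 1) / 2))) * .DEG
}

#' Angular distance between two unit quaternions, in degrees
#'
#' Computes the relative quaternion \eqn{(s, v) = q_1^{-1} q_2} and returns
#' \eqn{2 \arccos(|s|)}. The absolute value absorbs the quaternion sign
#' ambiguity (`q` and `-q` are the same rotation), keeping the angle in
#' `[0, 180]` degrees. Agrees with [geodesic_error_deg()] on the
#' corresponding matrices.
#'
#' @param q1,q2 unit quaternions, scalar-first `(s, x, y, z)`.
#' @return angle in degrees, in `[0, 180]`.
#' @export
quaternion_angle_deg <- function(q1, q2) {
  rel <- quat_mul(quat_conj(q1), q2)
  s <- abs(rel[1]) / sqrt(sum(rel^2))
  2 * acos(min(1, s)) * .DEG
}

#' Euclidean translation error in millimetres
#'
#' Plane translations live in the normalized `[-1, 1]` brain frame; to report
#' errors in physical units the difference is scaled by the millimetres
#' spanned by one normalized unit. `mm_per_unit` may be a scalar (isotropic
#' normalized frame) or a length-3 vector for per-axis scales, in which case
#' the difference is scaled component-wise before taking the norm.
#'
#' @param t_pred,t_gt length-3 translations in normalized units.
#' @param mm_per_unit positive scalar or length-3 vector, mm per normalized
#'   unit.
#' @return non-negative error in mm.
#' @export
translation_error <- function(t_pred, t_gt, mm_per_unit = 1) {
  stopifnot(length(t_pred) == 3, length(t_gt) == 3,
            length(mm_per_unit) %in% c(1L, 3L))
  if (any(mm_per_unit <= 0)) stop("mm_per_unit must be positive", call. = FALSE)
  d <- (t_pred - t_gt) * mm_per_unit
  sqrt(sum(d^2))
}

## ---- rotation averaging and spread statistics -------------------------------

#' Chordal L2 mean of a set of rotations
#'
#' The chordal L2 average is the rotation minimizing the summed squared
#' Frobenius distances \eqn{\sum_i \|R_c - R_i\|_F^2}. It is obtained by
#' projecting the arithmetic mean of the input matrices onto SO(3) via polar
#' decomposition (SVD); if the projection of the mean would have determinant
#' -1, the sign of the smallest singular direction is flipped (the standard
#' Kabsch correction) to return a proper rotation.
#'
#' @param rotations non-empty list of 3x3 rotation matrices.
#' @return the average rotation (3x3 matrix).
#' @section Degenerate configurations:
#' If the arithmetic mean is (numerically) singular — e.g. antipodal inputs
#' such as the identity and a 180-degree rotation — the chordal mean is not
#' unique and an error is raised.
#' @export
chordal_mean <- function(rotations) {
  if (!is.list(rotations) || length(rotations) == 0) {
    stop("'rotations' must be a non-empty list of rotation matrices", call. = FALSE)
  }
  M <- Reduce(`+`, rotations) / length(rotations)
  sv <- svd(M)
  if (min(sv$d) < 1e-8) {
    stop("degenerate rotation configuration: arithmetic mean is singular, chordal mean not unique",
         call. = FALSE)
  }
  s <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
}

#' Centroid of a set of translations
#'
#' Component-wise arithmetic mean of plane translations (normalized units).
#'
#' @param points non-empty list of length-3 numeric vectors, or an n x 3
#'   matrix with one point per row.
#' @return length-3 numeric vector.
#' @export
translation_centroid <- function(points) {
  pts <- as_point_matrix(points)
  colMeans(pts)
}

#' RMS spread of translations about their centroid
#'
#' Computes the Euclidean distance from each translation to the centroid and
#' returns the root mean square of those distances, scaled to millimetres.
#' This is the translation half of the annotation-variance statistic used to
#' quantify how consistently a standard plane is annotated across volumes.
#'
#' @inheritParams translation_centroid
#' @inheritParams translation_error
#' @return RMS distance in mm (0 iff all points coincide).
#' @export
rms_translation_spread <- function(points, mm_per_unit = 1) {
  pts <- as_point_matrix(points)
  ctr <- colMeans(pts)
  d2 <- vapply(seq_len(nrow(pts)), function(i) {
    translation_error(pts[i, ], ctr, mm_per_unit)^2
  }, numeric(1))
  sqrt(mean(d2))
}

#' RMS spread of rotations about their chordal mean
#'
#' Computes the chordal L2 mean of the rotations, the geodesic angle of each
#' rotation's residual with respect to that mean, and returns the root mean
#' square of those angles in degrees. Together with
#' [rms_translation_spread()] this summarizes the pose variance of a set of
#' standard-plane annotations.
#'
#' @inheritParams chordal_mean
#' @return RMS residual angle in degrees (0 iff all rotations are equal).
#' @export
rms_rotation_spread <- function(rotations) {
  Rc <- chordal_mean(rotations)
  ang <- vapply(rotations, function(R) geodesic_error_deg(R, Rc), numeric(1))
  sqrt(mean(ang^2))
}

as_point_matrix <- function(points) {
  if (is.list(points)) {
    if (length(points) == 0) stop("empty point set", call. = FALSE)
    points <- do.call(rbind, lapply(points, function(p) {
      stopifnot(length(p) == 3)
      as.numeric(p)
    }))
  }
  if (!is.matrix(points) || ncol(points) != 3 || nrow(points) == 0) {
    stop("points must be a non-empty list of length-3 vectors or an n x 3 matrix",
         call. = FALSE)
  }
  points
}

## ---- poses ------------------------------------------------------------------

#' Construct a 6D plane pose
#'
#' A pose couples a translation in the normalized `[-1, 1]` brain frame with
#' a proper rotation. The plane through a pose is spanned by the first two
#' rotation columns (image x -> columns, image y -> rows) with the third
#' column as plane normal.
#'
#' @param translation length-3 numeric, normalized units.
#' @param rotation 3x3 rotation matrix.
#' @return an object of class `pose6d` (a list with `translation` and
#'   `rotation`).
#' @export
pose6d <- function(translation = c(0, 0, 0), rotation = diag(3)) {
  stopifnot(length(translation) == 3, all(is.finite(translation)))
  assert_rotation(rotation)
  structure(list(translation = as.numeric(translation), rotation = rotation),
            class = "pose6d")
}

#' @export
print.pose6d <- function(x, ...) {
  cat("<pose6d> t = (", paste(sprintf("%.4f", x$translation), collapse = ", "),
      "), euler zyx deg = (",
      paste(sprintf("%.2f", matrix_to_euler_deg(x$rotation)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
format.pose6d <- function(x, ...) {
  sprintf("pose6d(t=%s)", paste(sprintf("%.3f", x$translation), collapse = ","))
}

#' Read and write pose files
#'
#' Poses are interchanged as a JSON array of objects with a `translation`
#' field (length-3, normalized units) and either a `rotation_matrix` (3x3,
#' row-major nested arrays) or a `rotation_quaternion` (scalar-first
#' `[s, x, y, z]`). Writing always emits `rotation_matrix`.
#'
#' @param poses list of [pose6d()] objects.
#' @param path file path.
#' @return [read_poses()]: list of `pose6d`; [write_poses()]: `path`,
#'   invisibly.
#' @export
write_poses <- function(poses, path) {
  if (inherits(poses, "pose6d")) poses <- list(poses)
  recs <- lapply(poses, function(p) {
    list(translation = p$translation,
         rotation_matrix = apply(p$rotation, 1, function(r) r, simplify = FALSE))
  })
  jsonlite::write_json(recs, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_poses
#' @export
read_poses <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(rec) {
    tr <- as.numeric(unlist(rec$translation))
    if (!is.null(rec$rotation_matrix)) {
      R <- do.call(rbind, lapply(rec$rotation_matrix, function(r) as.numeric(unlist(r))))
    } else if (!is.null(rec$rotation_quaternion)) {
      R <- quat_to_matrix(as.numeric(unlist(rec$rotation_quaternion)))
    } else {
      stop("pose record has neither 'rotation_matrix' nor 'rotation_quaternion'",
           call. = FALSE)
    }
    pose6d(tr, R)
  })
}
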