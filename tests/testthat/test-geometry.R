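# Rotation mathematics: 6D representation, angular metrics, averaging, and
# the pose-spread statistics.

test_that("6D decoding handles orthonormal, scaled and oblique inputs", {
  expect_equal(rot6d_to_matrix(c(1, 0, 0, 0, 1, 0)), diag(3))
  # normalization removes scaling
  expect_equal(rot6d_to_matrix(c(2, 0, 0, 0, 3, 0)), diag(3))
  # Gram-Schmidt of b = (1,1,0) against a = (1,0,0) leaves (0,1,0)
  expect_equal(rot6d_to_matrix(c(1, 0, 0, 1, 1, 0)), diag(3))
})

test_that("6D decoding rejects degenerate representations without NaNs", {
  expect_error(rot6d_to_matrix(c(0, 0, 0, 0, 1, 0)), "zero")
  expect_error(rot6d_to_matrix(c(1, 0, 0, 2, 0, 0)), "parallel")
  expect_error(rot6d_to_matrix(c(1, 0, 0, NA, 1, 0)), "finite")
})

test_that("matrix encoding inverts the decoding", {
  expect_equal(matrix_to_rot6d(diag(3)), c(1, 0, 0, 0, 1, 0))
  # 90 degree z-rotation: columns (0,1,0) and (-1,0,0)
  expect_equal(matrix_to_rot6d(rot_z(90)), c(0, 1, 0, -1, 0, 0))
})

test_that("6D round trip is exact over uniformly sampled rotations", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    R <- random_rotations(1)
    worst <- max(worst, max(abs(rot6d_to_matrix(matrix_to_rot6d(R)) - R)))
  }
  expect_lt(worst, 1e-6)
})

test_that("rot6d_backward matches numerical differentiation", {
  set.seed(3)
  for (k in 1:10) {
    r <- rnorm(6)
    G <- matrix(rnorm(9), 3, 3)
    f <- function(r) sum(G * rot6d_to_matrix(r))
    num <- vapply(1:6, function(i) {
      h <- 1e-6
      rp <- r; rp[i] <- rp[i] + h
      rm <- r; rm[i] <- rm[i] - h
      (f(rp) - f(rm)) / (2 * h)
    }, numeric(1))
    expect_equal(rot6d_backward(r, G), num, tolerance = 1e-5)
  }
})

test_that("geodesic error spans [0, 180] with exact landmarks", {
  R <- random_rotations(1)
  expect_equal(geodesic_error_deg(R, R), 0)
  expect_equal(geodesic_error_deg(diag(3), rot_z(180)), 180)
  expect_equal(geodesic_error_deg(diag(3), rot_axis_angle(c(1, 2, -1), 90)), 90)
  # symmetry
  A <- random_rotations(1); B <- random_rotations(1)
  expect_equal(geodesic_error_deg(A, B), geodesic_error_deg(B, A))
})

test_that("quaternion and matrix angular metrics agree on 1000 random pairs", {
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    R1 <- random_rotations(1); R2 <- random_rotations(1)
    d1 <- geodesic_error_deg(R1, R2)
    d2 <- quaternion_angle_deg(quat_from_matrix(R1), quat_from_matrix(R2))
    worst <- max(worst, abs(d1 - d2))
  }
  expect_lt(worst, 1e-6)
})

test_that("quaternion sign ambiguity is absorbed", {
  set.seed(8)
  q <- quat_from_matrix(random_rotations(1))
  expect_equal(quaternion_angle_deg(q, q), 0)
  expect_equal(quaternion_angle_deg(q, -q), 0)
})

test_that("quaternion conversions round trip", {
  set.seed(9)
  for (i in 1:50) {
    R <- random_rotations(1)
    expect_equal(quat_to_matrix(quat_from_matrix(R)), R, tolerance = 1e-9)
  }
})

test_that("geodesic distance is left-invariant", {
  set.seed(10)
  for (i in 1:50) {
    Q <- random_rotations(1); R1 <- random_rotations(1); R2 <- random_rotations(1)
    expect_equal(geodesic_error_deg(Q %*% R1, Q %*% R2),
                 geodesic_error_deg(R1, R2), tolerance = 1e-9)
  }
})

test_that("translation error scales by mm_per_unit", {
  expect_equal(translation_error(c(1, 2, 3), c(1, 2, 3), 50), 0)
  expect_equal(translation_error(c(0.1, 0, 0), c(0, 0, 0), 50), 5)
  expect_equal(translation_error(c(0.03, 0.04, 0), c(0, 0, 0), 100), 5)
  # per-axis scales applied component-wise
  expect_equal(translation_error(c(0.1, 0.1, 0), c(0, 0, 0), c(30, 40, 99)), 5)
  expect_error(translation_error(c(0, 0, 0), c(0, 0, 0), -1), "positive")
})

test_that("chordal mean recovers exact single-axis averages", {
  R <- random_rotations(1)
  expect_equal(chordal_mean(list(R, R, R)), R)
  expect_equal(chordal_mean(list(rot_z(20), rot_z(-20))), diag(3))
  expect_equal(chordal_mean(list(rot_z(10), rot_z(20), rot_z(30))), rot_z(20),
               tolerance = 1e-9)
})

test_that("chordal mean rejects antipodal (singular) configurations", {
  expect_error(chordal_mean(list(diag(3), rot_z(180))), "degenerate")
  expect_error(chordal_mean(list()), "non-empty")
})

test_that("chordal mean is left-equivariant", {
  set.seed(11)
  Rs <- random_rotations(5)
  Q <- random_rotations(1)
  expect_equal(chordal_mean(lapply(Rs, function(R) Q %*% R)),
               Q %*% chordal_mean(Rs), tolerance = 1e-9)
})

test_that("translation centroid equals independent summation", {
  expect_equal(translation_centroid(list(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(translation_centroid(list(c(3, -1, 2))), c(3, -1, 2))
  set.seed(12)
  pts <- lapply(1:6, function(i) rnorm(3))
  manual <- Reduce(`+`, pts) / 6
  expect_equal(translation_centroid(pts), manual)
})

test_that("RMS translation spread matches a brute-force two-pass oracle", {
  expect_equal(rms_translation_spread(list(c(1, 1, 1), c(1, 1, 1))), 0)
  expect_equal(rms_translation_spread(list(c(-1, 0, 0), c(1, 0, 0)), 1), 1)
  set.seed(13)
  pts <- lapply(1:6, function(i) rnorm(3))
  ctr <- Reduce(`+`, pts) / 6
  d2 <- vapply(pts, function(p) sum((p - ctr)^2), numeric(1))
  expect_equal(rms_translation_spread(pts, 2.5), 2.5 * sqrt(mean(d2)))
})

test_that("RMS rotation spread matches a brute-force oracle", {
  R <- random_rotations(1)
  expect_equal(rms_rotation_spread(list(R, R, R)), 0)
  expect_equal(rms_rotation_spread(list(rot_z(10), rot_z(-10))), 10)
  set.seed(14)
  Rs <- lapply(1:6, function(i) {
    rot_axis_angle(rnorm(3), runif(1, 0, 40)) # cluster, keep mean well-defined
  })
  Rc <- chordal_mean(Rs)
  ang <- vapply(Rs, function(Ri) {
    quaternion_angle_deg(quat_from_matrix(Ri), quat_from_matrix(Rc))
  }, numeric(1))
  expect_equal(rms_rotation_spread(Rs), sqrt(mean(ang^2)), tolerance = 1e-9)
})

test_that("spread statistics are invariant under a common rigid transform", {
  set.seed(15)
  pts <- lapply(1:5, function(i) rnorm(3) * 0.3)
  Rs <- lapply(1:5, function(i) rot_axis_angle(rnorm(3), runif(1, 0, 30)))
  Q <- random_rotations(1); shift <- rnorm(3)
  pts2 <- lapply(pts, function(p) as.numeric(Q %*% p) + shift)
  Rs2 <- lapply(Rs, function(R) Q %*% R)
  expect_equal(rms_translation_spread(pts2), rms_translation_spread(pts),
               tolerance = 1e-9)
  expect_equal(rms_rotation_spread(Rs2), rms_rotation_spread(Rs),
               tolerance = 1e-9)
})

test_that("Euler helpers round trip and rotation constructors compose", {
  set.seed(16)
  for (i in 1:20) {
    R <- random_rotations(1)
    expect_equal(euler_deg_to_matrix(matrix_to_euler_deg(R)), R,
                 tolerance = 1e-9)
  }
  expect_equal(rot_axis_angle(c(0, 0, 2), 30), rot_z(30))
})

test_that("pose JSON files round trip through both rotation encodings", {
  set.seed(17)
  poses <- lapply(1:3, function(i) pose6d(runif(3, -1, 1), random_rotations(1)))
  f <- withr::local_tempfile(fileext = ".json")
  write_poses(poses, f)
  back <- read_poses(f)
  for (i in 1:3) {
    expect_equal(back[[i]]$translation, poses[[i]]$translation)
    expect_equal(back[[i]]$rotation, poses[[i]]$rotation)
  }
  # quaternion-encoded input
  q <- quat_from_matrix(poses[[1]]$rotation)
  jsonlite::write_json(list(list(translation = poses[[1]]$translation,
                                 rotation_quaternion = q)),
                       f, digits = NA, auto_unbox = FALSE)
  back <- read_poses(f)
  expect_equal(back[[1]]$rotation, poses[[1]]$rotation, tolerance = 1e-9)
})
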