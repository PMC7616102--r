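# Fiducial similarity registration and its quality metrics.

random_fiducials <- function(n = 6, center = c(0, 0, 0), radius = 10) {
  data.frame(label = paste0("f", seq_len(n)),
             x_mm = center[1] + runif(n, -radius, radius),
             y_mm = center[2] + runif(n, -radius, radius),
             z_mm = center[3] + runif(n, -radius, radius))
}

apply_tf <- function(fid, tf) {
  pts <- transform_points(tf, as.matrix(fid[, c("x_mm", "y_mm", "z_mm")]))
  data.frame(label = fid$label, x_mm = pts[, 1], y_mm = pts[, 2],
             z_mm = pts[, 3])
}

test_that("fitting identical point sets yields the identity transform", {
  set.seed(60)
  fid <- random_fiducials()
  tf <- fit_similarity(fid, fid)
  expect_equal(tf$scale, 1, tolerance = 1e-12)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf$translation_mm, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(attr(tf, "rms_mm"), 0, tolerance = 1e-9)
})

test_that("a noiseless 7-DOF transform is recovered to machine precision", {
  set.seed(61)
  fid <- random_fiducials(5)
  truth <- similarity_transform(2, rot_z(30), c(5, 0, 0))
  moved <- apply_tf(fid, truth)
  tf <- fit_similarity(fid, moved)
  expect_equal(tf$scale, 2, tolerance = 1e-9)
  expect_lt(geodesic_error_deg(tf$rotation, rot_z(30)), 1e-6)
  expect_equal(tf$translation_mm, c(5, 0, 0), tolerance = 1e-6)
  expect_lt(attr(tf, "rms_mm"), 1e-9)
})

test_that("recovery error shrinks monotonically as fiducial noise vanishes", {
  set.seed(62)
  fid <- random_fiducials(8)
  truth <- similarity_transform(1.3, rot_axis_angle(c(1, 1, 0), 20), c(2, -3, 1))
  moved <- apply_tf(fid, truth)
  errs <- vapply(c(1, 0.1, 0.01, 0.001), function(sigma) {
    mean(vapply(1:20, function(rep) {
      noisy <- moved
      noisy[, 2:4] <- noisy[, 2:4] + matrix(rnorm(24, sd = sigma), ncol = 3)
      tf <- fit_similarity(fid, noisy)
      geodesic_error_deg(tf$rotation, truth$rotation)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("the fit is invariant to point order and fails on bad input", {
  set.seed(63)
  fid <- random_fiducials(6)
  truth <- similarity_transform(0.8, rot_y(40), c(0, 1, 2))
  moved <- apply_tf(fid, truth)
  shuffled <- moved[sample(6), ]
  tf1 <- fit_similarity(fid, moved)
  tf2 <- fit_similarity(fid, shuffled)
  expect_equal(tf1$rotation, tf2$rotation, tolerance = 1e-12)
  expect_equal(tf1$translation_mm, tf2$translation_mm, tolerance = 1e-12)
  # fewer than 3 points
  expect_error(fit_similarity(fid[1:2, ], moved[1:2, ]), "at least 3")
  # collinear configuration
  line <- data.frame(label = c("a", "b", "c"), x_mm = c(0, 1, 2),
                     y_mm = 0, z_mm = 0)
  expect_error(fit_similarity(line, line), "collinear")
  # mismatched labels are named
  bad <- moved
  bad$label[1] <- "rogue"
  expect_error(fiducial_rms(fid, bad), "rogue|f1")
})

test_that("fiducial RMS matches hand arithmetic and a brute-force loop", {
  fid <- data.frame(label = c("a", "b", "c", "d"),
                    x_mm = c(0, 1, 2, 3), y_mm = 0, z_mm = 0)
  off <- fid
  off$x_mm[2] <- off$x_mm[2] + 2 # one point off by 2 mm
  expect_equal(fiducial_rms(fid, fid), 0)
  expect_equal(fiducial_rms(fid, off), 1) # sqrt((4+0+0+0)/4)
  set.seed(64)
  a <- random_fiducials(7)
  b <- random_fiducials(7)
  manual <- sqrt(mean(vapply(seq_len(7), function(i) {
    sum((as.numeric(a[i, 2:4]) - as.numeric(b[i, 2:4]))^2)
  }, numeric(1))))
  expect_equal(fiducial_rms(a, b), manual)
})

test_that("masked intensity RMS matches a brute-force voxel loop", {
  v <- test_phantom()
  expect_equal(intensity_rms(v, v), 0)
  shifted <- v
  shifted$voxels <- v$voxels + 10
  expect_equal(intensity_rms(v, shifted), 10)
  set.seed(65)
  other <- v
  other$voxels <- v$voxels + array(rnorm(length(v$voxels), sd = 4),
                                   dim(v$voxels))
  manual <- sqrt(mean((v$voxels[v$mask] - other$voxels[v$mask])^2))
  expect_equal(intensity_rms(v, other), manual)
  expect_error(intensity_rms(v, other, array(FALSE, dim(v$voxels))), "empty")
})

test_that("resampling under identity and inverse transforms is faithful", {
  v <- test_phantom()
  same <- resample_volume(v, similarity_transform())
  expect_equal(same$voxels, v$voxels, tolerance = 1e-12)
  # ramp volume shifted by one voxel moves intensities by one spacing
  n <- 24
  ramp <- us_volume(array(rep(0:(n - 1), times = n * n), dim = c(n, n, n)),
                    spacing = c(1, 1, 1))
  sh <- resample_volume(ramp, similarity_transform(translation_mm = c(1, 0, 0)))
  expect_equal(sh$voxels[2:n, , ], ramp$voxels[1:(n - 1), , ], tolerance = 1e-9)
  # round trip T then T^-1 stays below an interpolation bound (noise-free
  # phantom: i.i.d. speckle is not reproducible through interpolation)
  vs <- test_phantom("smooth", grid_shape = c(48, 48, 48), ga_scale = 0.42,
                     noise_level = 0, seed = 7)
  tf <- compose_transforms(
    similarity_transform(1, diag(3), vs$center_mm),
    compose_transforms(similarity_transform(1.05, rot_z(8), c(0.4, 0, 0)),
                       similarity_transform(1, diag(3), -vs$center_mm)))
  fwd <- suppressWarnings(resample_volume(vs, tf))
  back <- suppressWarnings(resample_volume(fwd, invert_transform(tf)))
  core <- vs$mask & back$mask
  rms <- sqrt(mean((back$voxels[core] - vs$voxels[core])^2))
  # 0-255 scale; skull-shell and falx edges dominate the residual (~23),
  # while a misregistered pair scores 60-80
  expect_lt(rms, 30)
})

test_that("transform JSON files round trip", {
  tf <- similarity_transform(1.7, rot_axis_angle(c(1, 0, 2), 33), c(-2, 0.5, 9))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(tf, f)
  back <- read_transform(f)
  expect_equal(back$scale, tf$scale)
  expect_equal(back$rotation, tf$rotation, tolerance = 1e-12)
  expect_equal(back$translation_mm, tf$translation_mm)
})

test_that("compose and invert obey the group laws", {
  set.seed(66)
  a <- similarity_transform(1.2, random_rotations(1), rnorm(3))
  b <- similarity_transform(0.7, random_rotations(1), rnorm(3))
  pts <- matrix(rnorm(9), 3, 3)
  expect_equal(transform_points(compose_transforms(a, b), pts),
               transform_points(a, transform_points(b, pts)),
               tolerance = 1e-12)
  ab_inv <- compose_transforms(invert_transform(a), a)
  expect_equal(ab_inv$scale, 1, tolerance = 1e-12)
  expect_equal(ab_inv$rotation, diag(3), tolerance = 1e-12)
  expect_equal(ab_inv$translation_mm, c(0, 0, 0), tolerance = 1e-12)
})

test_that("full volume registration improves both quality metrics", {
  v <- test_phantom()
  tf <- compose_transforms(
    similarity_transform(1, diag(3), v$center_mm),
    compose_transforms(similarity_transform(1.08, rot_z(9) %*% rot_x(-5),
                                            c(1, -0.7, 0.4)),
                       similarity_transform(1, diag(3), -v$center_mm)))
  moving <- perturb_phantom(v, tf)
  reg <- register_volumes(moving, v)
  expect_lt(reg$report[["fiducial_rms_post"]], 1e-6)
  expect_lt(reg$report[["fiducial_rms_post"]], reg$report[["fiducial_rms_pre"]])
  expect_lt(reg$report[["intensity_rms_post"]], reg$report[["intensity_rms_pre"]])
})
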