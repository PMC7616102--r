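# Shared fixtures. Phantoms are cached per session: building one is cheap but
# several test files reuse the same geometry.

.fixture_env <- new.env(parent = emptyenv())

test_phantom <- function(key = "default", ...) {
  if (is.null(.fixture_env[[key]])) {
    args <- list(...)
    if (key == "default" && length(args) == 0) {
      args <- list(grid_shape = c(48, 48, 48), ga_scale = 0.42, seed = 7L)
    }
    .fixture_env[[key]] <- make_phantom(do.call(phantom_spec, args))
  }
  .fixture_env[[key]]
}

# independent uniform rotation sampler used as an oracle (quaternion-free
# path: QR decomposition of a Gaussian matrix with sign fix)
oracle_random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}
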