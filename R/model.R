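## The plane pose regressor: a convolutional backbone ending in a single
## linear head that outputs 9 parameters (3 translation + 6 rotation). The
## 6 rotation parameters are decoded to a proper rotation matrix inside the
## forward pass via the Gram-Schmidt construction, so predicted rotations are
## valid by construction and the loss can compare full rotation matrices.

#' Training configuration for the pose regressor
#'
#' Defaults mirror standard practice for this task: Adam with learning rate
#' 1e-4 and betas (0.9, 0.999), batch size 64, 50 epochs, a 20% validation
#' split with best-on-validation checkpointing.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param adam_betas length-2, Adam exponential decay rates.
#' @param val_fraction fraction of the training set held out for validation
#'   (strictly between 0 and 1).
#' @param augment logical; apply brightness/contrast jitter
#'   ([augment_image()]) to training batches on the fly.
#' @param backbone `"small"` (4 strided conv blocks, for desk-scale runs) or
#'   `"resnet18"` (an 18-weight-layer residual CNN with projection
#'   shortcuts).
#' @param rot_weight weight of the rotation-matrix MSE term in the loss
#'   (translation term has weight 1). The default 0.5 balances the gradient
#'   magnitudes of the two terms: rotation-matrix entries are O(1) while
#'   normalized translations are typically well inside the unit cube, so an
#'   unweighted sum lets the rotation term dominate early training.
#' @param seed seed controlling initialization, the validation split and
#'   shuffling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 64L, learning_rate = 1e-4,
                         adam_betas = c(0.9, 0.999), val_fraction = 0.2,
                         augment = FALSE, backbone = "small", rot_weight = 0.5,
                         seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            length(adam_betas) == 2, val_fraction > 0, val_fraction < 1,
            rot_weight >= 0)
  if (!backbone %in% c("small", "resnet18")) {
    stop("unknown backbone '", backbone, "'; use \"small\" or \"resnet18\"",
         call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, adam_betas = adam_betas,
                 val_fraction = val_fraction, augment = isTRUE(augment),
                 backbone = backbone, rot_weight = rot_weight,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Read a training configuration from YAML
#'
#' @param path YAML file; keys mirror [train_config()] arguments.
#' @return a `train_config`.
#' @export
read_train_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(train_config))
  do.call(train_config, x[intersect(names(x), known)])
}

backbone_layers <- function(backbone, input_px) {
  if (backbone == "small") {
    px <- input_px
    for (i in 1:4) px <- conv_out_px(px, 3L, 2L, 1L)
    if (px < 1) stop("input size too small for the 'small' backbone", call. = FALSE)
    ch <- c(1L, 16L, 32L, 64L, 64L)
    layers <- list()
    for (i in 1:4) {
      layers <- c(layers, list(nn_conv(ch[i], ch[i + 1], 3L, 2L, 1L),
                               nn_bnorm(ch[i + 1]), nn_relu()))
    }
    c(layers, list(nn_flatten(), nn_linear(px * px * 64L, 9L)))
  } else { # resnet18: stem conv + 8 residual blocks (2 convs each) + head
    px <- conv_out_px(input_px, 3L, 2L, 1L)
    plan <- list(c(8L, 8L, 1L), c(8L, 8L, 1L), c(8L, 16L, 2L), c(16L, 16L, 1L),
                 c(16L, 32L, 2L), c(32L, 32L, 1L), c(32L, 64L, 2L), c(64L, 64L, 1L))
    layers <- list(nn_conv(1L, 8L, 3L, 2L, 1L), nn_bnorm(8L), nn_relu())
    for (b in plan) {
      layers <- c(layers, list(nn_resblock(b[1], b[2], b[3])))
      if (b[3] == 2L) px <- conv_out_px(px, 3L, 2L, 1L)
    }
    if (px < 1) stop("input size too small for the 'resnet18' backbone", call. = FALSE)
    c(layers, list(nn_flatten(), nn_linear(px * px * 64L, 9L)))
  }
}

#' Build a pose-regression model
#'
#' The model maps a single-channel `input_px` x `input_px` image in `[0, 1]`
#' to a 9-parameter pose vector: 3 translation components (normalized units)
#' followed by the 6D rotation encoding. Weights are He-initialized from
#' `config$seed`.
#'
#' @param config a [train_config()].
#' @param input_px input image side in pixels (default 128).
#' @return an object of class `pose_regressor`.
#' @export
build_model <- function(config = train_config(), input_px = 128L) {
  layers <- backbone_layers(config$backbone, as.integer(input_px))
  params <- with_seed(config$seed, nn_init_params(layers))
  # start the head at the identity pose: a zero 6D vector is the singular
  # point of the Gram-Schmidt decode (and the unconditional MSE optimum for
  # widely spread rotation targets), so biasing the rotation part to the
  # identity encoding keeps the decode well-conditioned from the first step
  head <- length(params)
  params[[head]]$b <- c(0, 0, 0, 1, 0, 0, 0, 1, 0)
  params[[head]]$W <- params[[head]]$W * 0.1
  structure(list(layers = layers, params = params, stats = nn_init_stats(layers),
                 config = config, input_px = as.integer(input_px)),
            class = "pose_regressor")
}

#' @export
print.pose_regressor <- function(x, ...) {
  n_par <- sum(unlist(lapply(x$params, function(p) sum(lengths(p)))))
  cat(sprintf("<pose_regressor> backbone %s, input %dx%d, %d parameters\n",
              x$config$backbone, x$input_px, x$input_px, n_par))
  invisible(x)
}

# raw forward pass: images (H, W, N) array -> 9 x N output matrix
model_forward <- function(model, images, keep_caches = FALSE,
                          training = FALSE) {
  d <- dim(images)
  if (length(d) == 2) d <- c(d, 1L)
  stopifnot(d[1] == model$input_px, d[2] == model$input_px)
  dims <- c(d[1], d[2], 1L, d[3])
  f <- nn_forward(model$layers, model$params, as.numeric(images), dims,
                  stats = model$stats, training = training)
  if (keep_caches) f else f$out
}

#' Pose regression loss
#'
#' `loss = mean_3((t - t_gt)^2) + rot_weight * mean_9((R' - R_gt)^2)`, where
#' `R'` is the rotation decoded from the 6D parameters in the forward pass.
#' Both terms average over their components (3 translation entries, 9 matrix
#' entries); the loss is zero exactly when the decoded pose matches the
#' ground truth.
#'
#' @param pred length-9 numeric: raw network output `(t1..t3, r1..r6)`.
#' @param gt a [pose6d()] ground truth.
#' @param rot_weight weight of the rotation term.
#' @return non-negative scalar.
#' @export
pose_loss <- function(pred, gt, rot_weight = 1) {
  stopifnot(length(pred) == 9)
  lt <- mean((pred[1:3] - gt$translation)^2)
  Rp <- rot6d_to_matrix(pred[4:9])
  lr <- mean((Rp - gt$rotation)^2)
  lt + rot_weight * lr
}

# batch loss + gradient wrt the 9 x N output matrix.
# t_gt: 3 x N; R_gt: list of rotation matrices.
pose_loss_batch <- function(out, t_gt, R_gt, rot_weight = 1) {
  n <- ncol(out)
  dt <- out[1:3, , drop = FALSE] - t_gt
  loss_t <- colMeans(dt^2)
  grad <- matrix(0, 9, n)
  grad[1:3, ] <- 2 * dt / (3 * n)
  loss_r <- numeric(n)
  for (i in seq_len(n)) {
    r <- out[4:9, i]
    Rp <- rot6d_to_matrix(r)
    diff <- Rp - R_gt[[i]]
    loss_r[i] <- mean(diff^2)
    grad[4:9, i] <- rot6d_backward(r, (2 * rot_weight / (9 * n)) * diff)
  }
  list(loss = mean(loss_t + rot_weight * loss_r), grad = grad)
}

#' Load a manifest's images into memory
#'
#' @param manifest a manifest data.frame (see [read_manifest()]).
#' @param dir dataset directory the manifest paths are relative to; defaults
#'   to the directory of `attr(manifest, "path")`.
#' @return a list with `images` (H x W x N array in `[0, 1]`), `poses` (list
#'   of [pose6d()]) and `tags`.
#' @export
load_dataset <- function(manifest, dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(dir)) {
    mp <- attr(manifest, "path")
    if (is.null(mp)) stop("supply 'dir': manifest has no recorded path", call. = FALSE)
    dir <- dirname(mp)
  }
  n <- nrow(manifest)
  imgs <- NULL
  for (i in seq_len(n)) {
    f <- file.path(dir, manifest$path[i])
    if (!file.exists(f)) stop("image file not found: ", f, call. = FALSE)
    im <- png::readPNG(f)
    if (length(dim(im)) == 3) im <- im[, , 1]
    if (is.null(imgs)) imgs <- array(0, c(nrow(im), ncol(im), n))
    imgs[, , i] <- im
  }
  list(images = imgs, poses = manifest_poses(manifest), tags = manifest$tag)
}

# normalize user-supplied training data to list(images, poses)
as_pose_dataset <- function(data, dir = NULL) {
  if (is.character(data) || is.data.frame(data)) {
    data <- load_dataset(data, dir)
  }
  stopifnot(is.list(data), !is.null(data$images), !is.null(data$poses))
  if (dim(data$images)[3] != length(data$poses)) {
    stop("image count and pose count differ", call. = FALSE)
  }
  if (length(data$poses) == 0) stop("empty dataset", call. = FALSE)
  data
}

#' Train the pose regressor
#'
#' Minimizes the pose loss with Adam. A `val_fraction` share of the data is
#' held out (split fixed by `config$seed`); after every epoch the validation
#' loss is evaluated and the best-so-far weights are kept, so the returned
#' model is the best-on-validation checkpoint, not necessarily the last
#' epoch. With `config$augment` the training batches receive on-the-fly
#' brightness/contrast jitter; labels are unchanged (the augmentation is
#' photometric only).
#'
#' @param model a [build_model()] result.
#' @param data a dataset: a manifest data.frame / path (images are loaded
#'   from disk) or a list with `images` (H x W x N array) and `poses` (list
#'   of [pose6d()]).
#' @param config a [train_config()]; defaults to `model$config`.
#' @param dir dataset directory when `data` is a manifest.
#' @param verbose print per-epoch losses.
#' @return the trained model, with the epoch history data.frame (columns
#'   `epoch`, `train_loss`, `val_loss`) attached as `attr(*, "history")`.
#' @export
train <- function(model, data, config = model$config, dir = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(model, "pose_regressor"))
  data <- as_pose_dataset(data, dir)
  n <- length(data$poses)
  if (n < 2) stop("need at least 2 samples to split train/validation", call. = FALSE)
  t_all <- vapply(data$poses, `[[`, numeric(3), "translation")
  R_all <- lapply(data$poses, `[[`, "rotation")

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = model$params, stats = model$stats)

  with_seed(config$seed, {
    n_val <- max(1L, round(config$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    state <- adam_init(model$params)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      tr_losses <- numeric(0)
      for (lo in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[lo:min(lo + config$batch_size - 1L, length(ord))]
        imgs <- data$images[, , idx, drop = FALSE]
        if (config$augment) {
          for (j in seq_along(idx)) imgs[, , j] <- augment_image(imgs[, , j])
        }
        f <- model_forward(model, imgs, keep_caches = TRUE, training = TRUE)
        model$stats <- f$stats
        lb <- pose_loss_batch(f$out, t_all[, idx, drop = FALSE], R_all[idx],
                              config$rot_weight)
        grads <- nn_backward(model$layers, model$params, f$caches, lb$grad)
        upd <- adam_step(model$params, grads, state, config$learning_rate,
                         config$adam_betas)
        model$params <- upd$params
        state <- upd$state
        tr_losses <- c(tr_losses, lb$loss)
      }
      val_loss <- eval_loss(model, data, val_idx, t_all, R_all, config$rot_weight)
      history[epoch, ] <- list(epoch, mean(tr_losses), val_loss)
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = model$params, stats = model$stats)
      }
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        mean(tr_losses), val_loss))
      }
    }
  })
  model$params <- best$params
  model$stats <- best$stats
  attr(model, "history") <- history
  attr(model, "best_val_loss") <- best$loss
  model
}

eval_loss <- function(model, data, idx, t_all, R_all, rot_weight,
                      chunk = 256L) {
  total <- 0
  for (lo in seq(1L, length(idx), by = chunk)) {
    sub <- idx[lo:min(lo + chunk - 1L, length(idx))]
    out <- model_forward(model, data$images[, , sub, drop = FALSE])
    lb <- pose_loss_batch(out, t_all[, sub, drop = FALSE], R_all[sub], rot_weight)
    total <- total + lb$loss * length(sub)
  }
  total / length(idx)
}

#' Predict plane poses from images
#'
#' Runs the forward pass and decodes the 9-parameter output to a pose; the
#' rotation comes out of the 6D decoding and is therefore always a valid
#' rotation matrix, with no post-hoc projection.
#'
#' @param object a trained `pose_regressor`.
#' @param images a single `input_px` x `input_px` matrix in `[0, 1]`, or an
#'   H x W x N array.
#' @param ... unused.
#' @return a [pose6d()] for a single image, else a list of poses.
#' @export
predict.pose_regressor <- function(object, images, ...) {
  single <- length(dim(images)) == 2
  out <- model_forward(object, images)
  poses <- lapply(seq_len(ncol(out)), function(i) {
    pose6d(out[1:3, i], rot6d_to_matrix(out[4:9, i]))
  })
  if (single) poses[[1]] else poses
}

#' Save and load model checkpoints
#'
#' A checkpoint stores the layer specification, weights, training
#' configuration, input size and training history.
#'
#' @param model a `pose_regressor`.
#' @param path file path (RDS).
#' @return [load_checkpoint()]: the restored `pose_regressor`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(layers = model$layers, params = model$params,
               stats = model$stats, config = model$config,
               input_px = model$input_px,
               history = attr(model, "history")), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  model <- structure(list(layers = x$layers, params = x$params,
                          stats = x$stats, config = x$config,
                          input_px = x$input_px),
                     class = "pose_regressor")
  attr(model, "history") <- x$history
  model
}
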