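## Error summaries, annotation-variance reports, and the leave-one-out
## cross-validation driver.

#' Summarize pose errors between predictions and ground truth
#'
#' Computes, per pair, the Euclidean translation error (mm) and the geodesic
#' rotation error (degrees), and summarizes each as median, mean, sd, min and
#' max. The median is the standard middle-order statistic (mean of the two
#' middle values for even n).
#'
#' @param preds,gts equal-length non-empty lists of [pose6d()].
#' @param mm_per_unit scalar or length-3 mm-per-normalized-unit scale.
#' @param tag optional fold/volume identifier carried in the summary.
#' @return an object of class `error_summary`: a list with `translation` and
#'   `rotation` (named vectors `median, mean, sd, min, max`), `n` and `tag`;
#'   the raw per-pair errors are attached as `attr(*, "errors")`.
#' @export
summarize_errors <- function(preds, gts, mm_per_unit = 1, tag = NULL) {
  if (length(preds) != length(gts)) {
    stop("prediction and ground-truth lists differ in length", call. = FALSE)
  }
  if (length(preds) == 0) stop("empty prediction list", call. = FALSE)
  te <- vapply(seq_along(preds), function(i) {
    translation_error(preds[[i]]$translation, gts[[i]]$translation, mm_per_unit)
  }, numeric(1))
  re <- vapply(seq_along(preds), function(i) {
    geodesic_error_deg(preds[[i]]$rotation, gts[[i]]$rotation)
  }, numeric(1))
  fivestat <- function(x) {
    c(median = median(x), mean = mean(x),
      sd = if (length(x) > 1) sd(x) else 0, min = min(x), max = max(x))
  }
  out <- structure(list(translation = fivestat(te), rotation = fivestat(re),
                        n = length(preds), tag = tag),
                   class = "error_summary")
  attr(out, "errors") <- data.frame(trans_mm = te, rot_deg = re)
  out
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary%s> n = %d\n",
              if (is.null(x$tag)) "" else paste0(" ", x$tag), x$n))
  df <- as.data.frame(x)
  print(format(df, digits = 4))
  invisible(x)
}

#' @export
as.data.frame.error_summary <- function(x, ...) {
  data.frame(metric = c("translation_mm", "rotation_deg"),
             rbind(x$translation, x$rotation), row.names = NULL)
}

#' Average several error summaries statistic-by-statistic
#'
#' Cross-validation averaging: each summary statistic (median, mean, sd, min,
#' max) is averaged across folds, matching the convention of reporting the
#' average of the per-fold errors rather than pooling raw samples.
#'
#' @param summaries list of `error_summary` objects.
#' @return an `error_summary` tagged `"average"` (its `n` is the total sample
#'   count; it carries no raw errors).
#' @export
average_summaries <- function(summaries) {
  stopifnot(length(summaries) > 0)
  tr <- Reduce(`+`, lapply(summaries, `[[`, "translation")) / length(summaries)
  ro <- Reduce(`+`, lapply(summaries, `[[`, "rotation")) / length(summaries)
  structure(list(translation = tr, rotation = ro,
                 n = sum(vapply(summaries, `[[`, numeric(1), "n")),
                 tag = "average"),
            class = "error_summary")
}

#' Annotation-variance report for a set of standard-plane poses
#'
#' Quantifies how consistently a standard plane is annotated across volumes:
#' the RMS distance of the plane translations to their centroid (in mm) and
#' the RMS geodesic residual of the rotations about their chordal L2 mean (in
#' degrees). These spreads double as an estimate of the ground-truth
#' uncertainty and hence a lower bound for achievable pose-regression
#' accuracy.
#'
#' @param sp_poses list of at least 2 [pose6d()] annotations (one per
#'   volume), expressed in a common normalized frame.
#' @param mm_per_unit scalar or length-3 mm-per-normalized-unit scale.
#' @return a list with `rms_translation_mm`, `rms_rotation_deg`, `centroid`
#'   (normalized units), `mean_rotation` (3x3) and `n`.
#' @export
annotation_variance_report <- function(sp_poses, mm_per_unit = 1) {
  if (length(sp_poses) < 2) stop("need at least 2 poses", call. = FALSE)
  trs <- lapply(sp_poses, `[[`, "translation")
  rots <- lapply(sp_poses, `[[`, "rotation")
  list(rms_translation_mm = rms_translation_spread(trs, mm_per_unit),
       rms_rotation_deg = rms_rotation_spread(rots),
       centroid = translation_centroid(trs),
       mean_rotation = chordal_mean(rots),
       n = length(sp_poses))
}

#' Leave-one-out cross-validation over a set of volumes
#'
#' One fold per volume: the model is trained on slice datasets generated from
#' all other volumes and tested on slices from the held-out volume. Per-fold
#' pose-error summaries are reported together with their cross-fold average
#' (statistic-wise, via [average_summaries()]) and a pooled summary
#' recomputed from the concatenated per-fold errors. The whole run is
#' reproducible from the sampling and training seeds.
#'
#' @param volumes list of >= 2 `us_volume` objects with standard-plane poses.
#' @param sampling a [sampling_config()] (per-volume slice counts etc.).
#' @param spec a [slice_spec()].
#' @param config a [train_config()].
#' @param n_test number of held-out-volume slices used for testing
#'   (default: as many as the per-volume training slices).
#' @param verbose print fold progress.
#' @return an object of class `loocv_report`: list with `folds` (per-fold
#'   `error_summary`), `average`, `pooled` and `history` (per-fold training
#'   history).
#' @export
run_loocv <- function(volumes, sampling = sampling_config(),
                      spec = slice_spec(), config = train_config(),
                      n_test = NULL, verbose = FALSE) {
  if (length(volumes) < 2) stop("LOOCV needs at least 2 volumes", call. = FALSE)
  if (any(vapply(volumes, function(v) is.null(v$sp_pose), logical(1)))) {
    stop("every volume needs a standard-plane pose", call. = FALSE)
  }
  ids <- vapply(seq_along(volumes), function(i) {
    if (is.null(volumes[[i]]$id)) paste0("vol", i) else volumes[[i]]$id
  }, character(1))
  datasets <- lapply(seq_along(volumes), function(i) {
    cfg <- sampling
    cfg$seed <- sampling$seed + i - 1L
    make_pose_dataset(volumes[[i]], cfg, spec)
  })
  if (is.null(n_test)) n_test <- sampling$n_random + sampling$n_near_sp

  folds <- vector("list", length(volumes))
  hist <- vector("list", length(volumes))
  for (i in seq_along(volumes)) {
    tr_imgs <- do.call(abind3, lapply(datasets[-i], `[[`, "images"))
    tr_poses <- do.call(c, lapply(datasets[-i], `[[`, "poses"))
    model <- build_model(config, input_px = spec$size_px)
    fit <- tryCatch(
      train(model, list(images = tr_imgs, poses = tr_poses), config),
      error = function(e) stop("LOOCV fold ", ids[i], " failed: ",
                               conditionMessage(e), call. = FALSE))
    te <- datasets[[i]]
    n_use <- min(n_test, length(te$poses))
    preds <- predict(fit, te$images[, , seq_len(n_use), drop = FALSE])
    folds[[i]] <- summarize_errors(preds, te$poses[seq_len(n_use)],
                                   mm_per_unit = volumes[[i]]$mm_per_unit,
                                   tag = ids[i])
    hist[[i]] <- attr(fit, "history")
    if (verbose) {
      message(sprintf("fold %s: median %.3f mm / %.2f deg", ids[i],
                      folds[[i]]$translation[["median"]],
                      folds[[i]]$rotation[["median"]]))
    }
  }
  pooled_err <- do.call(rbind, lapply(folds, attr, "errors"))
  fivestat <- function(x) c(median = median(x), mean = mean(x), sd = sd(x),
                            min = min(x), max = max(x))
  pooled <- structure(list(translation = fivestat(pooled_err$trans_mm),
                           rotation = fivestat(pooled_err$rot_deg),
                           n = nrow(pooled_err), tag = "pooled"),
                      class = "error_summary")
  attr(pooled, "errors") <- pooled_err
  structure(list(folds = setNames(folds, ids), average = average_summaries(folds),
                 pooled = pooled, history = setNames(hist, ids)),
            class = "loocv_report")
}

abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[3], numeric(1)))
  out <- array(0, c(d[1], d[2], n))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[3]
    out[, , at + seq_len(k)] <- a
    at <- at + k
  }
  out
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("<loocv_report> %d folds\n", length(x$folds)))
  for (s in x$folds) {
    cat(sprintf("  %s: median %.3f mm / %.2f deg (n = %d)\n", s$tag,
                s$translation[["median"]], s$rotation[["median"]], s$n))
  }
  cat(sprintf("  average: median %.3f mm / %.2f deg\n",
              x$average$translation[["median"]], x$average$rotation[["median"]]))
  invisible(x)
}

#' Write an error report as JSON and a Markdown table
#'
#' @param report an `error_summary` or `loocv_report`.
#' @param dir output directory (created if needed); writes `report.json` and
#'   `report.md`.
#' @return `dir`, invisibly.
#' @export
write_error_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- if (inherits(report, "loocv_report")) {
    c(report$folds, list(average = report$average, pooled = report$pooled))
  } else list(report)
  js <- lapply(summaries, function(s) {
    list(tag = s$tag, n = s$n, translation_mm = as.list(s$translation),
         rotation_deg = as.list(s$rotation))
  })
  jsonlite::write_json(js, file.path(dir, "report.json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  fmt <- function(s, metric, unit) {
    v <- s[[metric]]
    sprintf("| %s (%s) | %.3f | %.3f ± %.3f | %.3f | %.3f |",
            if (is.null(s$tag)) metric else paste(s$tag, metric), unit,
            v[["median"]], v[["mean"]], v[["sd"]], v[["min"]], v[["max"]])
  }
  lines <- c("| set | Median | Mean ± SD | Min | Max |",
             "|---|---|---|---|---|",
             unlist(lapply(summaries, function(s) {
               c(fmt(s, "translation", "mm"), fmt(s, "rotation", "deg"))
             })))
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
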