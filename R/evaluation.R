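#' Rasterize a wrinkle shape into a tolerance band
#'
#' Draws the polyline through the landmark points at 1-px width, then
#' dilates with a disc so the band is `expansion` pixels wide (the disc
#' diameter is the nearest odd width, `2 * floor(expansion / 2) + 1`).
#' With `mode = "radius"` the disc radius is `expansion` instead
#' (band width `2 * expansion + 1`). Points outside the image are
#' clipped with a warning.
#'
#' @param shape n x 2 wrinkle landmark matrix (>= 2 points)
#' @param expansion tolerance band parameter in pixels (>= 0; default 20)
#' @param image_shape integer `(height, width)`
#' @param mode `"width"` (default) or `"radius"`
#' @return logical matrix
#' @export
rasterize_line <- function(shape, expansion = 20, image_shape,
                           mode = c("width", "radius")) {
  mode <- match.arg(mode)
  shape <- as_landmarks(shape)
  if (nrow(shape) < 2L) stop("need at least 2 points")
  if (expansion < 0) stop("expansion must be >= 0")
  h <- image_shape[1]; w <- image_shape[2]
  dense <- resample_polyline(shape, max(2L, ceiling(4 * polyline_length(shape))))
  xs <- round(dense[, 1]); ys <- round(dense[, 2])
  keep <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
  if (!all(keep)) {
    warning("points outside the image were clipped")
    xs <- xs[keep]; ys <- ys[keep]
  }
  raster <- matrix(FALSE, h, w)
  if (length(xs)) raster[cbind(ys, xs)] <- TRUE
  size <- if (mode == "width") 2L * floor(expansion / 2) + 1L
          else 2L * round(expansion) + 1L
  if (size > 1L && any(raster)) {
    raster <- as.matrix(EBImage::dilate(
      EBImage::Image(raster * 1), EBImage::makeBrush(size, "disc"))) > 0
  }
  raster
}

#' Jaccard similarity index between two wrinkle lines
#'
#' Rasterizes both shapes with the same tolerance expansion and returns
#' `|A intersect B| / |A union B|`; 1 when both rasters are empty.
#' Symmetric in its arguments and invariant under a common in-frame
#' translation.
#'
#' @param truth,detected wrinkle landmark matrices
#' @param expansion tolerance band width in pixels (default 20)
#' @param image_shape integer `(height, width)`
#' @param ... passed to [rasterize_line()]
#' @return fraction in `[0, 1]`
#' @export
jaccard_index <- function(truth, detected, expansion = 20, image_shape, ...) {
  a <- rasterize_line(truth, expansion, image_shape, ...)
  b <- rasterize_line(detected, expansion, image_shape, ...)
  uni <- sum(a | b)
  if (uni == 0L) return(1)
  sum(a & b) / uni
}

#' Dataset-level detection accuracy
#'
#' The fraction of records whose JSI strictly exceeds 0.8 (a detection
#' with more than 80 percent overlap counts as correct; 0.8 exactly does
#' not). The per-init-mode mean and median JSI and accuracy are attached
#' as the `"summary"` attribute.
#'
#' @param records data frame with columns `jsi` and (optionally)
#'   `init_mode`
#' @param threshold correctness threshold (strict inequality)
#' @return overall accuracy fraction, with a `"summary"` attribute
#' @export
dataset_accuracy <- function(records, threshold = 0.8) {
  if (NROW(records) == 0L) stop("no evaluation records")
  jsi <- records$jsi
  acc <- mean(jsi > threshold)
  mode <- records$init_mode %||% rep("all", length(jsi))
  summary <- do.call(rbind, lapply(split(seq_along(jsi), mode), function(i)
    data.frame(init_mode = mode[i[1]], n = length(i),
               mean_jsi = mean(jsi[i]), median_jsi = median(jsi[i]),
               accuracy = mean(jsi[i] > threshold))))
  rownames(summary) <- NULL
  attr(acc, "summary") <- summary
  acc
}

#' Evaluate a trained detector on a fixture set
#'
#' Runs [detect()] on each fixture under each requested initialization
#' mode and scores the final wrinkle shape against the ground-truth
#' wrinkle landmarks with the tolerance-band Jaccard index.
#'
#' @param fixtures list of `wrinkle_fixture` (or `list(image =,
#'   landmarks =)` with 88-point landmarks)
#' @param models a trained [train_wrinkle_detector()]
#' @param config base [detector_config()]; `init_mode` is overridden
#' @param init_modes character vector of modes to evaluate
#' @param expansion JSI tolerance band width, pixels
#' @return data frame with columns `image_id`, `init_mode`, `jsi`,
#'   `correct`, `fallback`
#' @export
evaluate_fixtures <- function(fixtures, models, config = NULL,
                              init_modes = c("unique_shape", "generic_mean"),
                              expansion = 20) {
  config <- config %||% models$config
  rows <- list()
  for (mode in init_modes) {
    cfg <- config
    cfg$init_mode <- mode
    for (i in seq_along(fixtures)) {
      f <- fixtures[[i]]
      lm <- as_landmarks(f$landmarks)
      fit <- detect(f$image, lm, models, cfg)
      jsi <- jaccard_index(lm[69:88, , drop = FALSE], fit$final_shape,
                           expansion, dim(to_grayscale(f$image)))
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = sprintf("fix_%03d", i), init_mode = mode,
        jsi = jsi, correct = jsi > 0.8, fallback = fit$fallback)
    }
  }
  do.call(rbind, rows)
}

#' Write an evaluation report CSV
#'
#' Per-image rows followed by per-mode summary rows (mean/median JSI and
#' accuracy).
#'
#' @param records output of [evaluate_fixtures()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
eval_report <- function(records, path) {
  acc <- dataset_accuracy(records)
  summary <- attr(acc, "summary")
  write.csv(records, path, row.names = FALSE)
  con <- file(path, "a")
  on.exit(close(con))
  writeLines("", con)
  writeLines("init_mode,n,mean_jsi,median_jsi,accuracy", con)
  writeLines(sprintf("%s,%d,%.4f,%.4f,%.4f", summary$init_mode, summary$n,
                     summary$mean_jsi, summary$median_jsi, summary$accuracy),
             con)
  invisible(path)
}
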