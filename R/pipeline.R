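#' Detector configuration
#'
#' Thresholds and hyperparameters of the end-to-end wrinkle detector.
#' `llt` (line length threshold, 100 px) and `lat` (line angle
#' threshold, pi radians of total absolute turning) discard short and
#' distorted ridge lines; `lambda_sparse = 1e-6` regularizes the sparse
#' projection of the initial shape onto the training wrinkle structures.
#'
#' @param llt minimum arc length in pixels (> 0)
#' @param lat maximum total absolute turning in radians, in (0, 2*pi]
#' @param n_wrinkle_points number of wrinkle landmarks (>= 2)
#' @param hessian_sigma ridge-detection scale in pixels
#' @param multiscale take the pixel-wise maximum response over scales
#'   `c(1, 2, 4)` instead of the single scale (off by default)
#' @param lambda_sparse L1 weight of the sparse shape projection
#' @param use_sparse_projection apply the sparse projection to the
#'   ridge-derived initial shape
#' @param init_mode `"unique_shape"` (per-image Hessian initial shape) or
#'   `"generic_mean"` (global mean-shape baseline)
#' @param max_iterations AAM iteration cap
#' @param preprocess_sigma Gaussian denoising sigma before ridge detection
#' @param binarize_method threshold rule for the response map
#' @param side which cheek to analyse
#' @return object of class `detector_config`
#' @export
detector_config <- function(llt = 100, lat = pi, n_wrinkle_points = 20L,
                            hessian_sigma = 2, multiscale = FALSE,
                            lambda_sparse = 1e-6,
                            use_sparse_projection = TRUE,
                            init_mode = c("unique_shape", "generic_mean"),
                            max_iterations = 30L,
                            preprocess_sigma = 2.5,
                            binarize_method = c("otsu", "quantile", "fixed"),
                            side = c("left", "right")) {
  if (llt <= 0) stop("llt must be > 0")
  if (lat <= 0 || lat > 2 * pi) stop("lat must be in (0, 2*pi]")
  if (n_wrinkle_points < 2L) stop("n_wrinkle_points must be >= 2")
  structure(list(llt = llt, lat = lat,
                 n_wrinkle_points = as.integer(n_wrinkle_points),
                 hessian_sigma = hessian_sigma, multiscale = multiscale,
                 lambda_sparse = lambda_sparse,
                 use_sparse_projection = use_sparse_projection,
                 init_mode = match.arg(init_mode),
                 max_iterations = as.integer(max_iterations),
                 preprocess_sigma = preprocess_sigma,
                 binarize_method = match.arg(binarize_method),
                 side = match.arg(side)),
            class = "detector_config")
}

#' Filter ridge lines by length and turning
#'
#' Keeps lines with `arc_length >= llt` and `total_turning < lat`,
#' preserving input order. Short and distorted (direction-reversing)
#' lines are discarded.
#'
#' @param lines list of [ridge_polyline()]
#' @param llt line length threshold, pixels
#' @param lat line angle threshold, radians
#' @return sublist of `lines`
#' @export
filter_lines <- function(lines, llt = 100, lat = pi) {
  if (llt <= 0 || lat <= 0) stop("invalid thresholds")
  Filter(function(l) l$arc_length >= llt && l$total_turning < lat, lines)
}

point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2]) &&
        pt[1] < (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

#' Select the wrinkle line among filtered candidates
#'
#' Among candidates whose centroid lies inside the given cheek polygon,
#' returns the one maximizing `arc_length * mean_response` (a missing
#' response counts as 1).
#'
#' @param lines non-empty list of [ridge_polyline()]
#' @param face_landmarks landmark matrix resolving the cheek polygon
#' @param side `"left"` or `"right"`
#' @return a single `ridge_polyline`
#' @export
select_wrinkle_line <- function(lines, face_landmarks, side = c("left", "right")) {
  side <- match.arg(side)
  if (length(lines) == 0L)
    stop(no_candidate_error("no candidate lines"))
  region <- default_regions()[[paste0(side, "_cheek")]]
  poly <- as_landmarks(face_landmarks)[region, , drop = FALSE]
  in_region <- vapply(lines, function(l)
    point_in_polygon(colMeans(l$points), poly), logical(1))
  if (!any(in_region))
    stop(no_candidate_error("no candidate line inside the cheek region"))
  cand <- lines[in_region]
  score <- vapply(cand, function(l) {
    mr <- l$mean_response
    l$arc_length * (if (is.na(mr)) 1 else mr)
  }, numeric(1))
  cand[[which.max(score)]]
}

no_candidate_error <- function(msg) {
  structure(class = c("wrinklefind_no_candidate", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Resample a ridge line to a fixed-size wrinkle shape
#'
#' `n` points at equal arc-length spacing, endpoints included, ordered
#' nose end (smaller y) to chin end, matching the training label order.
#'
#' @param line a [ridge_polyline()] (or an n x 2 matrix)
#' @param n number of landmarks (>= 2)
#' @return n x 2 landmark matrix
#' @export
resample_to_shape <- function(line, n = 20L) {
  pts <- if (inherits(line, "ridge_polyline")) line$points else as_landmarks(line)
  if (nrow(pts) < 2L || n < 2L) stop("need >= 2 points")
  out <- resample_polyline(pts, n)
  if (out[1, 2] > out[n, 2]) out <- out[n:1, , drop = FALSE]
  out
}

# ---- training --------------------------------------------------------------

#' Train the wrinkle detector
#'
#' From training image/landmark pairs (88 points each), builds the
#' wrinkle appearance model (points 69-88), the face-frame positioning
#' model used by the generic-mean baseline and the fallback path, and
#' the Procrustes-aligned wrinkle dictionary used by the sparse
#' projection.
#'
#' @param fixtures list of `list(image =, landmarks =)`; `landmarks`
#'   must be 88 x 2 (or `wrinkle_fixture` objects)
#' @param config a [detector_config()]
#' @param ... passed to [build_appearance_model()]
#' @return object of class `wrinkle_detector`
#' @export
train_wrinkle_detector <- function(fixtures, config = detector_config(), ...) {
  pairs <- lapply(fixtures, function(f)
    list(image = to_grayscale(f$image), landmarks = as_landmarks(f$landmarks)))
  if (any(vapply(pairs, function(p) nrow(p$landmarks) != 88L, logical(1))))
    stop("training landmarks must have 88 points (68 face + 20 wrinkle)")
  wr <- lapply(pairs, function(p)
    list(image = p$image, landmarks = p$landmarks[69:88, , drop = FALSE]))
  appearance <- build_appearance_model(wr, ...)

  faces <- lapply(pairs, function(p) p$landmarks[1:68, , drop = FALSE])
  gpa_face <- procrustes_align(faces)
  # each training wrinkle mapped into the mean-face frame, then averaged
  wr_in_face <- mapply(function(p, face) {
    al <- align_similarity(face, gpa_face$mean)
    apply_similarity(p$landmarks[69:88, , drop = FALSE], al$rot, al$t)
  }, pairs, faces, SIMPLIFY = FALSE)
  mean_wrinkle_face_frame <- Reduce(`+`, wr_in_face) / length(wr_in_face)

  wshapes <- lapply(pairs, function(p) p$landmarks[69:88, , drop = FALSE])
  gpa_w <- procrustes_align(wshapes)
  W <- do.call(cbind, lapply(gpa_w$aligned, flatten_shape))

  structure(list(appearance = appearance,
                 mean_face = gpa_face$mean,
                 mean_wrinkle_face_frame = mean_wrinkle_face_frame,
                 wrinkle_gpa_mean = gpa_w$mean,
                 dictionary = W,
                 config = config,
                 n_train = length(pairs)),
            class = "wrinkle_detector")
}

#' @export
print.wrinkle_detector <- function(x, ...) {
  cat(sprintf("<wrinkle_detector> trained on %d images, %d-atom dictionary\n",
              x$n_train, ncol(x$dictionary)))
  invisible(x)
}

# Generic mean wrinkle shape positioned by the input face landmarks.
position_mean_wrinkle <- function(models, face_landmarks) {
  face <- as_landmarks(face_landmarks)[1:68, , drop = FALSE]
  al <- align_similarity(models$mean_face, face)
  apply_similarity(models$mean_wrinkle_face_frame, al$rot, al$t)
}

# Sparse projection of a wrinkle shape onto the training dictionary:
# align to the dictionary frame, solve the L1 problem, map back.
sparse_regularize_shape <- function(shape, models, lambda) {
  al <- align_similarity(shape, models$wrinkle_gpa_mean)
  vec <- flatten_shape(al$points)
  sol <- sparse_shape_projection(vec, models$dictionary, lambda)
  inv <- invert_similarity(al$rot, al$t)
  apply_similarity(unflatten_shape(sol$reconstruction), inv$rot, inv$t)
}

# Drop leading/trailing polyline points whose ridge response falls below
# frac * median on-line response: the binarization threshold is global
# and low, so the band extends past the valley ends along the decaying
# response tail; at the true endpoint the response is about half the
# interior level.
trim_line_by_response <- function(points, resp_value, frac = 0.5,
                                  smooth_win = 7L) {
  v <- resp_value[cbind(round(points[, 2]), round(points[, 1]))]
  if (length(v) > smooth_win) {
    k <- rep(1 / smooth_win, smooth_win)
    v <- as.vector(stats::filter(v, k, sides = 2))
    # running mean is NA at the ends; extend the nearest smoothed value
    first <- which(!is.na(v))[1]
    last <- tail(which(!is.na(v)), 1)
    v[seq_len(first - 1L)] <- v[first]
    v[seq(last + 1L, length.out = length(v) - last)] <- v[last]
  }
  cut <- frac * median(v)
  good <- which(v >= cut)
  if (length(good) < 2L) return(points)
  points[good[1]:good[length(good)], , drop = FALSE]
}

#' Build the per-image unique initial wrinkle shape
#'
#' Composes the ridge-detection front end: grayscale conversion, cheek
#' masking, smoothing + equalization, Hessian dark-ridge response,
#' masked binarization, skeleton line extraction, length/turning
#' filtering, in-region selection, arc-length resampling to
#' `n_wrinkle_points`, and (optionally) the sparse projection onto the
#' training wrinkle structures. On any failure the generic mean wrinkle
#' shape positioned by the face landmarks is returned instead, with
#' `attr(, "fallback") = TRUE`; this function never throws for valid
#' inputs.
#'
#' @param image grayscale or RGB image
#' @param face_landmarks at least the 68 face points (88-point sets are
#'   accepted; only indices 1-68 are used)
#' @param config a [detector_config()]
#' @param models a trained [train_wrinkle_detector()] object
#' @return n x 2 wrinkle landmark matrix with attributes `fallback`
#'   (logical) and `provenance` (`"hessian"` or `"generic_mean"`)
#' @export
build_initial_shape <- function(image, face_landmarks, config, models) {
  shape <- tryCatch({
    gray <- to_grayscale(image)
    lm <- as_landmarks(face_landmarks)
    mask <- cheek_mask(lm, paste0(config$side, "_cheek"), dim(gray))
    pre <- smooth_and_equalize(gray, config$preprocess_sigma, mask = mask)
    resp <- if (config$multiscale) {
      vals <- lapply(c(1, 2, 4), function(s)
        ridge_response(hessian_at_scale(pre, s, gamma_normalize = TRUE))$value)
      structure(list(value = pmax(vals[[1]], vals[[2]], vals[[3]]),
                     polarity = "dark_ridge"), class = "ridge_response")
    } else {
      ridge_response(hessian_at_scale(pre, config$hessian_sigma))
    }
    # threshold inside a slightly eroded mask: equalization stops at the
    # region border, whose intensity step would otherwise read as a ridge
    r <- 2L * ceiling(config$hessian_sigma) + 4L
    mask_in <- as.matrix(EBImage::erode(
      EBImage::Image(mask * 1), EBImage::makeBrush(2L * r + 1L, "disc"))) > 0
    if (!any(mask_in)) mask_in <- mask
    bin <- binarize_response(resp, mask_in, config$binarize_method)
    # close small gaps in the band before thinning
    bin <- as.matrix(EBImage::closing(EBImage::Image(bin * 1),
                                      EBImage::makeBrush(5L, "disc"))) > 0
    lines <- extract_lines(bin, prune_px = 10L)
    lines <- lapply(lines, function(l) {
      l$mean_response <- mean(resp$value[cbind(round(l$points[, 2]),
                                               round(l$points[, 1]))])
      l
    })
    lines <- filter_lines(lines, config$llt, config$lat)
    sel <- select_wrinkle_line(lines, lm, config$side)
    trimmed <- trim_line_by_response(sel$points, resp$value)
    shp <- resample_to_shape(trimmed, config$n_wrinkle_points)
    if (config$use_sparse_projection)
      shp <- sparse_regularize_shape(shp, models, config$lambda_sparse)
    attr(shp, "fallback") <- FALSE
    attr(shp, "provenance") <- "hessian"
    shp
  }, error = function(e) NULL)
  if (is.null(shape)) {
    shape <- position_mean_wrinkle(models, face_landmarks)
    attr(shape, "fallback") <- TRUE
    attr(shape, "provenance") <- "generic_mean"
  }
  shape
}

#' Detect the nasolabial wrinkle line in an image
#'
#' End-to-end detection: the initial wrinkle shape is either the
#' per-image unique Hessian-derived shape (`init_mode = "unique_shape"`)
#' or the positioned global mean shape (`init_mode = "generic_mean"`,
#' the baseline), then refined by the fixed-Jacobian AAM fit. In
#' `unique_shape` mode the generic-mean path additionally serves as a
#' safety net: if its fit explains the image texture better (smaller
#' final residual) than the fit seeded by the ridge line, its result is
#' returned (`selected_path = "generic"`). No ground truth enters this
#' choice.
#'
#' @param image grayscale or RGB image
#' @param face_landmarks the 68 face feature points (or full 88); the
#'   first-stage face localization is treated as a pluggable input
#' @param models a trained [train_wrinkle_detector()]
#' @param config a [detector_config()]; `NULL` uses the training config
#' @return an `aam_fit` result with extra fields `init_mode`,
#'   `init_shape`, `fallback`
#' @export
detect <- function(image, face_landmarks, models, config = NULL) {
  if (!inherits(models, "wrinkle_detector"))
    stop("models must be a trained wrinkle_detector")
  if (missing(face_landmarks) || is.null(face_landmarks))
    stop("face landmarks are required (no landmarker plugged in)")
  config <- config %||% models$config
  gray <- to_grayscale(image)
  model <- models$appearance
  generic_init <- position_mean_wrinkle(models, face_landmarks)
  attr(generic_init, "fallback") <- FALSE
  attr(generic_init, "provenance") <- "generic_mean"
  if (config$init_mode == "unique_shape") {
    # the unique initial shape enters the fit through its projection onto
    # the trained shape model (p = E^T (n - msh0)), which aam_fit performs
    init <- build_initial_shape(gray, face_landmarks, config, models)
    fit <- aam_fit(model, gray, init, config$max_iterations)
    selected <- "unique"
    if (!isTRUE(attr(init, "fallback"))) {
      # a ridge line that started the fit in a bad basin shows up as a
      # larger unexplained texture residual than the generic-mean path;
      # keep whichever fit explains the image better (fallback contract
      # extended to fit-stage failures; no ground truth involved)
      fit_generic <- aam_fit(model, gray, generic_init,
                             config$max_iterations)
      if (tail(fit_generic$error_trace, 1) < tail(fit$error_trace, 1)) {
        fit <- fit_generic
        init <- generic_init
        selected <- "generic"
      }
    }
  } else {
    init <- generic_init
    fit <- aam_fit(model, gray, init, config$max_iterations)
    selected <- "generic"
  }
  fit$init_mode <- config$init_mode
  fit$init_shape <- init
  fit$selected_path <- selected
  fit$fallback <- isTRUE(attr(init, "fallback"))
  fit
}
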