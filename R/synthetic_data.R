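#' Fixture generation specification
#'
#' Bundles the parameters of one synthetic skin-image fixture: a face-like
#' intensity field (bright face ellipse on a darker background) with an
#' embedded dark curvilinear valley in the cheek region standing in for
#' the nasolabial wrinkle, plus skin noise and an illumination gradient.
#' Defaults give a 420 x 420 px image whose wrinkle arc is ~115 px long,
#' so the standard line-length threshold of 100 px is meaningful.
#'
#' @param image_height,image_width image size in pixels
#' @param face_center numeric length-2, ellipse centre `(x, y)`
#' @param face_axes numeric length-2, ellipse half-axes in pixels
#' @param wrinkle_control_points 3-5 x 2 matrix of Bezier control points
#'   (pixel coordinates) defining the wrinkle centreline, nose end first;
#'   must lie strictly inside the face ellipse
#' @param wrinkle_depth valley depth in intensity units (0-1), > 0 unless
#'   deliberately generating a wrinkle-free image
#' @param wrinkle_width Gaussian cross-profile standard deviation, pixels
#' @param noise_std standard deviation of additive skin noise
#' @param illumination_gradient intensity change per pixel applied along x
#' @param seed integer seed; identical spec + seed gives bit-identical output
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(image_height = 420L, image_width = 420L,
                         face_center = c(210, 210),
                         face_axes = c(140, 180),
                         wrinkle_control_points = NULL,
                         wrinkle_depth = 0.25,
                         wrinkle_width = 3,
                         noise_std = 0.02,
                         illumination_gradient = 5e-4,
                         seed = 1L) {
  if (is.null(wrinkle_control_points)) {
    # cubic: two free interior points give the S-bends and bowing real
    # nasolabial folds show
    ctrl_rel <- rbind(c(-0.78, 0.20), c(-0.57, 0.44),
                      c(-0.47, 0.62), c(-0.44, 0.82))
    wrinkle_control_points <- cbind(
      face_center[1] + ctrl_rel[, 1] * face_axes[1],
      face_center[2] + ctrl_rel[, 2] * face_axes[2])
  }
  wrinkle_control_points <- as_landmarks(wrinkle_control_points)
  if (nrow(wrinkle_control_points) < 3L || nrow(wrinkle_control_points) > 5L)
    stop("wrinkle_control_points must have 3-5 points")
  if (wrinkle_depth < 0)
    stop("wrinkle_depth must be >= 0 (the wrinkle is darker than skin)")
  if (wrinkle_width <= 0) stop("wrinkle_width must be > 0")
  if (noise_std < 0) stop("noise_std must be >= 0")
  spec <- list(image_height = as.integer(image_height),
               image_width = as.integer(image_width),
               face_center = as.numeric(face_center),
               face_axes = as.numeric(face_axes),
               wrinkle_control_points = wrinkle_control_points,
               wrinkle_depth = wrinkle_depth,
               wrinkle_width = wrinkle_width,
               noise_std = noise_std,
               illumination_gradient = illumination_gradient,
               seed = as.integer(seed))
  class(spec) <- "fixture_spec"
  spec
}

#' Canonical 68-point face feature template
#'
#' Returns the fixed face-feature layout used by the fixture generator,
#' in normalized coordinates (unit face ellipse, y pointing down):
#' 1-17 jawline (left temple over the chin to the right temple),
#' 18-27 eyebrows, 28-31 nose bridge (31 = tip), 32-36 nose base
#' (32/36 = left/right wing), 37-48 eyes, 49-60 outer lip
#' (49/55 = left/right corner), 61-68 inner lip (61/64 = left/right
#' inner corner). The layout is a documented convention of this package;
#' it is chosen so that the standard cheek-region index lists resolve to
#' simple polygons.
#'
#' @return 68 x 2 matrix, normalized coordinates in `[-1, 1]`
#' @export
face_template <- function() {
  pts <- matrix(NA_real_, 68L, 2L)
  s <- (0:16) * pi / 16
  pts[1:17, ] <- cbind(-cos(s), sin(s))
  brow_y <- -0.55 + c(0.02, -0.02, -0.05, -0.02, 0.02)
  pts[18:22, ] <- cbind(seq(-0.62, -0.18, length.out = 5), brow_y)
  pts[23:27, ] <- cbind(seq(0.18, 0.62, length.out = 5), brow_y)
  pts[28:31, ] <- cbind(0, c(-0.30, -0.16, -0.01, 0.14))
  pts[32:36, ] <- cbind(c(-0.18, -0.09, 0, 0.09, 0.18),
                        c(0.21, 0.245, 0.26, 0.245, 0.21))
  eye <- cbind(c(-0.11, -0.05, 0.05, 0.11, 0.05, -0.05),
               c(0, -0.04, -0.04, 0, 0.04, 0.04))
  pts[37:42, ] <- sweep(eye, 2, c(-0.35, -0.35), "+")
  pts[43:48, ] <- sweep(eye, 2, c(0.35, -0.35), "+")
  th <- pi - (0:11) * pi / 6
  pts[49:60, ] <- cbind(0.36 * cos(th), 0.46 - 0.10 * sin(th))
  pts[61:68, ] <- rbind(c(-0.33, 0.46), c(-0.11, 0.425), c(0.11, 0.425),
                        c(0.33, 0.46), c(0.17, 0.50), c(0.06, 0.51),
                        c(-0.06, 0.51), c(-0.17, 0.50))
  colnames(pts) <- c("x", "y")
  pts
}

# Evaluate a Bezier curve (2-5 control points) densely at n parameter values.
bezier_points <- function(ctrl, n = 400L) {
  t <- seq(0, 1, length.out = n)
  k <- nrow(ctrl) - 1L
  out <- matrix(0, n, 2L)
  for (i in 0:k) {
    b <- choose(k, i) * t^i * (1 - t)^(k - i)
    out <- out + outer(b, ctrl[i + 1L, ])
  }
  colnames(out) <- c("x", "y")
  out
}

# Resample a polyline at m arc-length-uniform positions, endpoints included.
resample_polyline <- function(points, m) {
  points <- as_landmarks(points)
  seg <- sqrt(rowSums(diff(points)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("zero-length polyline")
  target <- seq(0, total, length.out = m)
  idx <- findInterval(target, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(points) - 1L)
  frac <- (target - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  out <- points[idx, , drop = FALSE] +
    (points[idx + 1L, , drop = FALSE] - points[idx, , drop = FALSE]) * frac
  colnames(out) <- c("x", "y")
  out
}

#' Generate one synthetic face fixture
#'
#' Renders `image = skin base + illumination gradient - wrinkle valley
#' (Gaussian cross-profile along the curve) + seeded noise`, clipped to
#' `[0, 1]`, together with the 88 ground-truth landmarks (68 template
#' face points scaled to the face ellipse plus 20 wrinkle points) and the
#' dense wrinkle centreline. The 20 wrinkle landmarks are an
#' arc-length-uniform resampling of the centreline.
#'
#' @param spec a [fixture_spec()]
#' @return object of class `wrinkle_fixture` with elements `image`
#'   (matrix in `[0,1]`), `landmarks` (88 x 2), `wrinkle_truth`
#'   (dense centreline matrix), and `spec`
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  h <- spec$image_height; w <- spec$image_width
  cx <- spec$face_center[1]; cy <- spec$face_center[2]
  ax <- spec$face_axes[1]; ay <- spec$face_axes[2]

  rel <- sweep(sweep(spec$wrinkle_control_points, 2, c(cx, cy)),
               2, c(ax, ay), "/")
  if (any(rowSums(rel^2) >= 1))
    stop("wrinkle curve exits the face ellipse")
  truth <- bezier_points(spec$wrinkle_control_points, 400L)
  rel_t <- cbind((truth[, 1] - cx) / ax, (truth[, 2] - cy) / ay)
  if (any(rowSums(rel_t^2) >= 1))
    stop("wrinkle curve exits the face ellipse")

  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  inside <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2
  # soft face boundary (~3 px) so the ellipse edge is not a hard ridge
  edge <- pmin(pmax((1 - inside) * (min(ax, ay) / 3), 0), 1)
  img <- 0.35 + 0.30 * edge
  img <- img + spec$illumination_gradient * (xs - cx)

  if (spec$wrinkle_depth > 0) {
    sdw <- spec$wrinkle_width
    pad <- ceiling(4 * sdw) + 2L
    x0 <- max(1L, floor(min(truth[, 1])) - pad)
    x1 <- min(w, ceiling(max(truth[, 1])) + pad)
    y0 <- max(1L, floor(min(truth[, 2])) - pad)
    y1 <- min(h, ceiling(max(truth[, 2])) + pad)
    gx <- rep(x0:x1, each = y1 - y0 + 1L)
    gy <- rep(y0:y1, times = x1 - x0 + 1L)
    d2 <- outer(gx, truth[, 1], "-")^2 + outer(gy, truth[, 2], "-")^2
    dmin2 <- do.call(pmin, as.data.frame(d2))
    valley <- spec$wrinkle_depth * exp(-dmin2 / (2 * sdw^2))
    sub <- img[y0:y1, x0:x1]
    sub <- sub - matrix(valley, y1 - y0 + 1L, x1 - x0 + 1L)
    img[y0:y1, x0:x1] <- sub
  }

  if (spec$noise_std > 0) {
    img <- img + with_seed(spec$seed,
                           matrix(rnorm(h * w, sd = spec$noise_std), h, w))
  }
  img <- pmin(pmax(img, 0), 1)

  face_pts <- sweep(sweep(face_template(), 2, c(ax, ay), "*"),
                    2, c(cx, cy), "+")
  wrinkle_pts <- resample_polyline(truth, 20L)
  landmarks <- rbind(face_pts, wrinkle_pts)
  colnames(landmarks) <- c("x", "y")

  structure(list(image = img, landmarks = landmarks,
                 wrinkle_truth = truth, spec = spec),
            class = "wrinkle_fixture")
}

#' @export
print.wrinkle_fixture <- function(x, ...) {
  cat(sprintf("<wrinkle_fixture> %d x %d image, %d landmarks, wrinkle arc %.1f px\n",
              nrow(x$image), ncol(x$image), nrow(x$landmarks),
              polyline_length(x$wrinkle_truth)))
  invisible(x)
}

#' Generate a dataset of synthetic fixtures
#'
#' Draws `n` fixtures with seeded randomization of the wrinkle control
#' points (+-6 px at the ends, +-12 px mid-curve, so wrinkle shape varies
#' beyond what the face frame predicts), depth (0.18-0.32), width
#' (2.5-3.5 px), face axes
#' (+-8 percent) and face centre (+-8 px) around `base_spec`. When
#' `out_dir` is given, writes `fix_###.png`, `fix_###.pts` and a
#' `manifest.csv` (image path, landmark path, split).
#'
#' @param n number of fixtures (>= 1)
#' @param base_spec a [fixture_spec()] giving the central conditions
#' @param seed integer seed driving all randomization
#' @param out_dir optional output directory
#' @param split label recorded in the manifest (e.g. "train" or "test")
#' @param depth_range,width_range uniform sampling ranges for the wrinkle
#'   valley depth (intensity) and cross-profile width (px)
#' @return list of `wrinkle_fixture` objects
#' @export
generate_dataset <- function(n, base_spec = fixture_spec(), seed = 1L,
                             out_dir = NULL, split = "train",
                             depth_range = c(0.18, 0.32),
                             width_range = c(2.5, 3.5)) {
  stopifnot(n >= 1)
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(ctrl_jit = matrix(runif(10, -1, 1), 5L, 2L),
           depth = runif(1, depth_range[1], depth_range[2]),
           width = runif(1, width_range[1], width_range[2]),
           extent = runif(1, 0.85, 1.1),
           slide = runif(1, -25, 10),
           axis_scale = runif(1, 0.92, 1.08),
           center_jit = runif(2, -8, 8),
           sub_seed = sample.int(2^30, 1))
    })
  })
  fixtures <- lapply(seq_len(n), function(i) {
    d <- draws[[i]]
    center <- base_spec$face_center + d$center_jit
    axes <- base_spec$face_axes * d$axis_scale
    base_rel <- sweep(sweep(base_spec$wrinkle_control_points, 2,
                            base_spec$face_center),
                      2, base_spec$face_axes, "/")
    ctrl <- sweep(sweep(base_rel, 2, axes, "*"), 2, center, "+")
    # folds differ in extent and in where they sit along the cheek:
    # stretch about the centroid and slide along the mean direction
    cc <- colMeans(ctrl)
    ctrl <- sweep(sweep(ctrl, 2, cc), 1, d$extent, "*")
    dirv <- ctrl[nrow(ctrl), ] - ctrl[1, ]
    dirv <- dirv / sqrt(sum(dirv^2))
    ctrl <- sweep(ctrl, 2, cc + d$slide * dirv, "+")
    # ends anchored near nose wing / mouth corner (+-6 px), body bows more
    k <- nrow(ctrl)
    jit_scale <- rep(12, k); jit_scale[c(1L, k)] <- 6
    ctrl <- ctrl + d$ctrl_jit[seq_len(k), , drop = FALSE] * jit_scale
    # deterministic inward pull keeps the curve safely inside the face
    for (guard in 1:10) {
      rel_chk <- sweep(sweep(ctrl, 2, center), 2, axes, "/")
      if (all(rowSums(rel_chk^2) < 0.94)) break
      ctrl <- sweep(sweep(ctrl, 2, center) * 0.96, 2, center, "+")
    }
    sp <- fixture_spec(image_height = base_spec$image_height,
                       image_width = base_spec$image_width,
                       face_center = center, face_axes = axes,
                       wrinkle_control_points = ctrl,
                       wrinkle_depth = d$depth, wrinkle_width = d$width,
                       noise_std = base_spec$noise_std,
                       illumination_gradient = base_spec$illumination_gradient,
                       seed = d$sub_seed)
    generate_fixture(sp)
  })
  if (!is.null(out_dir)) write_fixtures(fixtures, out_dir, split)
  fixtures
}

#' Write fixtures as PNG + PTS files with a manifest
#'
#' 8-bit PNG export rounds half-up.
#'
#' @param fixtures list of `wrinkle_fixture`
#' @param out_dir output directory (created if needed)
#' @param split split label for the manifest
#' @return path of the manifest, invisibly
#' @export
write_fixtures <- function(fixtures, out_dir, split = "train") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(fixtures), function(i) {
    stem <- sprintf("fix_%03d", i)
    img_path <- file.path(out_dir, paste0(stem, ".png"))
    pts_path <- file.path(out_dir, paste0(stem, ".pts"))
    q <- floor(fixtures[[i]]$image * 255 + 0.5) / 255
    png::writePNG(q, img_path)
    write_pts(fixtures[[i]]$landmarks, pts_path)
    data.frame(image = img_path, landmarks = pts_path, split = split,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

# Total arc length of a polyline in pixels.
polyline_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  sum(sqrt(rowSums(diff(as_landmarks(points))^2)))
}
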