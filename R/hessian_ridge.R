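#' Hessian field of an image at a given scale
#'
#' Computes the per-pixel second partial derivatives `hxx`, `hxy`, `hyy`
#' (units intensity per pixel squared) of the image by convolution with
#' derivative-of-Gaussian kernels at scale `sigma`; at small `sigma` the
#' response at a unit-width valley centreline approaches the analytic
#' second derivative. With `gamma_normalize = TRUE` the fields are
#' multiplied by `sigma^2` (scale-normalized derivatives), which makes
#' responses comparable across scales for a multi-scale maximum. The
#' off-diagonal `hxy` is shared (the 2 x 2 Hessian is symmetric).
#'
#' @param gray grayscale matrix
#' @param sigma derivative scale in pixels (> 0)
#' @param gamma_normalize multiply by `sigma^2` for cross-scale use
#' @return object of class `hessian_field` with elements `hxx`, `hxy`,
#'   `hyy`, `scale_sigma`
#' @export
hessian_at_scale <- function(gray, sigma = 2, gamma_normalize = FALSE) {
  if (sigma <= 0) stop("sigma must be > 0")
  g0 <- gaussian_kernel_1d(sigma, 0L)
  g1 <- gaussian_kernel_1d(sigma, 1L)
  g2 <- gaussian_kernel_1d(sigma, 2L)
  s2 <- if (gamma_normalize) sigma^2 else 1
  structure(list(
    hxx = s2 * convolve_separable(gray, g2, g0),
    hxy = s2 * convolve_separable(gray, g1, g1),
    hyy = s2 * convolve_separable(gray, g0, g2),
    scale_sigma = sigma), class = "hessian_field")
}

#' Per-pixel eigenvalues of a Hessian field
#'
#' Closed-form eigenvalues of the symmetric 2 x 2 matrix at every pixel:
#' `0.5 * ((hxx + hyy) +- sqrt((hxx - hyy)^2 + 4 hxy^2))`, returned with
#' `lambda1 >= lambda2` by signed value. They satisfy
#' `lambda1 + lambda2 = hxx + hyy` and
#' `lambda1 * lambda2 = hxx * hyy - hxy^2` pixel-wise.
#'
#' @param field a `hessian_field`
#' @return list with matrices `lambda1`, `lambda2`
#' @export
hessian_eigenvalues <- function(field) {
  stopifnot(inherits(field, "hessian_field"))
  tr <- field$hxx + field$hyy
  disc <- sqrt((field$hxx - field$hyy)^2 + 4 * field$hxy^2)
  list(lambda1 = 0.5 * (tr + disc), lambda2 = 0.5 * (tr - disc))
}

#' Ridge response map from a Hessian field
#'
#' A wrinkle is a thin dark valley: across it the intensity profile has
#' large positive curvature, so the dark-ridge response is the positive
#' part of the major eigenvalue, `max(lambda1, 0)`. For bright ridges the
#' response is `max(-lambda2, 0)`; inverting image intensities swaps the
#' two exactly.
#'
#' @param field a `hessian_field`
#' @param polarity `"dark_ridge"` or `"bright_ridge"`
#' @return object of class `ridge_response` with elements `value`
#'   (matrix) and `polarity`
#' @export
ridge_response <- function(field, polarity = c("dark_ridge", "bright_ridge")) {
  polarity <- match.arg(polarity)
  ev <- hessian_eigenvalues(field)
  value <- if (polarity == "dark_ridge") pmax(ev$lambda1, 0)
           else pmax(-ev$lambda2, 0)
  structure(list(value = value, polarity = polarity),
            class = "ridge_response")
}

#' Threshold a ridge response into a binary map
#'
#' The threshold is computed over masked pixels only; the output is 1
#' where `response >= threshold` and the mask is 1.
#'
#' @param resp a `ridge_response` (or a plain matrix)
#' @param mask logical/0-1 matrix of the same shape
#' @param method `"otsu"` (default), `"quantile"` or `"fixed"`
#' @param param quantile level for `"quantile"` (default 0.95) or the
#'   threshold itself for `"fixed"`
#' @return logical matrix
#' @export
binarize_response <- function(resp, mask, method = c("otsu", "quantile", "fixed"),
                              param = NULL) {
  method <- match.arg(method)
  value <- if (inherits(resp, "ridge_response")) resp$value else resp
  if (!all(dim(value) == dim(mask)))
    stop("response and mask shapes differ")
  vals <- value[mask > 0]
  if (length(vals) == 0L) stop("empty mask")
  if (all(vals == 0)) {   # flat zero response: nothing to detect
    out <- matrix(FALSE, nrow(value), ncol(value))
    attr(out, "threshold") <- Inf
    return(out)
  }
  thr <- switch(method,
    otsu = {
      rng <- range(vals)
      if (diff(rng) < .Machine$double.eps) {
        rng[2] + 1  # constant response: nothing above threshold
      } else {
        sc <- (vals - rng[1]) / diff(rng)
        t01 <- EBImage::otsu(matrix(sc, nrow = 1L), range = c(0, 1))
        rng[1] + t01 * diff(rng)
      }
    },
    quantile = quantile(vals, param %||% 0.95, names = FALSE),
    fixed = param %||% stop("method 'fixed' needs param"))
  out <- (value >= thr) & (mask > 0)
  attr(out, "threshold") <- thr
  out
}

# ---- skeletonization -------------------------------------------------------

# Shift a padded binary matrix; dy/dx in {-1,0,1}.
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Zhang-Suen skeletonization of a binary map
#'
#' Iterative morphological thinning preserving 8-connectivity, reducing
#' ridge bands to 1-px-wide centrelines.
#'
#' @param binary logical/0-1 matrix
#' @return logical matrix
#' @export
skeletonize <- function(binary) {
  m <- matrix(as.integer(binary > 0), nrow(binary), ncol(binary))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north (north = smaller y/row)
      p2 <- shift_mat(m,  1,  0); p3 <- shift_mat(m,  1, -1)
      p4 <- shift_mat(m,  0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1,  0); p7 <- shift_mat(m, -1,  1)
      p8 <- shift_mat(m,  0,  1); p9 <- shift_mat(m,  1,  1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- 0L
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      cond <- m == 1L & b >= 2L & b <= 6L & a == 1L
      if (step == 1L) {
        cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# ---- polyline extraction ---------------------------------------------------

#' Construct a ridge polyline
#'
#' Attaches arc length and total absolute turning to an ordered pixel
#' curve. The turning angle is measured on an arc-length resampled copy
#' (spacing ~8 px) because 8-connected raster steps quantize direction
#' to multiples of 45 degrees.
#'
#' @param points ordered n x 2 coordinate matrix
#' @param mean_response optional mean ridge response along the line
#' @param turning_step resampling step (px) for the turning measurement
#' @return object of class `ridge_polyline`
#' @export
ridge_polyline <- function(points, mean_response = NA_real_,
                           turning_step = 8) {
  points <- as_landmarks(points)
  len <- polyline_length(points)
  structure(list(points = points, arc_length = len,
                 total_turning = polyline_turning(points, turning_step),
                 mean_response = mean_response),
            class = "ridge_polyline")
}

#' @export
print.ridge_polyline <- function(x, ...) {
  cat(sprintf("<ridge_polyline> %d pts, length %.1f px, turning %.2f rad\n",
              nrow(x$points), x$arc_length, x$total_turning))
  invisible(x)
}

# Sum of absolute turn angles along an arc-length resampled polyline.
polyline_turning <- function(points, step = 8) {
  len <- polyline_length(points)
  if (len < 2 * step || nrow(points) < 3L) return(0)
  m <- max(3L, round(len / step) + 1L)
  rs <- resample_polyline(points, m)
  d <- diff(rs)
  ang <- atan2(d[, 2], d[, 1])
  dth <- diff(ang)
  dth <- (dth + pi) %% (2 * pi) - pi
  sum(abs(dth))
}

# Per-pixel neighbour count within a binary skeleton (8-connectivity).
skeleton_degree <- function(skel) {
  m <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  d <- matrix(0L, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    d <- d + shift_mat(m, dy, dx)
  }
  d
}

# Crossing number: how many distinct runs of set neighbours surround each
# pixel. A value >= 3 marks a true junction; staircase corners of a thin
# 8-connected line (neighbour count 3 but crossing number 2) are not.
skeleton_crossings <- function(skel) {
  m <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  p2 <- shift_mat(m,  1,  0); p3 <- shift_mat(m,  1, -1)
  p4 <- shift_mat(m,  0, -1); p5 <- shift_mat(m, -1, -1)
  p6 <- shift_mat(m, -1,  0); p7 <- shift_mat(m, -1,  1)
  p8 <- shift_mat(m,  0,  1); p9 <- shift_mat(m,  1,  1)
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  a <- matrix(0L, nrow(m), ncol(m))
  for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
  a
}

# Split a skeleton into ordered 8-connected arcs after removing branch
# points (degree >= 3). Returns a list of coordinate matrices, each with
# attributes telling whether its ends touch a removed branch point.
split_skeleton_arcs <- function(skel) {
  if (!any(skel)) return(list())
  branch <- skel & skeleton_crossings(skel) >= 3L
  body <- skel & !branch
  h <- nrow(skel)
  idx <- which(body)
  if (!length(idx)) return(list())
  ys <- ((idx - 1L) %% h) + 1L
  xs <- ((idx - 1L) %/% h) + 1L
  on <- new.env(hash = TRUE, size = length(idx))
  key <- function(x, y) paste0(x, ",", y)
  for (i in seq_along(idx)) assign(key(xs[i], ys[i]), i, envir = on)
  # orthogonal neighbours first so staircase corners are walked in order
  offs <- cbind(dx = c(0, -1, 1, 0, -1, 1, -1, 1),
                dy = c(-1, 0, 0, 1, -1, -1, 1, 1))
  nbrs <- function(i) {
    out <- integer(0)
    for (k in 1:8) {
      j <- mget(key(xs[i] + offs[k, 1], ys[i] + offs[k, 2]),
                envir = on, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  branch_nbrs <- function(i) {
    out <- character(0)
    for (k in 1:8) {
      y <- ys[i] + offs[k, 2]; x <- xs[i] + offs[k, 1]
      if (y >= 1 && y <= h && x >= 1 && x <= ncol(skel) && branch[y, x])
        out <- c(out, paste0(x, ",", y))
    }
    out
  }
  bn_cache <- lapply(seq_along(idx), branch_nbrs)
  touches_branch <- function(i) length(bn_cache[[i]]) > 0L
  # two pixels flanking the same removed branch point are only spuriously
  # diagonal-adjacent (they belong to different arms of the junction)
  edge_ok <- function(i, j) {
    if (abs(xs[i] - xs[j]) + abs(ys[i] - ys[j]) < 2L) return(TRUE)
    length(intersect(bn_cache[[i]], bn_cache[[j]])) == 0L
  }
  deg_in <- vapply(seq_along(idx), function(i)
    length(Filter(function(j) edge_ok(i, j), nbrs(i))), integer(1))
  visited <- rep(FALSE, length(idx))
  arcs <- list()
  order_start <- order(deg_in != 1L, ys, xs)
  for (s in order_start) {
    if (visited[s]) next
    path <- integer(0)
    cur <- s
    repeat {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nxt <- Filter(function(j) !visited[j] && edge_ok(cur, j), nbrs(cur))
      if (length(nxt) == 0L) break
      cur <- nxt[[1]]
    }
    pts <- cbind(x = xs[path], y = ys[path])
    attr(pts, "end_at_branch") <- c(touches_branch(path[1]),
                                    touches_branch(path[length(path)]))
    arcs[[length(arcs) + 1L]] <- pts
  }
  arcs
}

# Remove short spur arcs (dead-end side branches hanging off a junction)
# from a skeleton, then let the junction pixels rejoin the main line.
prune_skeleton <- function(skel, prune_px) {
  for (pass in 1:10) {
    arcs <- split_skeleton_arcs(skel)
    removed <- FALSE
    for (a in arcs) {
      ends <- attr(a, "end_at_branch")
      if (sum(ends) == 1L && nrow(a) < prune_px) {
        skel[cbind(a[, 2], a[, 1])] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

#' Extract ridge polylines from a binary map
#'
#' Skeletonizes the map, optionally prunes short dead-end spurs
#' (`prune_px` > 0), removes skeleton branch points (pixels with 3+
#' skeleton neighbours), and turns each remaining 8-connected arc into an
#' ordered [ridge_polyline()]. An empty map yields an empty list.
#'
#' @param binary logical/0-1 matrix
#' @param min_points arcs shorter than this many pixels are dropped
#' @param prune_px spur branches shorter than this many pixels are
#'   removed before splitting (0 = no pruning)
#' @return list of `ridge_polyline`
#' @export
extract_lines <- function(binary, min_points = 2L, prune_px = 0L) {
  skel <- skeletonize(binary)
  if (prune_px > 0L) skel <- prune_skeleton(skel, prune_px)
  arcs <- split_skeleton_arcs(skel)
  lines <- list()
  for (pts in arcs) {
    if (nrow(pts) < min_points) next
    attr(pts, "end_at_branch") <- NULL
    # canonical orientation: smaller y (nose end) first
    n <- nrow(pts)
    if (pts[1, 2] > pts[n, 2] ||
        (pts[1, 2] == pts[n, 2] && pts[1, 1] > pts[n, 1]))
      pts <- pts[n:1, , drop = FALSE]
    lines[[length(lines) + 1L]] <- ridge_polyline(pts)
  }
  lines
}
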