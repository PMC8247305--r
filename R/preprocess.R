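#' Convert an RGB or grayscale image to grayscale
#'
#' RGB input (h x w x 3 array) is reduced with the standard luminance
#' weights 0.299 R + 0.587 G + 0.114 B; grayscale input (matrix) passes
#' through unchanged.
#'
#' @param image numeric matrix or h x w x 3 array, intensities in `[0,1]`
#' @return numeric matrix
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L) {
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  }
  stop("expected a grayscale matrix or an RGB array with 3 channels")
}

# Separable Gaussian (and Gaussian-derivative) convolution with
# replicated borders, via EBImage's linear filter. Derivative kernels are
# moment-corrected so that on the discrete grid a constant maps to 0, a
# ramp to slope 1 and x^2/2 to 1 — without this, small-sigma sampled
# kernels are badly mis-scaled.
gaussian_kernel_1d <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -x / sigma^2 * g
    # convolution flips the kernel: calibrate sum(k * -x) = 1
    return(k / sum(k * -x))
  }
  if (order == 2L) {
    k <- (x^2 - sigma^2) / sigma^4 * g
    k <- k - mean(k)
    return(2 * k / sum(k * x^2))
  }
  stop("order must be 0, 1 or 2")
}

convolve_separable <- function(img, kx, ky) {
  # kernel rows follow y (image rows), columns follow x
  kern <- outer(ky, kx)
  as.matrix(EBImage::filter2(img, kern, boundary = "replicate"))
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma, 0L)
  convolve_separable(img, k, k)
}

#' Histogram equalization, optionally restricted to a mask
#'
#' Global 256-bin histogram equalization. With a mask, the mapping is
#' computed from and applied to masked pixels only; pixels outside keep
#' their input value.
#'
#' @param gray numeric matrix in `[0,1]`
#' @param mask optional logical/0-1 matrix of the same shape
#' @param levels number of histogram bins
#' @return matrix in `[0,1]`
#' @export
hist_equalize <- function(gray, mask = NULL, levels = 256L) {
  vals <- if (is.null(mask)) as.vector(gray) else gray[mask > 0]
  if (length(vals) == 0L) stop("empty mask")
  bins <- pmin(pmax(floor(vals * levels), 0), levels - 1L)
  cdf <- cumsum(tabulate(bins + 1L, nbins = levels))
  cdf0 <- cdf[which(cdf > 0)[1]]
  denom <- max(length(vals) - cdf0, 1L)
  lut <- pmin(pmax((cdf - cdf0) / denom, 0), 1)
  mapped <- lut[bins + 1L]
  if (is.null(mask)) {
    matrix(mapped, nrow(gray), ncol(gray))
  } else {
    out <- gray
    out[mask > 0] <- mapped
    out
  }
}

#' Smooth skin noise and equalize contrast
#'
#' Gaussian blur at `sigma` followed by histogram equalization, the
#' photometric normalization applied to the cheek region before ridge
#' detection. Output is in `[0,1]`.
#'
#' @param gray grayscale matrix in `[0,1]`
#' @param sigma blur standard deviation in pixels (>= 0; 0 = no blur)
#' @param mask optional mask restricting the equalization
#' @param equalize set `FALSE` to skip equalization
#' @return matrix in `[0,1]`
#' @export
smooth_and_equalize <- function(gray, sigma = 1.5, mask = NULL,
                                equalize = TRUE) {
  if (sigma < 0) stop("sigma must be >= 0")
  out <- gaussian_blur(gray, sigma)
  if (equalize) out <- hist_equalize(out, mask) else out <- pmin(pmax(out, 0), 1)
  out
}

#' Cheek region specifications
#'
#' The default masking polygons, as ordered lists of 1-based landmark
#' indices into the 88-point annotation: a coarse `cheek` bounding
#' quadrilateral and the `left_cheek` / `right_cheek` work areas
#' (index ranges written `1:7` and `15:11` are inclusive).
#'
#' @return named list of integer vectors
#' @export
default_regions <- function() {
  list(cheek = c(2L, 5L, 11L, 14L),
       left_cheek = c(1:7, 31L, 32L, 50L, 49L),
       right_cheek = c(15:11, 35L, 53L, 54L, 64L))
}

# TRUE if the closed polygon (n x 2) has no crossing non-adjacent edges.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  a <- poly
  b <- poly[c(2:n, 1L), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d2 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    d3 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d4 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Even-odd polygon rasterization over an h x w pixel grid.
fill_polygon <- function(poly, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  mask <- matrix(FALSE, h, w)
  x0 <- max(1L, floor(min(poly[, 1]))); x1 <- min(w, ceiling(max(poly[, 1])))
  y0 <- max(1L, floor(min(poly[, 2]))); y1 <- min(h, ceiling(max(poly[, 2])))
  if (x1 < x0 || y1 < y0) return(mask)
  px <- rep(x0:x1, each = y1 - y0 + 1L)
  py <- rep(y0:y1, times = x1 - x0 + 1L)
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mask[cbind(py[inside], px[inside])] <- TRUE
  mask
}

#' Binary cheek mask from landmarks
#'
#' Rasterizes the polygon spanned by the region's landmark indices
#' (1 inside, 0 elsewhere); any `exclude` regions (e.g. nose, mouth)
#' are set back to 0. A degenerate (collinear) polygon yields an empty
#' mask with a warning; a non-simple polygon warns and is filled with
#' the even-odd rule.
#'
#' @param landmarks 88 x 2 landmark matrix
#' @param region integer vector of 1-based landmark indices, or a name
#'   from [default_regions()]
#' @param image_shape integer length-2 `(height, width)`
#' @param exclude optional list of index vectors for excluded sub-polygons
#' @return logical matrix `(height x width)`
#' @export
cheek_mask <- function(landmarks, region = "left_cheek", image_shape,
                       exclude = NULL) {
  landmarks <- as_landmarks(landmarks)
  if (is.character(region)) region <- default_regions()[[region]]
  region <- as.integer(region)
  if (any(region < 1L | region > nrow(landmarks)))
    stop("region index out of range: ",
         paste(region[region < 1L | region > nrow(landmarks)], collapse = ", "))
  poly <- landmarks[region, , drop = FALSE]
  # collinearity: rank of centred points < 2
  cc <- sweep(poly, 2, colMeans(poly))
  if (qr(cc)$rank < 2L) {
    warning("degenerate (collinear) region polygon; returning empty mask")
    return(matrix(FALSE, image_shape[1], image_shape[2]))
  }
  if (!polygon_is_simple(poly))
    warning("region polygon is not simple; using even-odd fill")
  mask <- fill_polygon(poly, image_shape)
  for (ex in exclude) {
    exi <- as.integer(ex)
    mask[fill_polygon(landmarks[exi, , drop = FALSE], image_shape)] <- FALSE
  }
  mask
}
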