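# ---- texture reference frame ----------------------------------------------

# Bilinear interpolation at fractional positions; NA outside the image.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  ok <- x >= 1 & x <= w & y >= 1 & y <= h
  x0 <- pmin(pmax(floor(x), 1L), w - 1L)
  y0 <- pmin(pmax(floor(y), 1L), h - 1L)
  fx <- x - x0; fy <- y - y0
  v <- (1 - fx) * (1 - fy) * img[cbind(y0, x0)] +
       fx * (1 - fy) * img[cbind(y0, x0 + 1L)] +
       (1 - fx) * fy * img[cbind(y0 + 1L, x0)] +
       fx * fy * img[cbind(y0 + 1L, x0 + 1L)]
  v[!ok] <- NA_real_
  v
}

# Unit normals of an open polyline (central-difference tangents).
polyline_normals <- function(points) {
  n <- nrow(points)
  tangents <- rbind(points[2, ] - points[1, ],
                    points[3:n, , drop = FALSE] - points[1:(n - 2), , drop = FALSE],
                    points[n, ] - points[n - 1, ])
  len <- sqrt(rowSums(tangents^2))
  len[len < .Machine$double.eps] <- 1
  tangents <- tangents / len
  cbind(-tangents[, 2], tangents[, 1])
}

# Extend an open polyline beyond both endpoints along its end tangents;
# the sampled band then covers the valley-to-skin transition at the line
# ends, which anchors the along-curve position during fitting.
extend_polyline <- function(shape, margin) {
  if (margin <= 0) return(shape)
  n <- nrow(shape)
  d1 <- shape[1, ] - shape[2, ]
  d1 <- d1 / max(sqrt(sum(d1^2)), .Machine$double.eps)
  d2 <- shape[n, ] - shape[n - 1, ]
  d2 <- d2 / max(sqrt(sum(d2^2)), .Machine$double.eps)
  rbind(shape[1, ] + margin * d1, shape, shape[n, ] + margin * d2)
}

# Ribbon strip mesh around a shape: vertex i on side A is point i offset
# +half_width along its normal, side B is the opposite offset; triangles
# (Ai, Bi, Ai+1) and (Bi, Bi+1, Ai+1).
ribbon_mesh <- function(shape, half_width, end_margin = 0) {
  shape <- extend_polyline(shape, end_margin)
  n <- nrow(shape)
  nrm <- polyline_normals(shape)
  verts <- rbind(shape + half_width * nrm, shape - half_width * nrm)
  tri <- matrix(0L, 2L * (n - 1L), 3L)
  for (i in seq_len(n - 1L)) {
    tri[2L * i - 1L, ] <- c(i, n + i, i + 1L)
    tri[2L * i, ] <- c(n + i, n + i + 1L, i + 1L)
  }
  list(vertices = verts, triangles = tri)
}

tri_signed_areas <- function(verts, tri) {
  a <- verts[tri[, 1], , drop = FALSE]
  b <- verts[tri[, 2], , drop = FALSE]
  c <- verts[tri[, 3], , drop = FALSE]
  0.5 * ((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
         (b[, 2] - a[, 2]) * (c[, 1] - a[, 1]))
}

# Reference-frame pixel lattice: every integer pixel inside the ribbon,
# with its triangle id and barycentric coordinates (first hit wins).
reference_lattice <- function(mesh) {
  verts <- mesh$vertices; tri <- mesh$triangles
  taken_x <- numeric(0); taken_y <- numeric(0)
  tri_id <- integer(0); bary <- matrix(0, 0L, 3L)
  seen <- new.env(hash = TRUE)
  eps <- 1e-9
  for (t in seq_len(nrow(tri))) {
    a <- verts[tri[t, 1], ]; b <- verts[tri[t, 2], ]; c <- verts[tri[t, 3], ]
    xs <- floor(min(a[1], b[1], c[1])):ceiling(max(a[1], b[1], c[1]))
    ys <- floor(min(a[2], b[2], c[2])):ceiling(max(a[2], b[2], c[2]))
    px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(det) < .Machine$double.eps) next
    l2 <- ((py - a[2]) * (c[1] - a[1]) - (px - a[1]) * (c[2] - a[2])) / -det
    l3 <- ((py - a[2]) * (b[1] - a[1]) - (px - a[1]) * (b[2] - a[2])) / det
    l1 <- 1 - l2 - l3
    inside <- l1 >= -eps & l2 >= -eps & l3 >= -eps
    for (i in which(inside)) {
      key <- paste0(px[i], ",", py[i])
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        taken_x <- c(taken_x, px[i]); taken_y <- c(taken_y, py[i])
        tri_id <- c(tri_id, t)
        bary <- rbind(bary, c(l1[i], l2[i], l3[i]))
      }
    }
  }
  ord <- order(taken_x, taken_y)
  list(x = taken_x[ord], y = taken_y[ord],
       tri = tri_id[ord], bary = bary[ord, , drop = FALSE])
}

# Map reference-lattice pixels through the piecewise-affine warp defined
# by an image-space mesh; returns n_pix x 2 positions.
warp_positions <- function(lattice, mesh_img, tri) {
  n <- length(lattice$tri)
  out <- matrix(0, n, 2L)
  for (t in unique(lattice$tri)) {
    rows <- which(lattice$tri == t)
    V <- mesh_img[tri[t, ], , drop = FALSE]
    out[rows, ] <- lattice$bary[rows, , drop = FALSE] %*% V
  }
  out
}

# Image-space ribbon mesh for a shape; the band half-width scales with
# the shape's centroid size relative to the reference.
mesh_for_shape <- function(shape, model) {
  sc <- centroid_size(shape) / model$ref_size
  ribbon_mesh(shape, model$half_width * sc,
              (model$end_margin %||% 0) * sc)$vertices
}

#' Sample image texture at a shape into the model's reference frame
#'
#' Piecewise-affine warp from the shape's ribbon mesh to the reference
#' frame, followed by photometric normalization to zero mean and unit
#' variance (a constant patch normalizes to all zeros). Returns `NULL`
#' if the warp is degenerate (flipped triangles) or the shape leaves the
#' image, so callers can treat the step as failed.
#'
#' @param image grayscale matrix
#' @param shape n x 2 landmark matrix matching the model's point count
#' @param model an `appearance_model`
#' @param normalize set `FALSE` for raw samples
#' @return numeric texture vector over the reference-frame pixels, or `NULL`
#' @export
sample_texture <- function(image, shape, model, normalize = TRUE) {
  shape <- as_landmarks(shape)
  if (nrow(shape) != nrow(model$shape_model$mean_shape))
    stop("shape point count does not match the model")
  verts <- mesh_for_shape(shape, model)
  areas <- tri_signed_areas(verts, model$triangles)
  if (any(sign(areas) != sign(model$ref_areas)) || any(abs(areas) < 1e-9))
    return(NULL)
  pos <- warp_positions(model$lattice, verts, model$triangles)
  g <- bilinear_sample(image, pos[, 1], pos[, 2])
  if (anyNA(g)) return(NULL)
  if (!normalize) return(g)
  mu <- mean(g); s <- sd(g)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(g)))
  (g - mu) / s
}

# ---- pose parametrization --------------------------------------------------

# Pose q = (a, b, tx, ty): x' = (1+a) x - b y + tx, y' = b x + (1+a) y + ty.
pose_matrix <- function(q) matrix(c(1 + q[1], q[2], -q[2], 1 + q[1]), 2L, 2L)

pose_from_similarity <- function(rot, t) c(rot[1, 1] - 1, rot[2, 1], t)

shape_at_params <- function(model, p) {
  q <- p[1:4]
  ps <- p[-(1:4)]
  x_model <- flatten_shape(model$ref_mean)
  if (length(ps)) x_model <- x_model + as.vector(model$shape_basis %*% ps)
  apply_similarity(unflatten_shape(x_model), pose_matrix(q), q[3:4])
}

params_for_shape <- function(model, shape) {
  al <- align_similarity(model$ref_mean, as_landmarks(shape))
  q <- pose_from_similarity(al$rot, al$t)
  inv <- invert_similarity(al$rot, al$t)
  in_ref <- apply_similarity(shape, inv$rot, inv$t)
  ps <- as.vector(crossprod(model$shape_basis,
                            flatten_shape(in_ref) - flatten_shape(model$ref_mean)))
  c(q, ps)
}

# ---- model building --------------------------------------------------------

#' Build an appearance model from training image/landmark pairs
#'
#' Builds the Procrustes + PCA shape model, freezes the reference frame
#' (ribbon mesh around the mean shape at the mean training size), samples
#' and PCA-decomposes training textures at the ground-truth shapes, and
#' estimates the fixed Jacobian `J` relating parameter perturbations to
#' texture residuals by numeric perturbation: for each parameter and each
#' stated displacement, `(g(p + delta e_j) - g(p)) / delta`, averaged
#' over training images and displacement values.
#'
#' @param fixtures list of `list(image =, landmarks =)` pairs (>= 3);
#'   landmark point counts must agree
#' @param variance_kept shape-PCA variance fraction (default 0.98)
#' @param texture_variance_kept texture-PCA variance fraction (default 0.95)
#' @param half_width texture band half-width at reference scale, pixels
#' @param end_margin band extension beyond both curve ends (pixels at
#'   reference scale); the valley-to-skin transition there anchors the
#'   along-curve position during fitting
#' @param perturbations Jacobian estimation displacements: a list with
#'   `shape_sigma_frac` (fractions of each mode's standard deviation),
#'   `translate_px`, `scale`, `rotate`
#' @return object of class `appearance_model`
#' @export
build_appearance_model <- function(fixtures, variance_kept = 0.98,
                                   texture_variance_kept = 0.95,
                                   half_width = 6, end_margin = 10,
                                   perturbations = list(
                                     shape_sigma_frac = c(0.25, 0.5),
                                     translate_px = 2,
                                     scale = 0.05,
                                     rotate = 0.087)) {
  if (length(fixtures) < 3L) stop("need at least 3 training pairs")
  shapes <- lapply(fixtures, function(f) as_landmarks(f$landmarks))
  gpa <- procrustes_align(shapes)
  smodel <- build_shape_pca(gpa$aligned, variance_kept)
  ref_size <- mean(vapply(shapes, centroid_size, numeric(1)))
  ref_mean <- smodel$mean_shape * ref_size  # unit-size mean scaled to pixels
  mesh <- ribbon_mesh(ref_mean, half_width, end_margin)
  lattice <- reference_lattice(mesh)
  ref_areas <- tri_signed_areas(mesh$vertices, mesh$triangles)

  model <- structure(list(
    shape_model = smodel, ref_mean = ref_mean, ref_size = ref_size,
    shape_basis = smodel$basis,
    mode_sigma = sqrt(pmax(smodel$eigenvalues[seq_len(smodel$n_components)],
                           0)) * ref_size,
    half_width = half_width, end_margin = end_margin,
    triangles = mesh$triangles,
    ref_vertices = mesh$vertices, ref_areas = ref_areas,
    lattice = lattice), class = "appearance_model")

  textures <- lapply(fixtures, function(f)
    sample_texture(f$image, as_landmarks(f$landmarks), model))
  if (any(vapply(textures, is.null, logical(1))))
    stop("degenerate mesh while sampling a training shape")
  Tm <- do.call(rbind, textures)
  tex_mean <- colMeans(Tm)
  Tc <- sweep(Tm, 2, tex_mean)
  # PCA via SVD of the (small) Gram matrix: n_train << n_pixels
  gram <- tcrossprod(Tc) / (nrow(Tc) - 1L)
  eg <- eigen(gram, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  total <- sum(ev)
  if (total < 1e-14) {
    k <- 0L
  } else {
    cum <- cumsum(ev) / total
    k <- which(cum >= texture_variance_kept - 1e-12)[1]
    k <- min(k, sum(ev > 1e-12 * max(ev)))
  }
  if (k > 0) {
    B <- crossprod(Tc, eg$vectors[, seq_len(k), drop = FALSE])
    B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  } else {
    B <- matrix(0, ncol(Tm), 0L)
  }
  model$texture_mean <- tex_mean
  model$texture_basis <- B
  model$texture_eigenvalues <- ev

  # fixed Jacobian at the ground-truth parameters of each training image
  n_par <- 4L + smodel$n_components
  J <- matrix(0, length(tex_mean), n_par)
  counts <- numeric(n_par)
  deltas <- vector("list", n_par)
  deltas[[1]] <- c(perturbations$scale, -perturbations$scale)
  deltas[[2]] <- c(perturbations$rotate, -perturbations$rotate)
  deltas[[3]] <- c(perturbations$translate_px, -perturbations$translate_px)
  deltas[[4]] <- deltas[[3]]
  if (smodel$n_components > 0) {
    for (j in seq_len(smodel$n_components)) {
      d <- perturbations$shape_sigma_frac * model$mode_sigma[j]
      d <- d[d > 1e-12]
      if (!length(d)) d <- 0.5  # flat mode: fall back to a fixed step
      deltas[[4L + j]] <- c(d, -d)
    }
  }
  for (i in seq_along(fixtures)) {
    p0 <- params_for_shape(model, shapes[[i]])
    g0 <- sample_texture(fixtures[[i]]$image, shape_at_params(model, p0), model)
    if (is.null(g0)) next
    for (j in seq_len(n_par)) {
      for (d in deltas[[j]]) {
        pj <- p0; pj[j] <- pj[j] + d
        gj <- sample_texture(fixtures[[i]]$image, shape_at_params(model, pj),
                             model)
        if (is.null(gj)) next
        J[, j] <- J[, j] + (gj - g0) / d
        counts[j] <- counts[j] + 1
      }
    }
  }
  counts[counts == 0] <- 1
  J <- sweep(J, 2, counts, "/")
  # project out the texture subspace: misalignment must be explained by
  # what the texture model cannot, or the updates chase texture variation
  if (ncol(B) > 0) J <- J - B %*% crossprod(B, J)
  model$jacobian <- J
  model$JtJ <- crossprod(J)
  model
}

#' @export
print.appearance_model <- function(x, ...) {
  cat(sprintf(
    "<appearance_model> %d landmarks, %d shape modes, %d texture modes, %d band pixels\n",
    nrow(x$ref_mean), x$shape_model$n_components,
    ncol(x$texture_basis), length(x$lattice$x)))
  invisible(x)
}

# ---- fitting ---------------------------------------------------------------

#' Fit an appearance model to an image
#'
#' Fixed-Jacobian steepest-descent iteration: sample the image at the
#' current shape, reconstruct the model texture, form the residual
#' `dg = g_image - g_model` and error `E = dg dg^T`, predict the update
#' `dp = (J^T J + eps I)^{-1} J^T dg`, and try step sizes
#' `alpha in {1, 0.5, 0.25, 0.125}`, accepting the first that decreases
#' the error. Stops when no step size decreases the error or
#' `max_iterations` is reached. Deterministic.
#'
#' @param model an `appearance_model`
#' @param image grayscale matrix
#' @param init_shape n x 2 initial landmark estimate (must be inside the
#'   image)
#' @param max_iterations iteration cap
#' @param ridge Tikhonov damping added to `J^T J`
#' @param rel_tol minimum relative error decrease for a step to count as
#'   an improvement; smaller decreases end the fit ("no improvement")
#' @return object of class `aam_fit` with `final_shape`, `final_params`,
#'   `error_trace` (non-increasing over accepted iterations),
#'   `iterations`, `converged`
#' @export
aam_fit <- function(model, image, init_shape, max_iterations = 30L,
                    ridge = 1e-8, rel_tol = 0.1) {
  p <- params_for_shape(model, as_landmarks(init_shape))
  shape <- shape_at_params(model, p)
  g <- sample_texture(image, shape, model)
  if (is.null(g))
    stop("initial shape lies outside the image or is degenerate")
  B <- model$texture_basis
  reconstruct <- function(g) {
    if (ncol(B) == 0L) return(model$texture_mean)
    dc <- g - model$texture_mean
    model$texture_mean + as.vector(B %*% crossprod(B, dc))
  }
  # the model instance is re-evaluated for every sample, so the error is
  # the part of the sampled texture the texture model cannot explain
  residual_of <- function(g) g - reconstruct(g)
  n_par <- length(p)
  A <- model$JtJ + diag(ridge, n_par)
  alphas <- c(1, 0.5, 0.25, 0.125)
  dg <- residual_of(g)
  err <- sum(dg^2)
  trace <- err
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    dp <- tryCatch(solve(A, crossprod(model$jacobian, dg)),
                   error = function(e) NULL)
    if (is.null(dp)) { converged <- TRUE; break }
    accepted <- FALSE
    for (alpha in alphas) {
      p_try <- p - alpha * as.vector(dp)
      shape_try <- shape_at_params(model, p_try)
      g_try <- sample_texture(image, shape_try, model)
      if (is.null(g_try)) next
      dg_try <- residual_of(g_try)
      e_try <- sum(dg_try^2)
      if (e_try < err * (1 - rel_tol)) {
        p <- p_try; shape <- shape_try; g <- g_try
        dg <- dg_try; err <- e_try
        accepted <- TRUE
        break
      }
    }
    if (!accepted) { converged <- TRUE; break }
    trace <- c(trace, err)
  }
  structure(list(final_shape = shape, final_params = p,
                 error_trace = trace, iterations = iter,
                 converged = converged),
            class = "aam_fit")
}

#' @export
print.aam_fit <- function(x, ...) {
  cat(sprintf("<aam_fit> %d iterations, %s, error %.4g -> %.4g\n",
              x$iterations,
              if (x$converged) "converged" else "max iterations",
              x$error_trace[1], tail(x$error_trace, 1)))
  invisible(x)
}
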