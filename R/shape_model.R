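# ---- similarity alignment (2-D, complex-number form) -----------------------

centroid_size <- function(points) {
  points <- as_landmarks(points)
  sqrt(sum(sweep(points, 2, colMeans(points))^2))
}

# Similarity transform (scale+rotation+translation) aligning src to dst
# in the least-squares sense; returns the transformed points and the
# transform as a list(rot = 2x2 matrix incl. scale, t = length-2).
align_similarity <- function(src, dst) {
  zs <- complex(real = src[, 1], imaginary = src[, 2])
  zd <- complex(real = dst[, 1], imaginary = dst[, 2])
  ms <- mean(zs); md <- mean(zd)
  zs0 <- zs - ms; zd0 <- zd - md
  denom <- sum(Mod(zs0)^2)
  if (denom < .Machine$double.eps)
    stop("degenerate shape: all points identical")
  w <- sum(Conj(zs0) * zd0) / denom
  za <- w * zs0 + md
  rot <- matrix(c(Re(w), Im(w), -Im(w), Re(w)), 2L, 2L)
  tr <- c(Re(md), Im(md)) - as.vector(rot %*% c(Re(ms), Im(ms)))
  list(points = cbind(x = Re(za), y = Im(za)), rot = rot, t = tr)
}

apply_similarity <- function(points, rot, t) {
  out <- t(rot %*% t(as_landmarks(points))) + rep(t, each = nrow(points))
  colnames(out) <- c("x", "y")
  out
}

invert_similarity <- function(rot, t) {
  ri <- solve(rot)
  list(rot = ri, t = as.vector(-ri %*% t))
}

#' Generalized Procrustes alignment of landmark shapes
#'
#' Iteratively aligns each shape to the running mean by a similarity
#' transform (scale, rotation, translation), recomputes the mean, and
#' normalizes it to unit centroid size centred at the origin, until the
#' mean moves by less than `tol` or `max_iter` iterations.
#'
#' @param shapes list of n x 2 landmark matrices (>= 2, equal point counts)
#' @param tol convergence tolerance on the mean-shape movement
#' @param max_iter iteration cap
#' @return list with `aligned` (list of aligned shapes) and `mean`
#'   (the Procrustes mean shape, unit centroid size, centred)
#' @export
procrustes_align <- function(shapes, tol = 1e-7, max_iter = 100L) {
  if (length(shapes) < 2L) stop("need at least 2 shapes")
  shapes <- lapply(shapes, as_landmarks)
  np <- vapply(shapes, nrow, integer(1))
  if (length(unique(np)) != 1L) stop("shapes have unequal point counts")
  normalize <- function(p) {
    p <- sweep(p, 2, colMeans(p))
    cs <- sqrt(sum(p^2))
    if (cs < .Machine$double.eps) stop("degenerate shape: all points identical")
    p / cs
  }
  mean_shape <- normalize(shapes[[1]])
  for (it in seq_len(max_iter)) {
    aligned <- lapply(shapes, function(s) align_similarity(s, mean_shape)$points)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    # remove rotational drift relative to the previous mean, then renormalize
    new_mean <- align_similarity(new_mean, mean_shape)$points
    new_mean <- normalize(new_mean)
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  aligned <- lapply(shapes, function(s) align_similarity(s, mean_shape)$points)
  colnames(mean_shape) <- c("x", "y")
  list(aligned = aligned, mean = mean_shape)
}

#' Build a PCA shape model from aligned shapes
#'
#' Eigendecomposition of the sample covariance (divisor n-1) of the
#' flattened aligned shapes. The smallest number of leading components
#' whose cumulative variance reaches `variance_kept` is retained.
#'
#' @param aligned list of aligned n x 2 shapes (from [procrustes_align()])
#' @param variance_kept fraction of variance to keep, in (0, 1]
#' @param mean_shape optional mean to use (defaults to the sample mean)
#' @return object of class `shape_model`: `mean_shape` (n x 2),
#'   `basis` (2n x k, orthonormal columns), `eigenvalues`
#'   (full non-negative spectrum, non-increasing), `n_components`
#' @export
build_shape_pca <- function(aligned, variance_kept = 0.98, mean_shape = NULL) {
  if (length(aligned) < 2L) stop("need at least 2 shapes")
  if (variance_kept <= 0 || variance_kept > 1)
    stop("variance_kept must be in (0, 1]")
  X <- do.call(rbind, lapply(aligned, flatten_shape))
  mu <- if (is.null(mean_shape)) colMeans(X) else flatten_shape(mean_shape)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1L)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  total <- sum(ev)
  if (total < 1e-14) {
    k <- 0L
  } else {
    cum <- cumsum(ev) / total
    k <- which(cum >= variance_kept - 1e-12)[1]
    # never keep numerically-zero directions
    k <- min(k, sum(ev > 1e-12 * max(ev)))
  }
  basis <- if (k > 0) eg$vectors[, seq_len(k), drop = FALSE]
           else matrix(0, ncol(X), 0L)
  structure(list(mean_shape = unflatten_shape(mu), basis = basis,
                 eigenvalues = ev, n_components = as.integer(k)),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> %d points, %d components (of %d modes)\n",
              nrow(x$mean_shape), x$n_components,
              sum(x$eigenvalues > 1e-12 * max(x$eigenvalues, 1e-300))))
  invisible(x)
}

#' Synthesize a shape from model parameters
#'
#' Linear synthesis `s = mean + E p`; `p = 0` returns the mean shape.
#'
#' @param model a `shape_model`
#' @param p parameter vector of length `n_components`
#' @return n x 2 landmark matrix
#' @export
shape_from_params <- function(model, p) {
  if (length(p) != model$n_components)
    stop("parameter vector length != n_components")
  v <- flatten_shape(model$mean_shape)
  if (length(p)) v <- v + as.vector(model$basis %*% p)
  unflatten_shape(v)
}

#' Project a shape onto the model basis
#'
#' Orthogonal projection `p = E^T (s - mean)`; for an out-of-span shape
#' this gives the least-squares parameters.
#'
#' @param model a `shape_model`
#' @param shape n x 2 landmark matrix with matching point count
#' @return parameter vector
#' @export
params_from_shape <- function(model, shape) {
  shape <- as_landmarks(shape)
  if (nrow(shape) != nrow(model$mean_shape))
    stop("shape point count != model point count")
  as.vector(crossprod(model$basis,
                      flatten_shape(shape) - flatten_shape(model$mean_shape)))
}

#' Sparse projection of a shape onto a wrinkle-structure dictionary
#'
#' Solves `min_s 0.5 ||vec - W s||^2 + lambda ||s||_1` by cyclic
#' coordinate descent with soft thresholding. Used to regularize the
#' ridge-derived initial wrinkle shape toward the span of the training
#' wrinkle structures (default `lambda = 1e-6`).
#'
#' @param shape_vec flattened shape vector
#' @param W dictionary matrix, one training wrinkle structure per column
#' @param lambda L1 regularization weight (>= 0)
#' @param max_sweeps,tol iteration control
#' @return list with `coefficients`, `reconstruction` (`W s`) and
#'   `objective` (per-sweep objective values, non-increasing)
#' @export
sparse_shape_projection <- function(shape_vec, W, lambda = 1e-6,
                                    max_sweeps = 1000L, tol = 1e-10) {
  W <- as.matrix(W)
  if (ncol(W) == 0L) stop("empty dictionary")
  if (nrow(W) != length(shape_vec))
    stop("dictionary and shape dimensions disagree")
  if (lambda < 0) stop("lambda must be >= 0")
  colsq <- colSums(W^2)
  s <- numeric(ncol(W))
  r <- as.vector(shape_vec)            # residual v - W s (s = 0)
  obj <- numeric(0)
  for (sweep_i in seq_len(max_sweeps)) {
    max_change <- 0
    for (j in seq_len(ncol(W))) {
      if (colsq[j] < .Machine$double.eps) next
      z <- sum(W[, j] * r) + colsq[j] * s[j]
      new_sj <- sign(z) * max(abs(z) - lambda, 0) / colsq[j]
      if (new_sj != s[j]) {
        r <- r - W[, j] * (new_sj - s[j])
        max_change <- max(max_change, abs(new_sj - s[j]))
        s[j] <- new_sj
      }
    }
    obj <- c(obj, 0.5 * sum(r^2) + lambda * sum(abs(s)))
    if (max_change < tol) break
  }
  list(coefficients = s, reconstruction = as.vector(W %*% s),
       objective = obj)
}
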