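ellipse_shape <- function(n = 20, a = 3, b = 1.5) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(t), b * sin(t))
}

rand_sim <- function(shape, ang, sc, tx, ty) {
  R <- sc * matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  t(R %*% t(shape)) + rep(c(tx, ty), each = nrow(shape))
}

test_that("Procrustes alignment removes similarity differences", {
  s <- ellipse_shape()
  out <- procrustes_align(list(s, rand_sim(s, 0.7, 2.3, 10, -4)))
  expect_lt(mean_pt_err(out$aligned[[1]], out$aligned[[2]]), 1e-6)
  # identical copies: mean is the shape up to the normalizing similarity
  out2 <- procrustes_align(list(s, s, s))
  al <- wrinklefind:::align_similarity(s, out2$mean)$points
  expect_lt(mean_pt_err(al, out2$mean), 1e-8)
  expect_error(procrustes_align(list(s)), "at least 2")
  deg <- matrix(1, 5, 2)
  expect_error(procrustes_align(list(deg, deg)), "degenerate")
})

test_that("the Procrustes mean recovers a noisy ellipse generator", {
  set.seed(6)
  base <- ellipse_shape()
  shapes <- lapply(1:3, function(i) base + matrix(rnorm(40, sd = 0.05), 20, 2))
  out <- procrustes_align(shapes)
  ref <- wrinklefind:::align_similarity(base, out$mean)$points
  expect_lt(sqrt(mean(rowSums((ref - out$mean)^2))), 0.5)
})

test_that("the mean is invariant under a common similarity transform of all inputs", {
  set.seed(7)
  shapes <- lapply(1:5, function(i)
    ellipse_shape() + matrix(rnorm(40, sd = 0.1), 20, 2))
  m1 <- procrustes_align(shapes)$mean
  moved <- lapply(shapes, rand_sim, ang = -1.1, sc = 0.6, tx = 5, ty = 7)
  m2 <- procrustes_align(moved)$mean
  al <- wrinklefind:::align_similarity(m2, m1)$points
  expect_lt(mean_pt_err(al, m1), 1e-6)
})

test_that("shape PCA handles degenerate and rank-1 families", {
  s <- ellipse_shape()
  out <- procrustes_align(list(s, s, s, s))
  m0 <- build_shape_pca(out$aligned, 0.98)
  expect_equal(m0$n_components, 0L)
  # variation along a single direction only
  dirn <- matrix(rnorm(40), 20, 2)
  shapes <- lapply(c(-2, -1, 1, 2), function(t) s + 0.01 * t * dirn)
  m1 <- build_shape_pca(shapes, 1)
  expect_equal(sum(m1$eigenvalues > 1e-12 * max(m1$eigenvalues)), 1L)
  expect_error(build_shape_pca(out$aligned, 0), "variance_kept")
})

test_that("shape PCA matches a dense covariance eigendecomposition", {
  set.seed(8)
  shapes <- lapply(1:10, function(i) matrix(rnorm(16), 8, 2))
  m <- build_shape_pca(shapes, 1)
  X <- do.call(rbind, lapply(shapes, wrinklefind:::flatten_shape))
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  expect_lt(max(abs(m$eigenvalues - pmax(eg$values, 0))), 1e-8)
  for (k in seq_len(m$n_components)) {
    # eigenvectors match up to sign
    d <- min(sum(abs(m$basis[, k] - eg$vectors[, k])),
             sum(abs(m$basis[, k] + eg$vectors[, k])))
    expect_lt(d, 1e-7)
  }
  expect_lt(max(abs(crossprod(m$basis) - diag(m$n_components))), 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
})

test_that("shape synthesis and projection are exact inverses on the span", {
  set.seed(9)
  shapes <- lapply(1:8, function(i) ellipse_shape() + matrix(rnorm(40, sd = 0.2), 20, 2))
  m <- build_shape_pca(shapes, 1)
  expect_equal(shape_from_params(m, numeric(m$n_components)), m$mean_shape)
  expect_equal(params_from_shape(m, m$mean_shape), numeric(m$n_components))
  p <- rnorm(m$n_components)
  expect_lt(max(abs(params_from_shape(m, shape_from_params(m, p)) - p)), 1e-10)
  # full-rank reconstruction of a training shape is exact
  s1 <- shapes[[1]]
  rec <- shape_from_params(m, params_from_shape(m, s1))
  expect_lt(max(abs(rec - s1)), 1e-8)
  # linearity along the first eigenvector
  e1 <- m$basis[, 1]
  s_t <- shape_from_params(m, c(2.5, numeric(m$n_components - 1)))
  expect_equal(wrinklefind:::flatten_shape(s_t) -
                 wrinklefind:::flatten_shape(m$mean_shape), 2.5 * e1)
  expect_error(shape_from_params(m, 1), "n_components")
})

test_that("out-of-span projection leaves a residual orthogonal to the basis", {
  set.seed(10)
  shapes <- lapply(1:4, function(i) matrix(rnorm(12), 6, 2))
  m <- build_shape_pca(shapes, 1)
  target <- matrix(rnorm(12), 6, 2)
  p <- params_from_shape(m, target)
  resid <- wrinklefind:::flatten_shape(target) -
    wrinklefind:::flatten_shape(shape_from_params(m, p))
  expect_lt(max(abs(crossprod(m$basis, resid))), 1e-8)
})

# Independent lasso oracle: enumerate sign patterns and solve the KKT
# system for each; feasible solutions are compared by objective value.
lasso_oracle <- function(W, v, lambda) {
  p <- ncol(W)
  best <- list(obj = Inf)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (r in seq_len(nrow(signs))) {
    sg <- signs[r, ]
    act <- which(sg != 0)
    s <- numeric(p)
    if (length(act)) {
      Wa <- W[, act, drop = FALSE]
      rhs <- crossprod(Wa, v) - lambda * sg[act]
      sa <- tryCatch(solve(crossprod(Wa), rhs), error = function(e) NULL)
      if (is.null(sa) || any(sign(sa) != sg[act])) next
      s[act] <- sa
    }
    grad <- crossprod(W, v - W %*% s)
    if (any(abs(grad[sg == 0]) > lambda + 1e-9)) next
    obj <- 0.5 * sum((v - W %*% s)^2) + lambda * sum(abs(s))
    if (obj < best$obj) best <- list(obj = obj, s = s)
  }
  best
}

test_that("sparse projection solves the L1 problem", {
  set.seed(11)
  # orthonormal dictionary, lambda 0: plain least squares
  W <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:4]
  v <- rnorm(6)
  out <- sparse_shape_projection(v, W, 0)
  expect_lt(max(abs(out$coefficients - crossprod(W, v))), 1e-8)
  # atom recovery
  out2 <- sparse_shape_projection(W[, 2], W, 1e-8)
  expect_lt(abs(out2$coefficients[2] - 1), 1e-6)
  expect_lt(max(abs(out2$coefficients[-2])), 1e-6)
  # 5-atom, 8-dim problem against the KKT enumeration oracle
  W5 <- matrix(rnorm(40), 8, 5)
  v8 <- rnorm(8)
  lam <- 0.3
  out3 <- sparse_shape_projection(v8, W5, lam)
  obj3 <- 0.5 * sum((v8 - W5 %*% out3$coefficients)^2) +
    lam * sum(abs(out3$coefficients))
  oracle <- lasso_oracle(W5, v8, lam)
  expect_lt(abs(obj3 - oracle$obj), 1e-6)
  # objective is non-increasing across sweeps
  expect_true(all(diff(out3$objective) <= 1e-12))
  expect_error(sparse_shape_projection(v8, W5[, 0]), "empty dictionary")
  expect_error(sparse_shape_projection(v8, W5, -1), "lambda")
})

test_that("coordinate descent agrees with glmnet on a small problem", {
  skip_if_not_installed("glmnet")
  set.seed(12)
  W <- matrix(rnorm(60), 12, 5)
  v <- rnorm(12)
  lam <- 0.2
  ours <- sparse_shape_projection(v, W, lam)
  g <- glmnet::glmnet(W, v, alpha = 1, lambda = lam / nrow(W),
                      intercept = FALSE, standardize = FALSE,
                      thresh = 1e-14)
  obj <- function(s) 0.5 * sum((v - W %*% s)^2) + lam * sum(abs(s))
  expect_lt(abs(obj(ours$coefficients) - obj(as.vector(g$beta))), 1e-4)
})
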