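test_that("a constant image has an identically zero Hessian and response", {
  h <- hessian_at_scale(matrix(0.7, 30, 30), 2)
  expect_lt(max(abs(h$hxx)), 1e-12)
  expect_lt(max(abs(h$hxy)), 1e-12)
  expect_lt(max(abs(h$hyy)), 1e-12)
  expect_lt(max(ridge_response(h)$value), 1e-12)
  expect_error(hessian_at_scale(matrix(0, 3, 3), 0), "sigma")
})

test_that("a separable unit valley has the analytic cross curvature at small sigma", {
  xs <- matrix(rep(-20:20, each = 41), 41, 41)
  img <- -exp(-xs^2 / 2)
  h <- hessian_at_scale(img, 0.2)
  fd <- img[21, 20] - 2 * img[21, 21] + img[21, 22]  # discrete oracle
  expect_equal(h$hxx[21, 21], fd, tolerance = 1e-6)
  expect_lt(abs(h$hxx[21, 21] - 1), 0.25)  # analytic f''(0) = +1
  expect_lt(abs(h$hyy[21, 21]), 1e-8)
  expect_lt(abs(h$hxy[21, 21]), 1e-8)
  # response argmax per row sits on the centreline
  resp <- ridge_response(h)$value
  inner <- 5:37
  expect_true(all(abs(apply(resp[inner, ], 1, which.max) - 21) <= 1))
})

test_that("transposing the image swaps hxx and hyy and transposes hxy", {
  set.seed(3)
  img <- matrix(runif(900), 30, 30)
  h <- hessian_at_scale(img, 1.5)
  ht <- hessian_at_scale(t(img), 1.5)
  expect_equal(ht$hxx, t(h$hyy), tolerance = 1e-10)
  expect_equal(ht$hyy, t(h$hxx), tolerance = 1e-10)
  expect_equal(ht$hxy, t(h$hxy), tolerance = 1e-10)
})

test_that("closed-form eigenvalues handle diagonal and antidiagonal fields", {
  f <- structure(list(hxx = matrix(3, 2, 2), hxy = matrix(0, 2, 2),
                      hyy = matrix(-1, 2, 2), scale_sigma = 1),
                 class = "hessian_field")
  ev <- hessian_eigenvalues(f)
  expect_equal(ev$lambda1, matrix(3, 2, 2))
  expect_equal(ev$lambda2, matrix(-1, 2, 2))
  f$hxx <- f$hyy <- matrix(0, 2, 2); f$hxy <- matrix(2, 2, 2)
  ev <- hessian_eigenvalues(f)
  expect_equal(ev$lambda1, matrix(2, 2, 2))
  expect_equal(ev$lambda2, matrix(-2, 2, 2))
})

test_that("eigenvalue maps match a dense per-pixel eigendecomposition", {
  set.seed(4)
  f <- structure(list(hxx = matrix(rnorm(2500), 50), hxy = matrix(rnorm(2500), 50),
                      hyy = matrix(rnorm(2500), 50), scale_sigma = 1),
                 class = "hessian_field")
  ev <- hessian_eigenvalues(f)
  idx <- sample(2500, 300)
  for (i in idx) {
    o <- eigen(matrix(c(f$hxx[i], f$hxy[i], f$hxy[i], f$hyy[i]), 2, 2),
               symmetric = TRUE, only.values = TRUE)$values
    expect_lt(abs(ev$lambda1[i] - o[1]), 1e-10)
    expect_lt(abs(ev$lambda2[i] - o[2]), 1e-10)
  }
  expect_lt(max(abs(ev$lambda1 + ev$lambda2 - (f$hxx + f$hyy))), 1e-9)
  expect_lt(max(abs(ev$lambda1 * ev$lambda2 - (f$hxx * f$hyy - f$hxy^2))), 1e-9)
})

test_that("inverting intensities swaps dark and bright ridge responses exactly", {
  fx <- clean_fixture()
  img <- fx$image[200:300, 80:180]
  d1 <- ridge_response(hessian_at_scale(img, 2), "dark_ridge")$value
  b1 <- ridge_response(hessian_at_scale(1 - img, 2), "bright_ridge")$value
  expect_equal(d1, b1, tolerance = 1e-12)
})

test_that("ridge response is covariant with axis-aligned rotation", {
  fx <- clean_fixture()
  img <- fx$image[180:320, 60:200]
  r0 <- ridge_response(hessian_at_scale(img, 2))$value
  img90 <- t(img)[ncol(img):1, ]  # rotate 90 degrees counter-clockwise
  r90 <- ridge_response(hessian_at_scale(img90, 2))$value
  expect_equal(r90, t(r0)[ncol(r0):1, ], tolerance = 1e-9)
})

test_that("binarization thresholds over the mask only and respects its support", {
  resp <- matrix(0, 40, 40)
  mask <- matrix(TRUE, 40, 40)
  for (m in c("otsu", "quantile", "fixed")) {
    out <- binarize_response(resp, mask, m, param = 0.5)
    expect_false(any(out))
  }
  expect_error(binarize_response(resp, matrix(FALSE, 40, 40)), "empty mask")
  # mask excluding the wrinkle keeps the output disjoint from it
  fx <- clean_fixture()
  r <- ridge_response(hessian_at_scale(fx$image, 2))
  wm <- matrix(FALSE, nrow(fx$image), ncol(fx$image))
  tp <- unique(round(fx$wrinkle_truth))
  wm[cbind(tp[, 2], tp[, 1])] <- TRUE
  out <- binarize_response(r, !wm & cheek_mask(fx$landmarks, "left_cheek", dim(fx$image)))
  expect_false(any(out & wm))
})

test_that("otsu binarization splits a bimodal response between the modes", {
  set.seed(5)
  resp <- matrix(c(rnorm(500, 1, 0.05), rnorm(500, 5, 0.05)), 20, 50)
  mask <- matrix(TRUE, 20, 50)
  out <- binarize_response(resp, mask, "otsu")
  thr <- attr(out, "threshold")
  expect_gt(thr, 2)
  expect_lt(thr, 4.5)
  # exhaustive between-class-variance oracle; between well-separated
  # modes the criterion is flat, so compare the induced partitions
  vals <- as.vector(resp)
  cand <- seq(min(vals), max(vals), length.out = 512)
  bcv <- vapply(cand, function(t) {
    lo <- vals[vals < t]; hi <- vals[vals >= t]
    if (!length(lo) || !length(hi)) return(0)
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  oracle <- cand[which.max(bcv)]
  expect_identical(out, {
    o <- (resp >= oracle) & mask
    attr(o, "threshold") <- thr
    o
  })
})

test_that("line extraction recovers a straight raster line with near-zero turning", {
  bin <- matrix(FALSE, 140, 40)
  bin[11:130, 20] <- TRUE
  lines <- extract_lines(bin)
  expect_length(lines, 1L)
  expect_lt(abs(lines[[1]]$arc_length - 119), 2)
  expect_lt(lines[[1]]$total_turning, 1e-9)
  expect_identical(extract_lines(matrix(FALSE, 10, 10)), list())
})

test_that("a plus-sign raster splits into four arms at the branch point", {
  bin <- matrix(FALSE, 41, 41)
  bin[21, 5:37] <- TRUE
  bin[5:37, 21] <- TRUE
  lines <- extract_lines(bin)
  expect_length(lines, 4L)
  lens <- sort(vapply(lines, function(l) l$arc_length, numeric(1)))
  expect_true(all(lens > 10))
})

test_that("spur pruning removes short dead-end branches and rejoins the line", {
  bin <- matrix(FALSE, 60, 60)
  bin[10:50, 30] <- TRUE   # main line
  bin[cbind(30 - 0:4, 31 + 0:4)] <- TRUE  # 5-px diagonal spur
  pruned <- extract_lines(bin, prune_px = 8L)
  expect_length(pruned, 1L)
  expect_gt(pruned[[1]]$arc_length, 38)
})
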