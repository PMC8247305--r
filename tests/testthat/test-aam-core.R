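test_that("texture sampling normalizes a constant image to zeros", {
  det <- small_detector()
  m <- det$appearance
  img <- matrix(0.5, 420, 420)
  shape <- wrinklefind:::position_mean_wrinkle(det, clean_fixture()$landmarks)
  g <- sample_texture(img, shape, m)
  expect_true(all(g == 0))
})

test_that("texture sampling reproduces a linear ramp through the warp", {
  det <- small_detector()
  m <- det$appearance
  img <- matrix(rep(seq_len(420) / 420, each = 420), 420, 420)  # ramp in x
  shape <- wrinklefind:::position_mean_wrinkle(det, clean_fixture()$landmarks)
  g_raw <- sample_texture(img, shape, m, normalize = FALSE)
  verts <- wrinklefind:::mesh_for_shape(shape, m)
  pos <- wrinklefind:::warp_positions(m$lattice, verts, m$triangles)
  expect_equal(g_raw, pos[, 1] / 420, tolerance = 1e-8)
})

test_that("a shape outside the image yields a failed sample, not garbage", {
  det <- small_detector()
  m <- det$appearance
  img <- matrix(0.5, 420, 420)
  shape <- wrinklefind:::position_mean_wrinkle(det, clean_fixture()$landmarks)
  expect_null(sample_texture(img, shape - 300, m))
})

test_that("training textures are reconstructed by a full-rank texture basis", {
  fx <- noisefree_set()[1:6]
  pairs <- lapply(fx, function(f)
    list(image = f$image, landmarks = f$landmarks[69:88, ]))
  m <- build_appearance_model(pairs, texture_variance_kept = 1)
  g <- sample_texture(fx[[3]]$image, fx[[3]]$landmarks[69:88, ], m)
  rec <- m$texture_mean +
    as.vector(m$texture_basis %*% crossprod(m$texture_basis, g - m$texture_mean))
  expect_lt(sqrt(mean((g - rec)^2)), 1e-6)
})

test_that("identical training fixtures give an empty texture basis and no shape modes", {
  f <- noisefree_set()[[1]]
  pairs <- rep(list(list(image = f$image, landmarks = f$landmarks[69:88, ])), 5)
  m <- build_appearance_model(pairs)
  expect_equal(ncol(m$texture_basis), 0L)
  expect_equal(m$shape_model$n_components, 0L)
  expect_error(build_appearance_model(pairs[1:2]), "at least 3")
})

test_that("model building is deterministic", {
  fx <- noisefree_set()[1:5]
  pairs <- lapply(fx, function(f)
    list(image = f$image, landmarks = f$landmarks[69:88, ]))
  m1 <- build_appearance_model(pairs)
  m2 <- build_appearance_model(pairs)
  expect_identical(m1$jacobian, m2$jacobian)
  expect_identical(m1$texture_mean, m2$texture_mean)
})

test_that("the texture residual is lowest at the ground-truth parameters", {
  det <- noisefree_detector()
  m <- det$appearance
  fx <- noisefree_set()
  resid_at <- function(f, shape) {
    g <- sample_texture(f$image, shape, m)
    r <- g - (m$texture_mean +
      as.vector(m$texture_basis %*% crossprod(m$texture_basis, g - m$texture_mean)))
    sum(r^2)
  }
  better <- vapply(fx, function(f) {
    truth <- f$landmarks[69:88, ]
    e0 <- resid_at(f, truth)
    sig <- m$mode_sigma[1]
    p <- wrinklefind:::params_for_shape(m, truth)
    p[5] <- p[5] + 2 * sig
    e1 <- resid_at(f, wrinklefind:::shape_at_params(m, p))
    e0 < e1
  }, logical(1))
  expect_gte(mean(better), 0.9)
})

test_that("the fitter recovers a translated initialization", {
  det <- noisefree_detector()
  f <- noisefree_set()[[2]]
  truth <- f$landmarks[69:88, ]
  init <- truth + 5
  r <- aam_fit(det$appearance, f$image, init)
  expect_lt(mean_pt_err(r$final_shape, truth), mean_pt_err(init, truth))
  expect_true(all(diff(r$error_trace) <= 0))
})

test_that("fitting is deterministic and stops immediately on a flat image", {
  det <- noisefree_detector()
  f <- noisefree_set()[[1]]
  truth <- f$landmarks[69:88, ]
  r1 <- aam_fit(det$appearance, f$image, truth + 2)
  r2 <- aam_fit(det$appearance, f$image, truth + 2)
  expect_identical(r1, r2)
  flat <- matrix(0.5, nrow(f$image), ncol(f$image))
  r3 <- aam_fit(det$appearance, flat, truth)
  expect_true(r3$converged)
  expect_length(r3$error_trace, 1L)
  expect_equal(r3$final_shape, wrinklefind:::shape_at_params(
    det$appearance, wrinklefind:::params_for_shape(det$appearance, truth)))
  expect_error(aam_fit(det$appearance, f$image, truth - 500), "outside")
})
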