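test_that("identical spec and seed give bit-identical fixtures", {
  a <- generate_fixture(fixture_spec(seed = 9L))
  b <- generate_fixture(fixture_spec(seed = 9L))
  expect_identical(a$image, b$image)
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(a$wrinkle_truth, b$wrinkle_truth)
})

test_that("the wrinkle is a dark valley: centreline darker than flanking skin", {
  fx <- clean_fixture()
  w <- fx$spec$wrinkle_width
  idx <- seq(20, 380, by = 20)
  pts <- fx$wrinkle_truth[idx, ]
  nrm <- wrinklefind:::polyline_normals(fx$wrinkle_truth)[idx, ]
  at <- function(p) fx$image[round(p[2]), round(p[1])]
  for (i in seq_len(nrow(pts))) {
    on_line <- at(pts[i, ])
    off1 <- at(pts[i, ] + 3 * w * nrm[i, ])
    off2 <- at(pts[i, ] - 3 * w * nrm[i, ])
    expect_lt(on_line, off1)
    expect_lt(on_line, off2)
  }
})

test_that("zero wrinkle depth leaves no valley below the local base level", {
  sp <- fixture_spec(noise_std = 0, illumination_gradient = 0,
                     wrinkle_depth = 0)
  fx <- generate_fixture(sp)
  # interior of the face ellipse is a constant base level
  inner <- fx$image[150:280, 150:280]
  expect_gte(min(inner), max(inner) - 1e-12)
})

test_that("a wrinkle curve outside the face ellipse is rejected", {
  sp <- fixture_spec()
  sp$wrinkle_control_points[1, ] <- c(5, 5)
  expect_error(generate_fixture(sp), "exits the face ellipse")
})

test_that("wrinkle landmarks are an arc-length-uniform resampling of the truth", {
  fx <- clean_fixture()
  w20 <- fx$landmarks[69:88, ]
  expect_equal(w20, wrinklefind:::resample_polyline(fx$wrinkle_truth, 20L))
  gaps <- sqrt(rowSums(diff(w20)^2))
  expect_lt(diff(range(gaps)) / mean(gaps), 0.05)
})

test_that("face landmarks lie on or inside the face ellipse", {
  fx <- clean_fixture()
  sp <- fx$spec
  rel <- sweep(sweep(fx$landmarks[1:68, ], 2, sp$face_center),
               2, sp$face_axes, "/")
  expect_true(all(rowSums(rel^2) <= 1 + 1e-9))
})

test_that("generate_dataset is deterministic and produces distinct wrinkles", {
  a <- generate_dataset(5, seed = 4L)
  b <- generate_dataset(5, seed = 4L)
  expect_identical(lapply(a, `[[`, "image"), lapply(b, `[[`, "image"))
  expect_length(generate_dataset(1, seed = 1L), 1L)
  truths <- lapply(a, function(f) wrinklefind:::resample_polyline(f$wrinkle_truth, 20))
  for (i in 1:4) for (j in (i + 1):5)
    expect_gt(mean_pt_err(truths[[i]], truths[[j]]), 0)
})

test_that("written fixture trees are reproducible and round-trip", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(3, seed = 12L, out_dir = d1, split = "test")
  generate_dataset(3, seed = 12L, out_dir = d2, split = "test")
  for (f in list.files(d1)) {
    if (grepl("manifest", f)) next  # manifests embed their directory paths
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  loaded <- read_manifest(file.path(d1, "manifest.csv"))
  expect_length(loaded, 3L)
  expect_equal(dim(loaded[[1]]$landmarks), c(88L, 2L))
})

test_that("the rendered valley is a ridge of the negated image for the Hessian", {
  fx <- clean_fixture()
  mask <- cheek_mask(fx$landmarks, "left_cheek", dim(fx$image))
  resp <- ridge_response(hessian_at_scale(fx$image, 2))
  tp <- unique(round(fx$wrinkle_truth))
  on_w <- mean(resp$value[cbind(tp[, 2], tp[, 1])])
  set.seed(42)
  off <- which(mask)
  off_pix <- sample(off, 500)
  oy <- ((off_pix - 1) %% nrow(mask)) + 1
  ox <- ((off_pix - 1) %/% nrow(mask)) + 1
  d2min <- vapply(seq_along(ox), function(i)
    min((fx$wrinkle_truth[, 1] - ox[i])^2 + (fx$wrinkle_truth[, 2] - oy[i])^2),
    numeric(1))
  far <- d2min > (4 * fx$spec$wrinkle_width)^2
  off_resp <- mean(resp$value[cbind(oy[far], ox[far])])
  expect_gt(on_w, 5 * off_resp)
})
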