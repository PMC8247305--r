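# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

clean_fixture <- function() {
  cached("clean", generate_fixture(
    fixture_spec(noise_std = 0, illumination_gradient = 0)))
}

# noise-free but with the default illumination gradient: the histogram
# is non-degenerate, so equalization behaves as it does on real skin
ridge_fixture <- function() {
  cached("ridge", generate_fixture(fixture_spec(noise_std = 0)))
}

default_fixture <- function() {
  cached("default", generate_fixture(fixture_spec()))
}

noisefree_set <- function() {
  cached("nf20", generate_dataset(20, fixture_spec(noise_std = 0), seed = 303))
}

noisefree_detector <- function() {
  cached("nf20_det", train_wrinkle_detector(noisefree_set()))
}

small_detector <- function() {
  cached("small_det",
         train_wrinkle_detector(generate_dataset(6, seed = 11)))
}

# mean distance from each point to its counterpart
mean_pt_err <- function(a, b) mean(sqrt(rowSums((a - b)^2)))

# mean distance from points to the nearest vertex of a dense curve
mean_pt_to_curve <- function(pts, curve) {
  mean(vapply(seq_len(nrow(pts)), function(i)
    min(sqrt((curve[, 1] - pts[i, 1])^2 + (curve[, 2] - pts[i, 2])^2)),
    numeric(1)))
}

# straight-raster polyline as a ridge_polyline with a given pixel length
straight_line <- function(n, x0 = 10, y0 = 10) {
  ridge_polyline(cbind(x0, y0 + 0:(n - 1)))
}
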