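# Shared fixtures, memoized so expensive objects (system matrices, scans)
# are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# short fan, coarse pixels: fast but geometrically faithful
tiny_geometry <- function() {
  system_geometry(fan_length = 20, pixel_pitch = 1)
}

tiny_qgrid <- function() q_grid(0.04, 0.33, 0.005)

tiny_mask <- function() cached("tiny_mask", generate_mask(seed = 3))

tiny_sm <- function() {
  cached("tiny_sm",
         build_system_matrix(tiny_geometry(), tiny_mask(), tiny_qgrid()))
}

# full-fan system matrix at desk-scale binning, shared by the acceptance
# criteria tests
acc_geometry <- function() system_geometry(pixel_pitch = 0.5)

acc_qgrid <- function() q_grid(0.04, 0.33, 0.002)

acc_mask <- function() cached("acc_mask", generate_mask(seed = 7))

acc_sm <- function() {
  cached("acc_sm",
         build_system_matrix(acc_geometry(), acc_mask(), acc_qgrid()))
}

# single-line spectrum matrix helper
line_spectra <- function(sm, voxels, qs, sigma = 0.003) {
  f <- matrix(0, length(sm$voxel_x), length(sm$qgrid$centers))
  for (k in seq_along(voxels)) {
    f[voxels[k], ] <- exp(-(sm$qgrid$centers - qs[k])^2 / (2 * sigma^2))
  }
  f
}
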