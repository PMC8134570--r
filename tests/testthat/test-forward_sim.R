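test_that("system matrix satisfies the adjoint identity", {
  sm <- tiny_sm()
  H <- sm$H
  set.seed(31)
  for (i in 1:5) {
    x <- stats::runif(ncol(H))
    y <- stats::runif(nrow(H))
    lhs <- sum(as.numeric(H %*% x) * y)
    rhs <- sum(x * as.numeric(Matrix::t(H) %*% y))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  expect_true(all(H@x >= 0))
})

test_that("design-range columns have positive sensitivity", {
  sm <- tiny_sm()
  cs <- Matrix::colSums(sm$H)
  design <- rep(sm$qgrid$centers >= 0.05 & sm$qgrid$centers <= 0.3,
                times = length(sm$voxel_x))
  expect_true(all(cs[design] > 0))
})

test_that("ring radius matches the analytic cone geometry", {
  # independent oracle: r = L tan(theta(q)), with theta from the q
  # conversion; compared against the pixels the dense ray trace assigned to
  # that q bin for the centered voxel
  geom <- tiny_geometry()
  sm <- tiny_sm()
  v <- which.min(abs(sm$voxel_x))
  n_q <- length(sm$qgrid$centers)
  j <- which.min(abs(sm$qgrid$centers - 0.16))
  col <- sm$H[, (v - 1) * n_q + j]
  idx <- which(as.numeric(col) > 0)
  expect_gt(length(idx), 10)
  r_pix <- sqrt((sm$pixel_x[idx] - sm$voxel_x[v])^2 + sm$pixel_y[idx]^2)
  L <- geom$z_detector - geom$z_object
  r_oracle <- L * tan(scatter_angle(sm$qgrid$centers[j], 60) * pi / 180)
  # every assigned pixel lies on the ring to within a pixel + bin width
  expect_lt(max(abs(r_pix - r_oracle)), 1.5 * geom$pixel_pitch)
})

test_that("ring weights are left/right symmetric for a centered voxel", {
  # odd voxel count puts a voxel exactly on the fan axis; with the mask
  # removed the ring weights depend only on solid angle and polarization,
  # so they must mirror in x
  open_mask <- cached("open_mask", generate_mask(open_fraction = 1, seed = 1))
  smo <- cached("sym_sm_open", build_system_matrix(
    system_geometry(fan_length = 21, pixel_pitch = 1),
    open_mask, tiny_qgrid()
  ))
  v <- which(smo$voxel_x == 0)
  n_q <- length(smo$qgrid$centers)
  j <- which.min(abs(smo$qgrid$centers - 0.2))
  colo <- as.numeric(smo$H[, (v - 1) * n_q + j])
  left <- sum(colo[smo$pixel_x < 0]); right <- sum(colo[smo$pixel_x > 0])
  expect_equal(left, right, tolerance = 1e-6)
})

test_that("expected frame is the exact linear model mean", {
  sm <- tiny_sm()
  f <- line_spectra(sm, voxels = 5, qs = 0.16)
  mu <- expected_scatter(sm, f, flux_scale = 2, background_rate = 0.5)
  expect_equal(mu, as.numeric(2 * (sm$H %*% as.vector(t(f)))) + 0.5)
  # zero spectra, zero background -> zero frame
  f0 <- matrix(0, length(sm$voxel_x), length(sm$qgrid$centers))
  fr <- simulate_scatter_frame(sm, f0, 1, 0, seed = 1)
  expect_true(all(fr$counts == 0))
})

test_that("scatter counts scale linearly with flux and thickness", {
  sm <- tiny_sm()
  f <- line_spectra(sm, voxels = 8, qs = 0.2)
  m1 <- expected_scatter(sm, f, flux_scale = 1)
  expect_equal(expected_scatter(sm, f, flux_scale = 3), 3 * m1)
  expect_equal(expected_scatter(sm, 2 * f, flux_scale = 1), 2 * m1,
               tolerance = 1e-12)
})

test_that("flux calibration hits the target peak count", {
  sm <- tiny_sm()
  f <- line_spectra(sm, voxels = 10, qs = 0.21)
  flux <- calibrate_flux(sm, f, target_peak = 2500)
  expect_equal(max(expected_scatter(sm, f, flux)), 2500, tolerance = 1e-9)
  # the max over many near-peak pixels is biased upward by extreme-value
  # statistics, so allow 4 standard deviations
  fr <- simulate_scatter_frame(sm, f, flux, seed = 4)
  expect_lt(abs(max(fr$counts) - 2500), 4 * sqrt(2500))
})

test_that("scatter simulation is seed-reproducible", {
  sm <- tiny_sm()
  f <- line_spectra(sm, voxels = 7, qs = 0.18)
  a <- simulate_scatter_frame(sm, f, 1e6, 2, seed = 9)
  b <- simulate_scatter_frame(sm, f, 1e6, 2, seed = 9)
  c <- simulate_scatter_frame(sm, f, 1e6, 2, seed = 10)
  expect_identical(a$counts, b$counts)
  expect_gt(sum(a$counts != c$counts), 0)
  expect_true(all(a$counts == floor(a$counts)))
})

test_that("removing the mask yields a ring; the mask modulates it", {
  open_mask <- cached("open_mask", generate_mask(open_fraction = 1, seed = 1))
  smo <- cached("tiny_sm_open", build_system_matrix(tiny_geometry(),
                                                    open_mask, tiny_qgrid()))
  sm <- tiny_sm()
  v <- which.min(abs(sm$voxel_x))
  f <- line_spectra(sm, voxels = v, qs = 0.2)
  ring <- expected_scatter(smo, f)
  coded <- expected_scatter(sm, f)
  idx <- ring > 0
  ratio <- coded[idx] / ring[idx]
  # modulation only removes signal, never adds
  expect_true(all(ratio <= 1 + 1e-9))
  # a substantial fraction of ring pixels is strongly attenuated and a
  # substantial fraction passes nearly unmodulated
  expect_gt(mean(ratio < 0.5), 0.2)
  expect_gt(mean(ratio > 0.9), 0.2)
})

test_that("transmission of an air slice equals the air frame", {
  geom <- tiny_geometry()
  slab <- phantom(matrix(1L, 40, 40), matrix(3, 40, 40), 0.25, "water")
  tr <- simulate_transmission_frame(geom, slab, y = 1000)
  expect_true(all(tr$signal == tr$air))
  norm <- normalize_transmission(tr$signal, tr$air)
  expect_true(all(norm == 1))
})

test_that("monoenergetic transmission recovers Beer-Lambert exactly", {
  geom <- tiny_geometry()
  slab <- phantom(matrix(1L, 48, 80), matrix(4, 48, 80), 0.25, "water")
  mono <- energy_spectrum(60, 1)
  tr <- simulate_transmission_frame(geom, slab, y = 5, spectrum = mono)
  inside <- abs(tr$x) < 8
  norm <- normalize_transmission(tr$signal, tr$air)
  expect_equal(unique(norm[inside]), exp(-mu_linear("water", 60) * 4),
               tolerance = 1e-12)
  # thicker slab -> strictly smaller transmission
  slab2 <- phantom(matrix(1L, 48, 80), matrix(6, 48, 80), 0.25, "water")
  tr2 <- simulate_transmission_frame(geom, slab2, y = 5, spectrum = mono)
  expect_lt(normalize_transmission(tr2$signal, tr2$air)[which(inside)[1]],
            norm[which(inside)[1]])
})

test_that("air normalization averages bracketing scans and masks zeros", {
  expect_equal(normalize_transmission(1.1, 1.0, 1.2), 1.0)
  expect_true(is.na(normalize_transmission(1, 0, 0)))
  out <- normalize_transmission(c(0.5, 2), c(1, 1))
  expect_equal(out, c(0.5, 1.01))
})

test_that("step-and-shoot scan has one slice pair per mm and air frames", {
  sm <- tiny_sm()
  p <- phantom(matrix(1L, 24, 40), matrix(3, 24, 40), 0.25, "water",
               name = "slab6mm")
  scan <- assemble_scan(p, sm, seed = 2, target_peak = 300)
  expect_equal(length(scan$slice_y), 6)   # 6 mm extent / 1 mm step
  expect_equal(length(scan$scatter), 6)
  expect_equal(length(scan$transmission), 6)
  expect_equal(length(scan$air_scatter), 2)
  # same seed -> bit-identical scan
  scan2 <- assemble_scan(p, sm, seed = 2, target_peak = 300)
  expect_identical(lapply(scan$scatter, `[[`, "counts"),
                   lapply(scan2$scatter, `[[`, "counts"))
  # empty phantom: scatter frames are Poisson(background) only
  empty <- phantom(matrix(1L, 24, 40), matrix(0, 24, 40), 0.25, "air")
  scan0 <- assemble_scan(empty, sm, seed = 3, flux_scale = 1,
                         background_rate = 1.5)
  counts <- unlist(lapply(scan0$scatter, `[[`, "counts"))
  expect_equal(mean(counts), 1.5, tolerance = 0.05)
  # phantom wider than the fan is rejected
  wide <- phantom(matrix(1L, 10, 400), matrix(1, 10, 400), 0.25, "water")
  expect_error(assemble_scan(wide, sm, seed = 1, flux_scale = 1),
               "field of view")
})

test_that("system matrix round-trips through its triplet cache", {
  sm <- tiny_sm()
  dir <- file.path(withr::local_tempdir(), "smcache")
  write_system_matrix(sm, dir)
  sm2 <- read_system_matrix(dir)
  expect_equal(sm2$H, sm$H, tolerance = 1e-14)
  expect_equal(sm2$voxel_x, sm$voxel_x)
  expect_equal(sm2$qgrid$centers, sm$qgrid$centers)
  # cache hit: returns the stored matrix without rebuilding
  sm3 <- cached_system_matrix(tiny_geometry(), tiny_mask(), tiny_qgrid(),
                              60, cache_dir = dir)
  expect_equal(sm3$H, sm$H, tolerance = 1e-14)
  expect_identical(sm3$geometry_sig, sm$geometry_sig)
  # signature mismatch (different mask) triggers a rebuild
  other <- generate_mask(seed = 99)
  sm4 <- cached_system_matrix(tiny_geometry(), other, tiny_qgrid(),
                              60, cache_dir = dir)
  expect_false(identical(sm4$mask_sig, sm$mask_sig))
})
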