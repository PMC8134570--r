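test_that("mean q matches hand-computed weighted means", {
  q <- seq(0.05, 0.32, by = 0.005)
  delta <- function(at) { s <- numeric(length(q)); s[which.min(abs(q - at))] <- 1; s }
  expect_equal(mean_q(delta(0.2), q), 0.2)
  # uniform over [0.1, 0.3] -> midpoint
  u <- as.numeric(q >= 0.1 & q <= 0.3)
  expect_equal(mean_q(u, q), 0.2)
  expect_equal(mean_q(delta(0.12) + delta(0.24), q), 0.18)
  # invariant to positive rescaling
  s <- stats::runif(length(q))
  expect_equal(mean_q(7.3 * s, q), mean_q(s, q))
  # no mass in range -> invalid, not NaN
  expect_true(is.na(mean_q(delta(0.06), q)))
})

test_that("colorization maps mean q linearly onto the palette", {
  vals <- matrix(c(0.1, 0.2, 0.3, NA), 2, 2)
  rgb <- q_colorize(vals, range = c(0.1, 0.3))
  # constant field -> constant color
  const <- q_colorize(matrix(0.17, 3, 3), range = c(0.1, 0.3))
  expect_equal(length(unique(as.vector(const))), 3)
  # midpoint maps to the palette midpoint entry
  pal <- grDevices::col2rgb(grDevices::hcl.colors(255, "viridis")) / 255
  expect_equal(as.numeric(rgb[2, 1, ]), as.numeric(pal[, 128]))
  # invalid voxel gets the neutral grey
  expect_equal(as.numeric(rgb[2, 2, ]), rep(0.5, 3))
  # two-material field -> exactly two distinct colors
  two <- q_colorize(matrix(c(0.12, 0.12, 0.25, 0.25), 2, 2),
                    range = c(0.1, 0.3))
  cols <- unique(apply(two, c(1, 2), paste, collapse = ","))
  expect_equal(length(unique(as.vector(cols))), 2)
  expect_warning(q_colorize(matrix(0.2, 1, 1), range = c(0.2, 0.2)),
                 "degenerate")
})

test_that("TQC combines transmission intensity with mean-q color pixelwise", {
  mq <- structure(list(values = matrix(c(0.12, 0.25), 1, 2),
                       x = c(-0.5, 0.5), y = 0.5),
                  class = "mean_q_map")
  # air everywhere (T = 1) -> black under attenuation-bright convention
  tr <- list(image = matrix(1, 2, 4), x = seq(-0.75, 0.75, by = 0.5),
             y = c(0.25, 0.75))
  img <- tqc_image(tr, mq)
  expect_true(all(img == 0))
  # uniform mean q, varying T -> one hue scaled by attenuation
  mq2 <- structure(list(values = matrix(0.2, 1, 2), x = c(-0.5, 0.5),
                        y = 0.5), class = "mean_q_map")
  tr2 <- list(image = matrix(c(0.2, 0.6), 2, 4), x = tr$x, y = tr$y)
  img2 <- tqc_image(tr2, mq2)
  hue <- img2[1, 1, ] / (1 - 0.2)
  for (i in 1:2) for (j in 1:4) {
    expect_equal(img2[i, j, ], hue * (1 - tr2$image[i, j]), tolerance = 1e-12)
  }
  # nearest upsampling is idempotent: doubling resolution keeps colors
  coarse <- tqc_image(list(image = matrix(0.5, 2, 4), x = tr$x, y = tr$y), mq)
  fine <- tqc_image(list(image = matrix(0.5, 2, 8),
                         x = seq(-0.875, 0.875, by = 0.25),
                         y = c(0.25, 0.75)), mq)
  expect_equal(as.numeric(fine[1, 2, ]), as.numeric(fine[1, 1, ]))
  expect_equal(as.numeric(fine[1, 1, ]), as.numeric(coarse[1, 1, ]))
})

test_that("hyperspectral windows are additive over a partition", {
  cube <- structure(list(
    cube = array(stats::runif(2 * 3 * 20), c(2, 3, 20)),
    q = seq(0.0525, 0.2425, by = 0.01), voxel_x = 1:3, slice_y = 1:2
  ), class = "xrd_datacube")
  all_q <- hyperspectral_windows(cube, list(c(0, 1)))[[1]]
  parts <- hyperspectral_windows(cube, list(c(0, 0.1), c(0.1, 0.2), c(0.2, 1)))
  expect_equal(parts[[1]] + parts[[2]] + parts[[3]], all_q)
  expect_equal(all_q, apply(cube$cube, c(1, 2), sum))
  expect_warning(hyperspectral_windows(cube, list(c(0.9, 1))), "empty")
})

test_that("cross-correlation satisfies its metric axioms", {
  a <- c(1, 0)
  expect_equal(cross_correlation(a, c(1, 1)), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cross_correlation(c(0, 1, 0), c(0, 0, 2)), 0)
  set.seed(41)
  for (i in 1:20) {
    x <- stats::runif(30); y <- stats::runif(30)
    cxy <- cross_correlation(x, y)
    expect_equal(cxy, cross_correlation(y, x), tolerance = 1e-12)
    expect_lte(cxy, 1 + 1e-12)
    expect_gte(cxy, 0)
    expect_equal(cross_correlation(3.7 * x, y), cxy, tolerance = 1e-12)
    expect_equal(cross_correlation(x, 2.2 * x), 1, tolerance = 1e-12)
  }
  expect_warning(expect_true(is.na(cross_correlation(c(0, 0), c(1, 1)))),
                 "zero-norm")
})

test_that("cross-correlation resamples mismatched q grids", {
  q1 <- seq(0.05, 0.3, by = 0.005)
  q2 <- seq(0.05, 0.3, by = 0.002)
  shape <- function(q) exp(-(q - 0.16)^2 / (2 * 0.03^2))
  expect_equal(cross_correlation(shape(q1), shape(q2), q_a = q1, q_b = q2),
               1, tolerance = 1e-4)
})

test_that("FWHM measurement matches analytic peak shapes", {
  q <- seq(0.1, 0.3, by = 0.0005)
  g <- exp(-(q - 0.2)^2 / (2 * 0.004^2))
  pk <- fwhm_peak(g, q)
  # analytic 2.35482 sigma, within half a bin
  expect_lt(abs(pk$fwhm - 2 * sqrt(2 * log(2)) * 0.004), 0.00025)
  expect_equal(pk$position, 0.2, tolerance = 1e-4)
  expect_false(pk$edge)
  # triangle of half-width w has FWHM = w
  tri <- pmax(0, 1 - abs(q - 0.2) / 0.01)
  pk2 <- fwhm_peak(tri, q)
  expect_equal(pk2$fwhm, 0.01, tolerance = 1e-6)
  # symmetric spectrum: position at the symmetry center
  sym <- exp(-(q - 0.22)^2 / (2 * 0.01^2)) + exp(-(q - 0.18)^2 / (2 * 0.01^2))
  expect_equal(fwhm_peak(g + rev(g), q)$position, 0.2, tolerance = 1e-3)
  # peak at the grid edge is flagged
  edge <- exp(-(q - 0.1)^2 / (2 * 0.005^2))
  pke <- fwhm_peak(edge, q)
  expect_true(pke$edge)
  expect_equal(pke$fwhm, 2 * sqrt(2 * log(2)) * 0.005, tolerance = 5e-4)
})

test_that("characterization report aggregates match per-well entries", {
  sm <- tiny_sm()
  p <- make_well_phantom(n_pairs = 1, span = 15)
  scan <- assemble_scan(p, sm, seed = 21, target_peak = 2500)
  cube <- reconstruct_scan(scan, sm, n_iter = 80)
  rep <- characterize(cube, p)
  expect_equal(nrow(rep$wells), 1)
  expect_true(all(is.finite(unlist(rep$wells[, -(1:3)]))))
  expect_equal(rep$summary$centroid_error[["mean"]],
               mean(rep$wells$centroid_error))
  expect_equal(rep$summary$cross_correlation[["mean"]],
               mean(rep$wells$cross_correlation))
  # truth compared to itself gives correlation 1
  qg <- q_grid_from_centers(cube$q)
  al <- reference_spectrum("aluminum", qg)
  expect_equal(cross_correlation(al$intensity, al$intensity), 1)
})
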