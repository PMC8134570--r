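# Bragg-law oracle used for crystalline line positions: q_hkl =
# sqrt(h^2+k^2+l^2) / (2 a), computed here independently of the package's
# line table.
bragg_q <- function(hkl, a) sqrt(sum(hkl^2)) / (2 * a)

test_that("aluminum reference has Bragg lines at the fcc positions", {
  qg <- q_grid(0.04, 0.33, 0.0005)
  al <- reference_spectrum("aluminum", qg)
  q111 <- bragg_q(c(1, 1, 1), 4.0495)
  q200 <- bragg_q(c(2, 0, 0), 4.0495)
  expect_equal(q111, 0.2139, tolerance = 2e-4)
  expect_equal(q200, 0.2469, tolerance = 2e-4)
  # local maxima of the comb sit at the oracle positions
  for (qk in c(q111, q200)) {
    sel <- abs(qg$centers - qk) < 0.01
    pk <- fwhm_peak(al$intensity[sel], qg$centers[sel])
    expect_equal(pk$position, qk, tolerance = 5e-4)
  }
  # in-range global maximum is the (111) line (within one bin)
  expect_lt(abs(qg$centers[which.max(al$intensity)] - q111), 5e-4)
})

test_that("crystalline line positions are invariant to the width parameter", {
  qg <- q_grid(0.04, 0.33, 0.0005)
  q111 <- bragg_q(c(1, 1, 1), 4.0495)
  for (w in c(0.002, 0.004, 0.008)) {
    al <- reference_spectrum("aluminum", qg, crystalline_width = w)
    sel <- abs(qg$centers - q111) < 0.012
    pk <- fwhm_peak(al$intensity[sel], qg$centers[sel])
    expect_equal(pk$position, q111, tolerance = 1e-3)
  }
})

test_that("amorphous references have the canonical peak positions", {
  qg <- q_grid(0.04, 0.33, 0.001)
  w <- reference_spectrum("water", qg)
  expect_lt(abs(qg$centers[which.max(w$intensity)] - 0.16), 1e-3)
  ad <- reference_spectrum("adipose", qg)
  expect_lt(abs(qg$centers[which.max(ad$intensity)] - 0.111), 1e-3)
  air <- reference_spectrum("air", qg)
  expect_true(all(air$intensity == 0))
  expect_error(reference_spectrum("kryptonite", qg), "unknown")
})

test_that("reference spectra are deterministic and grid-covariant", {
  coarse <- q_grid(0.04, 0.33, 0.004)
  fine <- q_grid(0.04, 0.33, 0.0005)
  a <- reference_spectrum("water", coarse)
  b <- reference_spectrum("water", coarse)
  expect_identical(a$intensity, b$intensity)
  # evaluating fine then averaging down matches direct coarse evaluation
  f <- reference_spectrum("water", fine)
  down <- vapply(seq_along(coarse$centers), function(i) {
    sel <- fine$centers >= coarse$edges[i] & fine$centers < coarse$edges[i + 1]
    mean(f$intensity[sel])
  }, numeric(1))
  expect_equal(down, a$intensity, tolerance = 0.02)
})

test_that("well phantom lays out paired signal/background wells", {
  p <- make_well_phantom(n_pairs = 12, span = 150)
  expect_equal(diff(p$well_centers_x), rep(12.5, 11))
  # signal wells carry the fill, background wells are air
  fill_id <- match(p$fill, p$materials)
  air_id <- match("air", p$materials)
  expect_equal(sum(p$material_map == fill_id),
               12 * (1 / 0.25) * (4 / 0.25))
  expect_equal(sum(p$material_map == air_id),
               12 * (1 / 0.25) * (4 / 0.25))
  # single pair: exactly one 1 x 4 mm fill footprint
  p1 <- make_well_phantom(n_pairs = 1)
  expect_equal(sum(p1$material_map == match(p1$fill, p1$materials)),
               (1 / 0.25) * (4 / 0.25))
  # air fill makes the signal and background well columns identical
  pa <- make_well_phantom(n_pairs = 2, fill = "air")
  sig_rows <- abs((seq_len(nrow(pa$thickness_map)) - 0.5) * 0.25 - 3.5) < 2
  bkg_rows <- abs((seq_len(nrow(pa$thickness_map)) - 0.5) * 0.25 - 8.5) < 2
  expect_identical(
    matrix(pa$materials[pa$material_map[sig_rows, ]], nrow = sum(sig_rows)),
    matrix(pa$materials[pa$material_map[bkg_rows, ]], nrow = sum(bkg_rows))
  )
  expect_identical(pa$thickness_map[sig_rows, ], pa$thickness_map[bkg_rows, ])
})

test_that("two-material phantom respects thickness and depth contracts", {
  mask <- letter_d_mask(30, 0.25)
  p <- make_two_material_phantom(mask)
  expect_true(all(p$thickness_map <= 10))
  expect_equal(sort(unique(as.vector(p$material_map))), c(1L, 2L))
  expect_equal(p$thickness_map[mask], rep(5, sum(mask)))
  expect_equal(unique(p$thickness_map[!mask]), 6.5)
  # empty shape gives a uniform slab
  u <- make_two_material_phantom(matrix(FALSE, 8, 8))
  expect_true(all(u$material_map == 1L))
  expect_error(make_two_material_phantom(mask, inset_depth = 7,
                                         body_thickness = 6.5),
               "inset depth")
  expect_error(
    phantom(matrix(1L, 2, 2), matrix(11, 2, 2), materials = "water"),
    "thin-sample"
  )
})

test_that("slicing presents the beam-averaged composition to the fan", {
  geom <- tiny_geometry()
  # uniform slab: every voxel identical
  slab <- phantom(matrix(1L, 40, 80), matrix(5, 40, 80), 0.25, "water")
  s <- slice_to_fan(slab, 5, geom)
  expect_true(all(vapply(s$composition, function(d) {
    nrow(d) == 1 && d$material == "water" && d$thickness == 5
  }, logical(1))))
  # adjacent scan positions inside the same feature give identical slices
  s2 <- slice_to_fan(slab, 5.05, geom)
  expect_equal(s$composition, s2$composition)
  # outside the phantom: all air
  s3 <- slice_to_fan(slab, 100, geom)
  expect_true(all(slice_dominant_material(s3) == "air"))
})

test_that("a 1 mm well projects into a single fan voxel when aligned", {
  geom <- system_geometry(fan_length = 15, voxel_pitch = 1)
  # one 1 mm aluminum well centered on a voxel center
  p <- make_well_phantom(n_pairs = 1, span = 15)
  expect_equal(p$well_centers_x, 0)
  s <- slice_to_fan(p, p$signal_y, geom)
  has_al <- vapply(s$composition, function(d) "aluminum" %in% d$material,
                   logical(1))
  expect_equal(sum(has_al), 1)
  expect_equal(s$voxel_x[which(has_al)], 0)
})

test_that("true spectra follow the thin-sample linear model", {
  geom <- tiny_geometry()
  qg <- tiny_qgrid()
  slab <- phantom(matrix(1L, 40, 80), matrix(4, 40, 80), 0.25, "water")
  s <- slice_to_fan(slab, 5, geom)
  f <- slice_true_spectra(s, qg)
  ref <- reference_spectrum("water", qg)
  expect_equal(f[1, ], 4 * ref$strength * ref$intensity, tolerance = 1e-12)
  # doubling thickness doubles coefficients (linearity)
  slab2 <- phantom(matrix(1L, 40, 80), matrix(8, 40, 80), 0.25, "water")
  f2 <- slice_true_spectra(slice_to_fan(slab2, 5, geom), qg)
  expect_equal(f2, 2 * f, tolerance = 1e-12)
})

test_that("phantom round-trips through its file container bit-exactly", {
  p <- make_well_phantom(n_pairs = 3, span = 60)
  dir <- file.path(withr::local_tempdir(), "phantom")
  write_phantom(p, dir)
  p2 <- read_phantom(dir)
  expect_identical(p2$material_map, p$material_map)
  expect_identical(p2$thickness_map, p$thickness_map)
  expect_identical(p2$materials, p$materials)
  expect_identical(p2$well_centers_x, p$well_centers_x)
})

test_that("spectrum CSV round-trips", {
  qg <- tiny_qgrid()
  w <- reference_spectrum("water", qg)
  path <- file.path(withr::local_tempdir(), "water.csv")
  write_spectrum_csv(w, path)
  w2 <- read_spectrum_csv(path, "water")
  expect_equal(w2$q, w$q)
  expect_equal(w2$intensity, w$intensity)
})
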