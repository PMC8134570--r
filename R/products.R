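# Derived image products and characterization metrics: mean momentum
# transfer maps and their colorization, combined transmission + q
# colorized (TQC) images, hyperspectral q-window displays, spectrum
# cross-correlation, FWHM-based resolution, and the well-phantom
# characterization report.

#' Mean momentum transfer of a spectrum
#'
#' Intensity-weighted mean of `q` over bins with centers in
#' `[q_lo, q_hi]`.  Returns `NA` (an invalid voxel, not an error) when the
#' spectrum has no mass in the range.
#'
#' @param intensity Nonnegative spectrum values.
#' @param q Bin centers (1/Angstrom).
#' @param q_lo,q_hi Integration range (default 0.1-0.3, the range with the
#'   best material separability).
#' @return Scalar mean q, or `NA` for an empty range.
#' @export
mean_q <- function(intensity, q, q_lo = 0.1, q_hi = 0.3) {
  if (any(intensity < 0)) stop("spectrum must be nonnegative")
  sel <- q >= q_lo & q <= q_hi
  tot <- sum(intensity[sel])
  if (!any(sel) || tot <= 0) return(NA_real_)
  sum(q[sel] * intensity[sel]) / tot
}

#' Mean-q map of a datacube
#'
#' Per-voxel [mean_q()] with a low-signal validity mask: voxels whose
#' in-range integral is below `threshold` times the image maximum are
#' marked invalid (prevents noise-colored background).
#'
#' @param cube An `xrd_datacube`.
#' @param q_lo,q_hi Integration range in 1/Angstrom.
#' @param threshold Low-signal mask threshold as a fraction of the maximum
#'   in-range integral.
#' @return Object of class `mean_q_map`: `values` (slice x voxel, `NA`
#'   where invalid), `valid`, and the map coordinates.
#' @export
mean_q_map <- function(cube, q_lo = 0.1, q_hi = 0.3, threshold = 0.02) {
  sel <- cube$q >= q_lo & cube$q <= q_hi
  mass <- apply(cube$cube[, , sel, drop = FALSE], c(1, 2), sum)
  valid <- mass >= threshold * max(mass)
  d <- dim(cube$cube)
  values <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (v in seq_len(d[2])) {
      if (valid[i, v]) {
        values[i, v] <- mean_q(cube$cube[i, v, ], cube$q, q_lo, q_hi)
      }
    }
  }
  structure(list(values = values, valid = valid, x = cube$voxel_x,
                 y = cube$slice_y, q_lo = q_lo, q_hi = q_hi),
            class = "mean_q_map")
}

# linear colormap coordinate in [0, 1]
.cmap_coord <- function(x, lo, hi) {
  if (hi <= lo) stop("degenerate colormap range")
  pmin(1, pmax(0, (x - lo) / (hi - lo)))
}

#' Colorize a mean-q map
#'
#' Linear map of mean q onto a perceptually uniform colormap over a fixed
#' range (so colors are comparable across scans); invalid voxels get a
#' neutral grey.
#'
#' @param mq A [mean_q_map()] (or a plain numeric matrix with `NA` for
#'   invalid).
#' @param cmap Palette name understood by [grDevices::hcl.colors()].
#' @param range Mean-q range mapped onto the palette ends.
#' @param n_colors Palette resolution (odd, so the midpoint is exact).
#' @param neutral Grey level for invalid voxels.
#' @return RGB array (rows x cols x 3) in `[0, 1]`.
#' @export
q_colorize <- function(mq, cmap = "viridis", range = c(0.1, 0.3),
                       n_colors = 255, neutral = 0.5) {
  values <- if (inherits(mq, "mean_q_map")) mq$values else mq
  if (diff(range) == 0) {
    warning("degenerate colormap range: single-color image")
    range <- range + c(-0.5, 0.5) * 1e-12
  }
  pal <- grDevices::hcl.colors(n_colors, cmap)
  rgb_pal <- grDevices::col2rgb(pal) / 255
  coord <- .cmap_coord(values, range[1], range[2])
  idx <- round(coord * (n_colors - 1)) + 1
  out <- array(neutral, dim = c(nrow(values), ncol(values), 3))
  ok <- which(!is.na(idx))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[ok] <- rgb_pal[ch, idx[ok]]
    out[, , ch] <- plane
  }
  out
}

# nearest-neighbor index of `from` coordinates for each `to` coordinate
.nearest_index <- function(to, from) {
  vapply(to, function(t) which.min(abs(from - t)), integer(1))
}

#' Combined transmission + q colorized (TQC) image
#'
#' Multiplies per-pixel transmission intensity with the color of the
#' co-registered mean-q voxel.  The mean-q map (coarse XRD voxels) is
#' upsampled to the transmission grid by nearest neighbor, preserving voxel
#' boundaries.  The default intensity convention is attenuation-bright
#' (`1 - T`): dense material is bright and air is black.
#'
#' @param transmission List with `image` (slice x sample, values in
#'   `(0, 1]`), `x`, `y` — as produced by [scan_transmission_image()] or
#'   stored in a datacube.
#' @param mq A [mean_q_map()].
#' @param cmap,range Passed to [q_colorize()].
#' @param attenuation_bright If `FALSE`, multiplies by `T` instead of
#'   `1 - T`.
#' @return RGB array (transmission rows x cols x 3) in `[0, 1]`.
#' @export
tqc_image <- function(transmission, mq, cmap = "viridis",
                      range = c(0.1, 0.3), attenuation_bright = TRUE) {
  rgb_mq <- q_colorize(mq, cmap, range)
  ix <- .nearest_index(transmission$x, mq$x)
  iy <- .nearest_index(transmission$y, mq$y)
  up <- rgb_mq[iy, ix, , drop = FALSE]
  t_img <- transmission$image
  if (!all(dim(up)[1:2] == dim(t_img))) {
    stop("transmission and mean-q grids do not register")
  }
  intensity <- if (attenuation_bright) 1 - t_img else t_img
  intensity[is.na(intensity)] <- 0
  out <- up
  for (ch in 1:3) out[, , ch] <- up[, , ch] * intensity
  out
}

#' Hyperspectral q-window images
#'
#' One integral image per half-open window `[lo, hi)`: the sum of the cube
#' over bins whose centers fall in the window.  Disjoint windows that
#' partition the q span sum to the total-intensity image.
#'
#' @param cube An `xrd_datacube`.
#' @param windows List of `c(lo, hi)` pairs in 1/Angstrom.
#' @return List of matrices (slice x voxel), named by window.
#' @export
hyperspectral_windows <- function(cube, windows) {
  lapply(stats::setNames(
    windows,
    vapply(windows, function(w) sprintf("q_%g_%g", w[1], w[2]), character(1))
  ), function(w) {
    sel <- cube$q >= w[1] & cube$q < w[2]
    if (!any(sel)) {
      warning(sprintf("empty q window [%g, %g)", w[1], w[2]))
      return(matrix(0, dim(cube$cube)[1], dim(cube$cube)[2]))
    }
    apply(cube$cube[, , sel, drop = FALSE], c(1, 2), sum)
  })
}

#' Zero-lag normalized cross-correlation of two spectra
#'
#' `sum(a b) / sqrt(sum(a^2) sum(b^2))`: scale-invariant, in `[0, 1]` for
#' nonnegative spectra, 1 iff proportional.  Raw intensities are compared
#' (no mean subtraction).  Inputs on different q grids are resampled onto
#' the first grid by linear interpolation.
#'
#' @param a,b Numeric spectra or `xrd_spectrum_ref` objects.
#' @param q_a,q_b Optional q grids for numeric inputs (required only when
#'   they differ).
#' @return Correlation value, or `NA` with a warning for a zero-norm input.
#' @export
cross_correlation <- function(a, b, q_a = NULL, q_b = NULL) {
  if (inherits(a, "xrd_spectrum_ref")) { q_a <- a$q; a <- a$intensity }
  if (inherits(b, "xrd_spectrum_ref")) { q_b <- b$q; b <- b$intensity }
  if (!is.null(q_a) && !is.null(q_b) && !isTRUE(all.equal(q_a, q_b))) {
    b <- stats::approx(q_b, b, xout = q_a, rule = 2)$y
  }
  if (length(a) != length(b)) stop("spectra lengths differ and no grids given")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("zero-norm spectrum: cross-correlation undefined")
    return(NA_real_)
  }
  sum(a * b) / (na * nb)
}

#' Peak position and FWHM of a spectrum
#'
#' The peak position is the apex of a parabola through the three bins
#' around the global maximum; the width is the distance between the
#' half-maximum crossings located by linear interpolation on each side.  A
#' peak whose half-maximum crossing falls off the grid is flagged and the
#' one-sided width (doubled) is reported.
#'
#' @param intensity Nonnegative spectrum values.
#' @param q Bin centers.
#' @return List with `position`, `fwhm`, `left`, `right` (crossings) and
#'   `edge` (TRUE when one-sided).
#' @export
fwhm_peak <- function(intensity, q) {
  stopifnot(length(intensity) == length(q), length(q) >= 3)
  i0 <- which.max(intensity)
  ymax <- intensity[i0]
  if (ymax <= 0) stop("spectrum has no positive peak")
  # parabolic apex through the three bins around the max
  position <- if (i0 > 1 && i0 < length(q)) {
    y1 <- intensity[i0 - 1]; y2 <- intensity[i0]; y3 <- intensity[i0 + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) q[i0] + 0.5 * (y1 - y3) / denom * (q[2] - q[1]) else q[i0]
  } else q[i0]
  half <- ymax / 2
  left <- NA_real_; right <- NA_real_
  if (i0 >= 2) {
    for (i in i0:2) {
      if (intensity[i - 1] <= half) {
        left <- q[i - 1] + (q[i] - q[i - 1]) *
          (half - intensity[i - 1]) / (intensity[i] - intensity[i - 1])
        break
      }
    }
  }
  if (i0 <= length(q) - 1) {
    for (i in i0:(length(q) - 1)) {
      if (intensity[i + 1] <= half) {
        right <- q[i] + (q[i + 1] - q[i]) *
          (half - intensity[i]) / (intensity[i + 1] - intensity[i])
        break
      }
    }
  }
  edge <- is.na(left) || is.na(right)
  fwhm <- if (!edge) {
    right - left
  } else if (!is.na(right)) {
    2 * (right - position)
  } else if (!is.na(left)) {
    2 * (position - left)
  } else {
    NA_real_
  }
  list(position = position, fwhm = fwhm, left = left, right = right,
       edge = edge)
}

#' Characterize a well-phantom scan
#'
#' For each well of a [make_well_phantom()] scan: paired signal/background
#' spectral subtraction, intensity-weighted transverse centroid error
#' against the known well center, FWHM and position error of the fill
#' material's principal line, and cross-correlation of the well spectrum
#' against the ground-truth reference.  A well whose in-range signal does
#' not exceed 3 standard deviations of the off-well background is reported
#' as undetected (`detected = FALSE`), not dropped.
#'
#' @param cube An `xrd_datacube` of the well-phantom scan.
#' @param p The [make_well_phantom()] phantom that was scanned.
#' @param window_mm Half-width of the voxel window around each well used
#'   for the centroid (mm).
#' @param line_q Principal line position of the fill (default: the
#'   aluminum (111) line).
#' @param line_halfwidth Half-width of the q window isolating the line.
#' @param crystalline_width Reference width for the truth spectrum.
#' @return Object of class `characterization_report`: `wells` (data frame)
#'   and `summary` (mean and sd aggregates).
#' @export
characterize <- function(cube, p, window_mm = 3,
                         line_q = aluminum_bragg_lines()[["111"]],
                         line_halfwidth = 0.02,
                         crystalline_width = 0.003) {
  stopifnot(!is.null(p$well_centers_x))
  qg_sel <- cube$q >= 0.05 & cube$q <= 0.3
  i_sig <- which.min(abs(cube$slice_y - p$signal_y))
  i_bkg <- which.min(abs(cube$slice_y - p$background_y))
  n_vox <- length(cube$voxel_x)
  corrected <- t(vapply(seq_len(n_vox), function(v) {
    background_spectrum_subtract(cube, c(i_sig, v), c(i_bkg, v))
  }, numeric(length(cube$q))))
  integral <- rowSums(corrected[, qg_sel, drop = FALSE])
  off_well <- rep(TRUE, n_vox)
  for (cx in p$well_centers_x) {
    off_well[abs(cube$voxel_x - cx) <= window_mm + 1] <- FALSE
  }
  noise_sd <- stats::sd(integral[off_well])
  truth <- reference_spectrum(p$fill, crystalline_width = crystalline_width,
                              qgrid = q_grid_from_centers(cube$q))
  rows <- lapply(seq_along(p$well_centers_x), function(k) {
    cx <- p$well_centers_x[k]
    win <- which(abs(cube$voxel_x - cx) <= window_mm)
    w <- integral[win]
    detected <- max(w) > 3 * noise_sd
    centroid <- sum(cube$voxel_x[win] * w) / sum(w)
    spec <- colSums(corrected[win, , drop = FALSE])
    line_sel <- cube$q >= line_q - line_halfwidth &
      cube$q <= line_q + line_halfwidth
    pk <- fwhm_peak(spec[line_sel], cube$q[line_sel])
    data.frame(
      well = k, center_x = cx, detected = detected,
      centroid = centroid, centroid_error = abs(centroid - cx),
      peak_position = pk$position,
      position_error = abs(pk$position - line_q),
      fwhm = pk$fwhm,
      cross_correlation = cross_correlation(spec, truth$intensity)
    )
  })
  wells <- do.call(rbind, rows)
  agg <- function(x) c(mean = mean(x), sd = stats::sd(x))
  structure(
    list(wells = wells,
         summary = list(centroid_error = agg(wells$centroid_error),
                        position_error = agg(wells$position_error),
                        fwhm = agg(wells$fwhm),
                        cross_correlation = agg(wells$cross_correlation)),
         noise_sd = noise_sd),
    class = "characterization_report"
  )
}

#' @export
print.characterization_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<characterization_report> %d wells (%d detected)\n",
      "  centroid error: %.4f +/- %.4f mm (max %.4f)\n",
      "  line position error: %.5f +/- %.5f 1/A\n",
      "  line FWHM: %.5f +/- %.5f 1/A\n",
      "  spectrum cross-correlation: %.4f +/- %.4f\n"
    ),
    nrow(x$wells), sum(x$wells$detected),
    s$centroid_error["mean"], s$centroid_error["sd"],
    max(x$wells$centroid_error),
    s$position_error["mean"], s$position_error["sd"],
    s$fwhm["mean"], s$fwhm["sd"],
    s$cross_correlation["mean"], s$cross_correlation["sd"]
  ))
  invisible(x)
}

#' Rebuild a q_grid from bin centers
#'
#' Inverse of taking `centers` from a uniform [q_grid()].
#'
#' @param centers Equally spaced bin centers.
#' @return A [q_grid()].
#' @export
q_grid_from_centers <- function(centers) {
  dq <- diff(centers)
  if (length(dq) == 0) stop("need at least two centers")
  if (max(abs(dq - dq[1])) > 1e-9) stop("centers must be equally spaced")
  q_grid(centers[1] - dq[1] / 2, centers[length(centers)] + dq[1] / 2,
         dq[1])
}

#' Mean spectrum of a rectangular voxel region
#'
#' Average spectrum over a `(slices x voxels)` block of a datacube, e.g. a
#' 3 x 3 region inside a material.
#'
#' @param cube An `xrd_datacube`.
#' @param slice_range,voxel_range Integer index ranges.
#' @return Numeric spectrum over q bins.
#' @export
region_mean_spectrum <- function(cube, slice_range, voxel_range) {
  block <- cube$cube[slice_range, voxel_range, , drop = FALSE]
  apply(block, 3, mean)
}
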