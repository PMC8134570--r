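# Transmission imaging and step-and-shoot scan assembly.  Transmission uses
# the full polychromatic Beer-Lambert model with energy-integrating
# detection through the central slit; scatter frames use the encoded
# monoenergetic model of the system matrix.  Air scans bracket both modes
# for normalization and background estimation.

#' Simulate one transmission profile
#'
#' Energy-integrated signal along the fan for one scan position:
#' `sum_E fluence(E) * E * line_attenuation(path, E)` per fan-axis sample.
#' Transmission acquisitions are modeled noise-free (high-flux,
#' energy-integrating slit readout).
#'
#' @param geometry A [system_geometry()].
#' @param p A [phantom()].
#' @param y Scan position in mm.
#' @param spectrum An [energy_spectrum()]; default is the filtered 80 kVp
#'   transmission-mode beam.
#' @param sample_pitch Fan-axis sampling in mm (default: detector pixel
#'   pitch demagnified to the object plane).
#' @return Object of class `transmission_profile` with fields `x`
#'   (fan-axis positions), `signal` and `air` (the open-beam value).
#' @export
simulate_transmission_frame <- function(geometry, p, y,
                                        spectrum = default_source_spectrum(80),
                                        sample_pitch = NULL) {
  if (is.null(sample_pitch)) {
    sample_pitch <- geometry$pixel_pitch * geometry$z_object /
      geometry$z_detector
  }
  n <- round(geometry$fan_length / sample_pitch)
  x <- (seq_len(n) - (n + 1) / 2) * sample_pitch
  w <- spectrum$fluence * spectrum$energies
  air_value <- sum(w)
  prof <- slice_profile(p, y, x)
  signal <- numeric(n)
  # group identical (material, thickness) runs to avoid per-sample sums
  key <- paste(prof$material, prof$thickness)
  for (k in unique(key)) {
    idx <- which(key == k)
    i <- idx[1]
    signal[idx] <- sum(w * line_attenuation(prof$material[i],
                                            prof$thickness[i],
                                            spectrum$energies))
  }
  structure(list(x = x, signal = signal, air = air_value, y = y,
                 mode = "transmission"),
            class = "transmission_profile")
}

#' Normalize a transmission profile by bracketing air scans
#'
#' Divides by the mean of the leading and trailing air values, clipping to
#' `(0, 1 + eps]`; pixels with nonpositive air value are masked (`NA`).
#'
#' @param signal Numeric vector of transmission signal.
#' @param air_start,air_end Air-scan values (scalar or per-pixel).
#' @param eps Clip tolerance above 1 for noise (default 0.01).
#' @return Normalized transmission in `(0, 1 + eps]`, `NA` where masked.
#' @export
normalize_transmission <- function(signal, air_start, air_end = air_start,
                                   eps = 0.01) {
  air <- (air_start + air_end) / 2
  out <- signal / air
  out[!is.finite(out) | air <= 0] <- NA_real_
  pmin(out, 1 + eps)
}

#' Assemble a step-and-shoot scan of a phantom
#'
#' One transmission profile and one Poisson-noisy encoded scatter frame per
#' beam-width translation step across the phantom, bracketed by air frames
#' in both modes.  All randomness derives from `seed`.
#'
#' @param p A [phantom()].
#' @param sm A [build_system_matrix()] result.
#' @param seed Integer seed.
#' @param flux_scale Photon-flux scale; `NULL` calibrates so the brightest
#'   expected pixel over the scan reaches `target_peak` counts.
#' @param target_peak Peak expected scatter count per pixel used when
#'   calibrating (hardware operating point about 2500).
#' @param background_rate Expected air-scatter/detector background counts
#'   per pixel per scatter frame.
#' @param sigma_e Spectral width (keV) of the polychromatic q-smearing
#'   applied to the true spectra before projection; 0 disables.
#' @param noise If `FALSE`, scatter frames are the unsampled means.
#' @param crystalline_width Reference line width passed to
#'   [slice_true_spectra()].
#' @return Object of class `scan_set` with per-slice frames, air frames,
#'   true per-slice spectra (for characterization against ground truth),
#'   and a config snapshot.
#' @export
assemble_scan <- function(p, sm, seed = 1, flux_scale = NULL,
                          target_peak = 2500, background_rate = 2,
                          sigma_e = 0.75, noise = TRUE,
                          crystalline_width = 0.003) {
  geometry <- sm$geometry
  ext <- phantom_extent(p)
  if (diff(ext$x) > geometry$fan_length + 1e-9) {
    stop("phantom exceeds the fan field of view")
  }
  step <- geometry$fan_width
  n_slices <- max(1L, round(diff(ext$y) / step))
  ys <- ext$y[1] + (seq_len(n_slices) - 0.5) * step
  S <- q_smear_matrix(sm$qgrid, sm$e0_kev, sigma_e)
  f_true <- lapply(ys, function(y) {
    slice_true_spectra(slice_to_fan(p, y, geometry), sm$qgrid,
                       crystalline_width)
  })
  f_meas <- lapply(f_true, smear_spectra, S = S)
  if (is.null(flux_scale)) {
    peak <- max(vapply(f_meas, function(f) max(expected_scatter(sm, f)),
                       numeric(1)))
    if (peak <= 0) stop("cannot calibrate flux against an all-zero scan")
    flux_scale <- target_peak / peak
  }
  scatter <- vector("list", n_slices)
  transmission <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    scatter[[i]] <- simulate_scatter_frame(
      sm, f_meas[[i]], flux_scale, background_rate,
      seed = seed + 1000L + i, noise = noise
    )
    transmission[[i]] <- simulate_transmission_frame(geometry, p, ys[i])
  }
  zero_f <- matrix(0, nrow = length(sm$voxel_x),
                   ncol = length(sm$qgrid$centers))
  air_scatter <- list(
    simulate_scatter_frame(sm, zero_f, flux_scale, background_rate,
                           seed = seed + 1L, noise = noise),
    simulate_scatter_frame(sm, zero_f, flux_scale, background_rate,
                           seed = seed + 2L, noise = noise)
  )
  structure(
    list(slice_y = ys, scatter = scatter, transmission = transmission,
         air_scatter = air_scatter, f_true = f_true, f_meas = f_meas,
         flux_scale = flux_scale, background_rate = background_rate,
         sigma_e = sigma_e, seed = seed, noise = noise,
         geometry_sig = sm$geometry_sig, mask_sig = sm$mask_sig,
         phantom_name = p$name),
    class = "scan_set"
  )
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf(
    "<scan_set> '%s': %d slices, flux scale %.4g, background %g/px, seed %d\n",
    x$phantom_name, length(x$slice_y), x$flux_scale, x$background_rate,
    x$seed
  ))
  invisible(x)
}

#' Normalized transmission image of a scan
#'
#' Rows are scan positions, columns fan-axis samples; values in `(0, 1]`.
#'
#' @param scan A [assemble_scan()] result.
#' @return List with `image` (matrix), `x` (fan positions) and `y` (scan
#'   positions).
#' @export
scan_transmission_image <- function(scan) {
  img <- t(vapply(
    scan$transmission,
    function(tr) normalize_transmission(tr$signal, tr$air),
    numeric(length(scan$transmission[[1]]$x))
  ))
  list(image = img, x = scan$transmission[[1]]$x, y = scan$slice_y)
}
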