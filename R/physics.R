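# Photon energy / wavelength / momentum-transfer conversions shared by all
# modules.  Convention used throughout: q = sin(theta/2) / lambda, with theta
# the full scattering angle, so that the water coherent-scatter peak falls
# near 0.16 1/Angstrom.

#' Planck constant times speed of light
#'
#' `hc` in keV * Angstrom, the conversion constant between photon energy and
#' wavelength.
#' @export
HC_KEV_ANGSTROM <- 12.39842

#' Convert photon energy to wavelength
#'
#' @param energy_kev Photon energy in keV (vectorized, all > 0).
#' @return Wavelength in Angstrom.
#' @examples
#' wavelength_from_energy(60)
#' @export
wavelength_from_energy <- function(energy_kev) {
  if (any(!is.finite(energy_kev)) || any(energy_kev <= 0)) {
    stop("photon energy must be positive and finite")
  }
  HC_KEV_ANGSTROM / energy_kev
}

#' Momentum transfer from energy and scattering angle
#'
#' `q = sin(theta/2) / lambda(E)` with `theta` the full scattering angle in
#' degrees.
#'
#' @param energy_kev Photon energy in keV.
#' @param theta_deg Scattering angle in degrees, in `[0, 180)`.
#' @return Momentum transfer in 1/Angstrom.
#' @seealso [scatter_angle()] for the inverse.
#' @export
momentum_transfer <- function(energy_kev, theta_deg) {
  if (any(theta_deg < 0) || any(theta_deg >= 180)) {
    stop("scattering angle must be in [0, 180) degrees")
  }
  lambda <- wavelength_from_energy(energy_kev)
  sin(theta_deg * pi / 360) / lambda
}

#' Scattering angle from momentum transfer and energy
#'
#' Inverse of [momentum_transfer()]: `theta = 2 asin(q * lambda)`.
#'
#' @param q Momentum transfer in 1/Angstrom.
#' @param energy_kev Photon energy in keV.
#' @return Scattering angle in degrees.
#' @export
scatter_angle <- function(q, energy_kev) {
  lambda <- wavelength_from_energy(energy_kev)
  s <- q * lambda
  if (any(s < 0) || any(s > 1)) {
    stop("momentum transfer outside the physical range [0, 1/lambda]")
  }
  2 * asin(s) * 180 / pi
}

#' Momentum-transfer grid
#'
#' A binned momentum-transfer axis.  The default span extends slightly past
#' the 0.05--0.3 1/Angstrom design range so that spectra peaked at the range
#' ends are not truncated.
#'
#' @param q_min,q_max Grid limits in 1/Angstrom.
#' @param bin_width Bin width in 1/Angstrom.
#' @return An object of class `q_grid` with fields `edges` and `centers`.
#' @export
q_grid <- function(q_min = 0.04, q_max = 0.33, bin_width = 0.0025) {
  stopifnot(q_min >= 0, q_max > q_min, bin_width > 0)
  n <- max(1L, round((q_max - q_min) / bin_width))
  edges <- q_min + (0:n) * bin_width
  structure(
    list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2),
    class = "q_grid"
  )
}

#' @export
print.q_grid <- function(x, ...) {
  cat(sprintf(
    "<q_grid> %d bins over [%.4g, %.4g] 1/A (width %.4g)\n",
    length(x$centers), min(x$edges), max(x$edges), x$edges[2] - x$edges[1]
  ))
  invisible(x)
}

#' System geometry description
#'
#' Distances of the object, coded-aperture and detector planes from the
#' source, fan-beam extent, and detector sampling.  The scatter readout
#' window (`scatter_ymin`/`scatter_ymax`, one side of the fan projection) and
#' the beam-block band are part of the geometry because the system matrix is
#' built over exactly those pixels.
#'
#' @param z_object Source-to-object-plane distance (mm).
#' @param z_aperture Source-to-aperture-plane distance (mm).
#' @param z_detector Source-to-detector-plane distance (mm).
#' @param fan_length Illuminated extent at the object plane (mm).
#' @param fan_width Beam thickness at the object plane (mm).
#' @param voxel_pitch Fan discretization (mm).
#' @param detector_extent_x,detector_extent_y Detector active area (mm).
#' @param pixel_pitch Detector sampling after binning (mm).
#' @param scatter_ymin,scatter_ymax Scatter readout band on the detector,
#'   measured from the fan projection line (mm).
#' @param beam_block_width Width of the lead beam-block band shielding the
#'   primary fan during scatter acquisition (mm).
#' @return An object of class `system_geometry`.
#' @export
system_geometry <- function(z_object = 450, z_aperture = 600,
                            z_detector = 800, fan_length = 150,
                            fan_width = 1, voxel_pitch = 1,
                            detector_extent_x = 292, detector_extent_y = 228,
                            pixel_pitch = 0.5,
                            scatter_ymin = 5, scatter_ymax = 65,
                            beam_block_width = 10) {
  if (!(z_object > 0 && z_object < z_aperture && z_aperture < z_detector)) {
    stop("geometry requires 0 < z_object < z_aperture < z_detector")
  }
  stopifnot(
    fan_length > 0, fan_width > 0, voxel_pitch > 0, pixel_pitch > 0,
    detector_extent_x > 0, detector_extent_y > 0,
    scatter_ymax > scatter_ymin, beam_block_width >= 0
  )
  structure(
    list(
      z_object = z_object, z_aperture = z_aperture, z_detector = z_detector,
      fan_length = fan_length, fan_width = fan_width,
      voxel_pitch = voxel_pitch,
      detector_extent_x = detector_extent_x,
      detector_extent_y = detector_extent_y,
      pixel_pitch = pixel_pitch,
      scatter_ymin = scatter_ymin, scatter_ymax = scatter_ymax,
      beam_block_width = beam_block_width
    ),
    class = "system_geometry"
  )
}

#' Fan voxel centers for a geometry
#'
#' @param geometry A [system_geometry()].
#' @return Numeric vector of voxel center x positions (mm), centered on the
#'   fan axis.
#' @export
fan_voxel_centers <- function(geometry) {
  n <- round(geometry$fan_length / geometry$voxel_pitch)
  (seq_len(n) - (n + 1) / 2) * geometry$voxel_pitch
}

#' @export
print.system_geometry <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<system_geometry> object %g mm, aperture %g mm, detector %g mm\n",
      "  fan %g x %g mm, voxel pitch %g mm (%d voxels)\n",
      "  detector %g x %g mm at %g mm pixels, scatter band [%g, %g] mm\n"
    ),
    x$z_object, x$z_aperture, x$z_detector, x$fan_length, x$fan_width,
    x$voxel_pitch, length(fan_voxel_centers(x)),
    x$detector_extent_x, x$detector_extent_y, x$pixel_pitch,
    x$scatter_ymin, x$scatter_ymax
  ))
  invisible(x)
}
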