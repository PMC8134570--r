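# Source spectrum synthesis and filtration.  The tube output is modeled by
# Kramers' law (thick-target Bremsstrahlung, no characteristic lines) and
# hardened by the beam filtration stack: the quasi-monochromatic XRD band
# near 60 keV arises from the interplay of the low-energy filtration cutoff
# and the hafnium K-edge at 65.35 keV.

#' Energy spectrum container
#'
#' @param energies Photon energies in keV, strictly increasing.
#' @param fluence Relative photon counts per bin, nonnegative, at least one
#'   positive.
#' @return Object of class `energy_spectrum`.
#' @export
energy_spectrum <- function(energies, fluence) {
  stopifnot(length(energies) == length(fluence))
  if (any(diff(energies) <= 0)) stop("energies must be strictly increasing")
  if (any(fluence < 0) || !any(fluence > 0)) {
    stop("fluence must be nonnegative with at least one positive bin")
  }
  structure(list(energies = energies, fluence = fluence),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> %d bins, %g-%g keV, peak at %g keV\n",
              length(x$energies), min(x$energies), max(x$energies),
              x$energies[which.max(x$fluence)]))
  invisible(x)
}

#' Kramers-law Bremsstrahlung spectrum
#'
#' Unfiltered thick-target tube spectrum: fluence proportional to
#' `(kvp - E) / E` on 1 keV bins from 10 keV to the tube voltage, normalized
#' to unit sum.  Tungsten characteristic lines are not modeled.
#'
#' @param kvp Tube voltage in kV (generator range 30-160).
#' @return An [energy_spectrum()].
#' @export
bremsstrahlung_spectrum <- function(kvp) {
  if (length(kvp) != 1 || !is.finite(kvp) || kvp < 30 || kvp > 160) {
    stop("tube voltage must be a single value in [30, 160] kVp")
  }
  energies <- seq(10, kvp, by = 1)
  fluence <- (kvp - energies) / energies
  energy_spectrum(energies, fluence / sum(fluence))
}

#' Filter a spectrum through a material slab
#'
#' Multiplies each fluence bin by `exp(-mu(E) * thickness)`.  Chaining
#' filters is order-independent.
#'
#' @param spectrum An [energy_spectrum()].
#' @param material A material name or [material_attenuation()] object.
#' @param thickness_mm Slab thickness in mm (>= 0).
#' @return The filtered [energy_spectrum()] (not renormalized).
#' @export
filter_spectrum <- function(spectrum, material, thickness_mm) {
  if (thickness_mm < 0) stop("filter thickness must be nonnegative")
  if (thickness_mm == 0) return(spectrum)
  mu <- mu_linear(material, spectrum$energies)
  energy_spectrum(spectrum$energies,
                  spectrum$fluence * exp(-mu * thickness_mm))
}

#' Default filtered source spectrum
#'
#' Tube spectrum after the internal filtration stack: 0.75 mm beryllium,
#' 1 mm aluminum, and a 50 micron hafnium foil on the exit window.  At
#' 160 kVp this yields a band peaked below the hafnium K-edge (65.35 keV),
#' the quasi-monochromatic XRD illumination.
#'
#' @param kvp Tube voltage in kV (default 160, the XRD acquisition mode;
#'   use 80 for transmission mode).
#' @param be_mm,al_mm,hf_mm Filtration thicknesses in mm.
#' @return An [energy_spectrum()], renormalized to unit sum.
#' @export
default_source_spectrum <- function(kvp = 160, be_mm = 0.75, al_mm = 1,
                                    hf_mm = 0.05) {
  s <- bremsstrahlung_spectrum(kvp)
  s <- filter_spectrum(s, "beryllium", be_mm)
  s <- filter_spectrum(s, "aluminum", al_mm)
  s <- filter_spectrum(s, "hafnium", hf_mm)
  energy_spectrum(s$energies, s$fluence / sum(s$fluence))
}
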