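# Reference momentum-transfer spectra.  Crystalline materials are Bragg
# combs (lattice-derived line positions convolved with a Gaussian line
# width); amorphous and tissue-like materials are sums of 1-3 broad Gaussian
# humps with documented centers and widths.  Intensities are area-normalized
# densities; each material also carries a relative per-unit-thickness
# scatter strength used by the forward model.

# FCC aluminum, a = 4.0495 A.  q = 1/(2 d_hkl) = sqrt(h^2+k^2+l^2) / (2 a).
# Relative powder line intensities.
.AL_LATTICE_A <- 4.0495
.AL_HKL <- list(c(1, 1, 1), c(2, 0, 0), c(2, 2, 0), c(3, 1, 1), c(2, 2, 2))
.AL_REL_INT <- c(100, 47, 22, 24, 7)

#' Bragg line positions of fcc aluminum
#'
#' @return Named numeric vector of line positions in 1/Angstrom.
#' @export
aluminum_bragg_lines <- function() {
  q <- vapply(.AL_HKL, function(h) sqrt(sum(h^2)) / (2 * .AL_LATTICE_A),
              numeric(1))
  names(q) <- vapply(.AL_HKL, paste, character(1), collapse = "")
  q
}

# sum of Gaussians evaluated on q
.gauss_mix <- function(q, centers, sigmas, amps) {
  out <- numeric(length(q))
  for (i in seq_along(centers)) {
    out <- out + amps[i] * exp(-(q - centers[i])^2 / (2 * sigmas[i]^2))
  }
  out
}

# parameterized shapes; centers/sigmas in 1/A.  Tissue shapes follow the
# canonical coherent-scatter features: adipose peaked near 0.11, water and
# fibroglandular/cancer near 0.16 with differing widths and shoulder ratios.
.REF_SHAPES <- list(
  water = list(kind = "amorphous", centers = c(0.160, 0.285),
               sigmas = c(0.027, 0.045), amps = c(1, 0.18), strength = 1.0),
  pla = list(kind = "semicrystalline", centers = c(0.094, 0.115),
             sigmas = c(0.004, 0.035), amps = c(1, 0.55), strength = 0.85),
  aluminum = list(kind = "crystalline", strength = 2.5),
  adipose = list(kind = "amorphous", centers = 0.111, sigmas = 0.022,
                 amps = 1, strength = 0.95),
  fibroglandular = list(kind = "amorphous", centers = c(0.160, 0.111),
                        sigmas = c(0.032, 0.025), amps = c(1, 0.25),
                        strength = 1.0),
  cancer = list(kind = "amorphous", centers = c(0.161, 0.111),
                sigmas = c(0.026, 0.025), amps = c(1, 0.12), strength = 1.05),
  capsule_gel = list(kind = "amorphous", centers = 0.200, sigmas = 0.035,
                     amps = 1, strength = 1.1),
  air = list(kind = "none", strength = 0)
)

#' Materials with reference XRD spectra
#' @return Character vector of names accepted by [reference_spectrum()].
#' @export
reference_materials <- function() names(.REF_SHAPES)

#' Reference XRD spectrum of a material
#'
#' Deterministic parameterized spectrum evaluated on a momentum-transfer
#' grid.  Crystalline materials are Bragg combs convolved with
#' `crystalline_width`; line positions do not depend on the width.  `air`
#' is identically zero.
#'
#' @param name Material name (see [reference_materials()]).
#' @param qgrid A [q_grid()].
#' @param crystalline_width Gaussian line width (sigma, 1/Angstrom) applied
#'   to Bragg lines.  The default 0.003 approximates the instrumental line
#'   width of a commercial powder diffractometer at these q, so simulated
#'   ground truth plays the role of the reference measurement.
#' @return Object of class `xrd_spectrum_ref` with fields `name`, `q`
#'   (bin centers), `intensity` (area-normalized, >= 0) and `strength`
#'   (relative per-mm scatter strength).
#' @export
reference_spectrum <- function(name, qgrid = q_grid(),
                               crystalline_width = 0.003) {
  shape <- .REF_SHAPES[[name]]
  if (is.null(shape)) {
    stop("unknown reference material '", name, "'; known: ",
         paste(reference_materials(), collapse = ", "))
  }
  q <- qgrid$centers
  intensity <- switch(
    shape$kind,
    none = numeric(length(q)),
    crystalline = {
      lines <- aluminum_bragg_lines()
      .gauss_mix(q, lines, rep(crystalline_width, length(lines)),
                 .AL_REL_INT / max(.AL_REL_INT))
    },
    .gauss_mix(q, shape$centers, shape$sigmas, shape$amps)
  )
  dq <- diff(qgrid$edges)
  area <- sum(intensity * dq)
  if (area > 0) intensity <- intensity / area
  structure(
    list(name = name, q = q, intensity = intensity,
         strength = shape$strength),
    class = "xrd_spectrum_ref"
  )
}

#' @export
print.xrd_spectrum_ref <- function(x, ...) {
  pk <- if (any(x$intensity > 0)) sprintf("%.4f", x$q[which.max(x$intensity)])
        else "none"
  cat(sprintf("<xrd_spectrum_ref> %s: %d bins, peak at %s 1/A, strength %g\n",
              x$name, length(x$q), pk, x$strength))
  invisible(x)
}

#' Write a reference spectrum as two-column CSV
#'
#' Columns `q_invA`, `intensity`.
#' @param spec An `xrd_spectrum_ref` (or any list with `q` and `intensity`).
#' @param path Output CSV path.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(data.frame(q_invA = spec$q, intensity = spec$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column spectrum CSV
#'
#' @param path CSV with columns `q_invA`, `intensity`.
#' @param name Optional material label.
#' @return An `xrd_spectrum_ref` with strength `NA`.
#' @export
read_spectrum_csv <- function(path, name = NA_character_) {
  tab <- utils::read.csv(path)
  if (!all(c("q_invA", "intensity") %in% names(tab))) {
    stop("spectrum CSV must have columns q_invA, intensity")
  }
  structure(list(name = name, q = tab$q_invA, intensity = tab$intensity,
                 strength = NA_real_),
            class = "xrd_spectrum_ref")
}
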