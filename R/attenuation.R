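# Material attenuation.  Compact representative tabulations of the mass
# attenuation coefficient (photoelectric + scatter, 10-160 keV) are shipped
# as one CSV per material under extdata/attenuation; values are log-log
# interpolated between tabulated energies.  K-edges (Hf, W) are represented
# by closely spaced duplicate energies so the discontinuity survives
# interpolation.

# densities in g/cm^3; tissue-like and gel materials reuse the water table
# (their mass attenuation is water-like over this energy range) with their
# own density.
.MATERIAL_REGISTRY <- list(
  beryllium      = list(table = "beryllium", density = 1.848),
  aluminum       = list(table = "aluminum",  density = 2.699),
  copper         = list(table = "copper",    density = 8.960),
  hafnium        = list(table = "hafnium",   density = 13.31),
  tungsten       = list(table = "tungsten",  density = 19.30),
  water          = list(table = "water",     density = 1.000),
  pla            = list(table = "pla",       density = 1.240),
  adipose        = list(table = "water",     density = 0.950),
  fibroglandular = list(table = "water",     density = 1.040),
  cancer         = list(table = "water",     density = 1.050),
  capsule_gel    = list(table = "water",     density = 1.270),
  air            = list(table = "water",     density = 0.001205)
)

.attenuation_cache <- new.env(parent = emptyenv())

#' Materials with attenuation data
#'
#' @return Character vector of material names accepted by
#'   [material_attenuation()] and [line_attenuation()].
#' @export
attenuation_materials <- function() names(.MATERIAL_REGISTRY)

#' Read a mass attenuation table from CSV
#'
#' The expected format is two columns `energy_keV`, `mu_over_rho_cm2_g`.
#'
#' @param path Path to a CSV file.
#' @return Data frame with the two columns, energies increasing.
#' @export
read_attenuation_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("energy_keV", "mu_over_rho_cm2_g")
  if (!all(need %in% names(tab))) {
    stop("attenuation CSV must have columns ", paste(need, collapse = ", "))
  }
  tab <- tab[order(tab$energy_keV), need]
  if (any(tab$mu_over_rho_cm2_g <= 0)) stop("mu/rho must be positive")
  tab
}

#' Material attenuation description
#'
#' @param name Material name (see [attenuation_materials()]).
#' @return Object of class `material_attenuation` with fields `name`,
#'   `density` (g/cm^3) and `mu_over_rho` (data frame vs energy in keV).
#' @export
material_attenuation <- function(name) {
  entry <- .MATERIAL_REGISTRY[[name]]
  if (is.null(entry)) {
    stop("unknown material '", name, "'; known: ",
         paste(attenuation_materials(), collapse = ", "))
  }
  key <- entry$table
  if (is.null(.attenuation_cache[[key]])) {
    path <- system.file("extdata", "attenuation", paste0(key, ".csv"),
                        package = "fanxrd", mustWork = TRUE)
    .attenuation_cache[[key]] <- read_attenuation_csv(path)
  }
  structure(
    list(name = name, density = entry$density,
         mu_over_rho = .attenuation_cache[[key]]),
    class = "material_attenuation"
  )
}

#' Linear attenuation coefficient
#'
#' Log-log interpolated linear attenuation coefficient in 1/mm.
#'
#' @param material A [material_attenuation()] object or material name.
#' @param energy_kev Energies in keV (must lie within the tabulated range).
#' @return Numeric vector, `mu` in 1/mm.
#' @export
mu_linear <- function(material, energy_kev) {
  if (is.character(material)) material <- material_attenuation(material)
  tab <- material$mu_over_rho
  rng <- range(tab$energy_keV)
  if (any(energy_kev < rng[1]) || any(energy_kev > rng[2])) {
    stop(sprintf("energy outside tabulated range [%g, %g] keV for %s",
                 rng[1], rng[2], material$name))
  }
  logmu <- stats::approx(log(tab$energy_keV), log(tab$mu_over_rho_cm2_g),
                         xout = log(energy_kev), ties = "ordered")$y
  # cm^2/g * g/cm^3 = 1/cm; /10 -> 1/mm
  exp(logmu) * material$density / 10
}

#' Transmitted fraction along a ray
#'
#' Beer-Lambert product over a sequence of slabs:
#' `prod(exp(-mu_i(E) * t_i))`.
#'
#' @param materials Character vector of material names along the ray.
#' @param thicknesses_mm Slab thicknesses in mm (same length).
#' @param energy_kev Photon energy (scalar or vector) in keV.
#' @return Transmitted fraction in `(0, 1]`, vectorized over `energy_kev`.
#' @export
line_attenuation <- function(materials, thicknesses_mm, energy_kev) {
  if (length(materials) != length(thicknesses_mm)) {
    stop("materials and thicknesses must have equal length")
  }
  if (any(thicknesses_mm < 0)) stop("thicknesses must be nonnegative")
  out <- rep(1, length(energy_kev))
  for (i in seq_along(materials)) {
    if (thicknesses_mm[i] == 0) next
    out <- out * exp(-mu_linear(materials[i], energy_kev) * thicknesses_mm[i])
  }
  out
}
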