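# System configuration: one YAML file with sections for geometry, source,
# mask, detector, exposure (plus q grid, reconstruction and phantom
# sections used by the pipeline).  Unknown sections or keys are errors so
# typos cannot silently fall back to defaults.

#' Default system configuration
#'
#' The desk-scale scanner description: every geometry, source, mask,
#' detector and exposure parameter of the digital twin, overridable from a
#' YAML file via [load_config()].
#'
#' @return Nested list of class `system_config`.
#' @export
default_config <- function() {
  structure(list(
    geometry = list(
      z_object = 450, z_aperture = 600, z_detector = 800,
      fan_length = 150, fan_width = 1, voxel_pitch = 1
    ),
    source = list(
      kvp_xrd = 160, kvp_transmission = 80, e0_kev = 60, sigma_e = 0.75,
      be_mm = 0.75, al_mm = 1, hf_mm = 0.05
    ),
    mask = list(
      feature_size = 0.75, thickness = 3, extent_x = 228, extent_y = 132,
      open_fraction = 0.4, slit_width = 8, contrast_floor = 0.01,
      material = "copper", seed = 7
    ),
    detector = list(
      extent_x = 292, extent_y = 228, pixel_pitch = 0.5,
      scatter_ymin = 5, scatter_ymax = 65, beam_block_width = 10
    ),
    exposure = list(
      target_peak = 2500, background_rate = 2,
      xrd_exposure_s = 15, transmission_exposure_ms = 100
    ),
    qgrid = list(q_min = 0.04, q_max = 0.33, bin_width = 0.0025),
    reconstruction = list(n_iter = 150, tol = 1e-6),
    phantom = list(preset = "calibration_wells")
  ), class = "system_config")
}

# recursive merge of user values over defaults with unknown-key checking
.merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(base)) {
      stop("unknown config key: ", full)
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]])) stop("config section is not a map: ", full)
      base[[key]] <- .merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Load a YAML system configuration
#'
#' Reads a YAML file and merges it over [default_config()].  Unknown keys
#' raise an error naming them; `required` sections must be present in the
#' file.
#'
#' @param path YAML file path.
#' @param required Character vector of section names that must appear.
#' @return A `system_config`.
#' @export
load_config <- function(path, required = "geometry") {
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("config file is not a YAML map")
  missing <- setdiff(required, names(user))
  if (length(missing) > 0) {
    stop("config is missing required section(s): ",
         paste0("[", missing, "]", collapse = ", "))
  }
  structure(.merge_config(unclass(default_config()), user),
            class = "system_config")
}

#' Write a configuration to YAML
#'
#' @param cfg A `system_config`.
#' @param path Output file.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Geometry object from a configuration
#'
#' @param cfg A `system_config`.
#' @return A [system_geometry()].
#' @export
config_geometry <- function(cfg) {
  g <- cfg$geometry; d <- cfg$detector
  system_geometry(
    z_object = g$z_object, z_aperture = g$z_aperture,
    z_detector = g$z_detector, fan_length = g$fan_length,
    fan_width = g$fan_width, voxel_pitch = g$voxel_pitch,
    detector_extent_x = d$extent_x, detector_extent_y = d$extent_y,
    pixel_pitch = d$pixel_pitch, scatter_ymin = d$scatter_ymin,
    scatter_ymax = d$scatter_ymax, beam_block_width = d$beam_block_width
  )
}

#' Mask object from a configuration
#'
#' @param cfg A `system_config`.
#' @return A [generate_mask()] result.
#' @export
config_mask <- function(cfg) {
  m <- cfg$mask
  generate_mask(
    feature_size = m$feature_size, thickness = m$thickness,
    extent_x = m$extent_x, extent_y = m$extent_y,
    open_fraction = m$open_fraction, slit_width = m$slit_width,
    contrast_floor = m$contrast_floor, material = m$material, seed = m$seed
  )
}

#' Momentum-transfer grid from a configuration
#'
#' @param cfg A `system_config`.
#' @return A [q_grid()].
#' @export
config_qgrid <- function(cfg) {
  q <- cfg$qgrid
  q_grid(q$q_min, q$q_max, q$bin_width)
}
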