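# Programmatic phantoms.  A phantom is a 2D material-ID map (rows = scan
# direction y, cols = fan direction x) with a per-pixel thickness map in mm,
# at a grid pitch finer than the fan voxels so partial-volume mixing at
# feature boundaries emerges naturally when a slice is presented to the fan.

#' Construct a phantom
#'
#' @param material_map Integer matrix of indices into `materials`
#'   (rows = y/scan direction, cols = x/fan direction).
#' @param thickness_map Numeric matrix of per-pixel thickness in mm
#'   (same shape, all <= 10: the thin-sample regime).
#' @param pixel_size Grid pitch in mm.
#' @param materials Character vector legend; `material_map` values index it.
#' @param name Phantom label.
#' @param x_center Position of the phantom's x midline on the fan axis (mm).
#' @return Object of class `phantom`.
#' @export
phantom <- function(material_map, thickness_map, pixel_size = 0.25,
                    materials, name = "phantom", x_center = 0) {
  stopifnot(is.matrix(material_map), is.matrix(thickness_map),
            all(dim(material_map) == dim(thickness_map)), pixel_size > 0)
  if (any(thickness_map < 0) || any(thickness_map > 10)) {
    stop("thickness must be in [0, 10] mm (thin-sample regime)")
  }
  ids <- sort(unique(as.vector(material_map)))
  if (any(ids < 1) || any(ids > length(materials))) {
    stop("material_map indices must address the materials legend")
  }
  unknown <- setdiff(materials, reference_materials())
  if (length(unknown) > 0) {
    stop("materials not in the reference library: ",
         paste(unknown, collapse = ", "))
  }
  storage.mode(material_map) <- "integer"
  structure(
    list(material_map = material_map, thickness_map = thickness_map,
         pixel_size = pixel_size, materials = materials, name = name,
         x_center = x_center),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> '%s': %d x %d px at %g mm (%g x %g mm), materials: %s\n",
              x$name, nrow(x$material_map), ncol(x$material_map),
              x$pixel_size,
              ncol(x$material_map) * x$pixel_size,
              nrow(x$material_map) * x$pixel_size,
              paste(x$materials, collapse = ", ")))
  invisible(x)
}

#' Phantom extent
#'
#' @param p A [phantom()].
#' @return List with `x` and `y` ranges in mm.  x is centered on
#'   `x_center`; y starts at 0.
#' @export
phantom_extent <- function(p) {
  wx <- ncol(p$material_map) * p$pixel_size
  wy <- nrow(p$material_map) * p$pixel_size
  list(x = p$x_center + c(-wx / 2, wx / 2), y = c(0, wy))
}

#' Well calibration phantom
#'
#' A PLA slab spanning the fan with paired wells at evenly spaced fan
#' positions: at each position a signal well (filled with `fill` to the well
#' depth) and, offset along the scan direction, a background well left as
#' air.  Emulates a resolution/accuracy calibration object: the paired
#' empty wells allow background subtraction of the body's own scatter.
#'
#' @param n_pairs Number of well pairs.
#' @param well_size Well dimensions `c(x, y, depth)` in mm.
#' @param fill Signal-well material name.
#' @param span Fan extent over which pairs are evenly spaced (mm).
#' @param body_thickness Slab thickness in mm.
#' @param pixel_size Grid pitch in mm.
#' @return A [phantom()].  Attribute fields `well_centers_x` (signal/
#'   background x positions, mm on the fan axis), `signal_y`, `background_y`
#'   (scan positions of the well row centers, mm) are attached.
#' @export
make_well_phantom <- function(n_pairs = 12, well_size = c(1, 4, 3),
                              fill = "aluminum", span = 150,
                              body_thickness = 5, pixel_size = 0.25) {
  stopifnot(n_pairs >= 1, length(well_size) == 3, all(well_size > 0))
  if (well_size[3] > body_thickness) stop("well depth exceeds body thickness")
  spacing <- span / n_pairs
  centers <- (seq_len(n_pairs) - (n_pairs + 1) / 2) * spacing
  if (max(abs(centers)) + well_size[1] / 2 > span / 2) {
    stop("wells do not fit within the fan span")
  }
  ny <- round(12 / pixel_size)
  nx <- round(span / pixel_size)
  materials <- unique(c("pla", fill, "air"))
  fill_id <- match(fill, materials)
  air_id <- match("air", materials)
  fill_thk <- if (identical(fill, "air")) 0 else well_size[3]
  mat <- matrix(1L, nrow = ny, ncol = nx)
  thk <- matrix(body_thickness, nrow = ny, ncol = nx)
  xc <- (seq_len(nx) - (nx + 1) / 2) * pixel_size
  yc <- (seq_len(ny) - 0.5) * pixel_size
  signal_y <- 3.5; background_y <- 8.5
  for (cx in centers) {
    in_x <- abs(xc - cx) < well_size[1] / 2 - 1e-9
    for (wy in c(signal_y, background_y)) {
      in_y <- abs(yc - wy) < well_size[2] / 2 - 1e-9
      if (!any(in_x) || !any(in_y)) next
      idx <- which(outer(in_y, in_x, "&"))
      if (any(mat[idx] != 1L)) stop("overlapping wells")
      mat[idx] <- if (wy == signal_y) fill_id else air_id
      thk[idx] <- if (wy == signal_y) fill_thk else 0
    }
  }
  p <- phantom(mat, thk, pixel_size, materials, name = "well_phantom")
  p$well_centers_x <- centers
  p$signal_y <- signal_y
  p$background_y <- background_y
  p$fill <- fill
  p
}

#' Two-material phantom (body + shaped inset)
#'
#' A uniform body slab with an inset material replacing the body over the
#' pixels of a binary shape mask (e.g. a letter-shaped well filled with
#' water in a printed plastic body).
#'
#' @param shape_mask Logical/0-1 matrix marking inset pixels; its shape
#'   defines the phantom grid.
#' @param body,inset Material names.
#' @param body_thickness Body slab thickness in mm.
#' @param inset_depth Inset material thickness in mm
#'   (<= `body_thickness`).
#' @param pixel_size Grid pitch in mm.
#' @param name Phantom label.
#' @return A [phantom()].
#' @export
make_two_material_phantom <- function(shape_mask, body = "pla",
                                      inset = "water", body_thickness = 6.5,
                                      inset_depth = 5, pixel_size = 0.25,
                                      name = "two_material") {
  if (inset_depth > body_thickness) {
    stop("inset depth cannot exceed body thickness")
  }
  shape <- matrix(as.logical(shape_mask), nrow = nrow(shape_mask))
  mat <- matrix(1L, nrow = nrow(shape), ncol = ncol(shape))
  mat[shape] <- 2L
  thk <- matrix(body_thickness, nrow = nrow(shape), ncol = ncol(shape))
  thk[shape] <- inset_depth
  phantom(mat, thk, pixel_size, c(body, inset), name = name)
}

#' Letter-D shape mask
#'
#' Binary mask of a block letter "D" (vertical stroke plus semi-annular
#' bowl), used by the bundled two-material phantom preset.
#'
#' @param size_mm Square extent in mm.
#' @param pixel_size Grid pitch in mm.
#' @param stroke_mm Stroke width in mm.
#' @return Logical matrix.
#' @export
letter_d_mask <- function(size_mm = 30, pixel_size = 0.25, stroke_mm = 4) {
  n <- round(size_mm / pixel_size)
  xc <- (seq_len(n) - 0.5) * pixel_size
  yc <- (seq_len(n) - 0.5) * pixel_size
  x <- matrix(xc, nrow = n, ncol = n, byrow = TRUE)
  y <- matrix(yc, nrow = n, ncol = n)
  x0 <- 0.25 * size_mm; y0 <- size_mm / 2
  r_out <- 0.36 * size_mm
  bar <- x >= x0 - stroke_mm / 2 & x <= x0 + stroke_mm / 2 &
    abs(y - y0) <= r_out
  r <- sqrt((x - x0)^2 + (y - y0)^2)
  bowl <- x > x0 & r <= r_out & r >= r_out - stroke_mm
  bar | bowl
}

#' Present one scan position of a phantom to the fan beam
#'
#' Averages material occupancy over the beam thickness and, per fan voxel,
#' returns the material composition: each material's occupancy fraction and
#' occupancy-weighted mean thickness.  Scan positions outside the phantom
#' give an all-air slice.
#'
#' @param p A [phantom()].
#' @param y Scan position in mm (phantom y coordinates).
#' @param geometry A [system_geometry()].
#' @return Object of class `fan_slice`: list with `y`, `voxel_x` (centers)
#'   and `composition`, a list per voxel of data frames
#'   `(material, occupancy, thickness)`.
#' @export
slice_to_fan <- function(p, y, geometry) {
  vx <- fan_voxel_centers(geometry)
  half <- geometry$voxel_pitch / 2
  ext <- phantom_extent(p)
  yc <- (seq_len(nrow(p$material_map)) - 0.5) * p$pixel_size
  rows <- which(abs(yc - y) <= geometry$fan_width / 2 + 1e-9)
  xc <- p$x_center +
    (seq_len(ncol(p$material_map)) - (ncol(p$material_map) + 1) / 2) *
      p$pixel_size
  comp <- vector("list", length(vx))
  for (v in seq_along(vx)) {
    cols <- which(xc > vx[v] - half - 1e-9 & xc <= vx[v] + half + 1e-9)
    # pixels per voxel = voxel area / pixel area over the beam rows; pixels
    # outside the phantom count as air
    n_tot <- max(
      1L,
      round(geometry$voxel_pitch / p$pixel_size) *
        max(1L, round(geometry$fan_width / p$pixel_size))
    )
    if (length(rows) == 0 || length(cols) == 0) {
      comp[[v]] <- data.frame(material = "air", occupancy = 1, thickness = 0)
      next
    }
    ids <- as.vector(p$material_map[rows, cols, drop = FALSE])
    thk <- as.vector(p$thickness_map[rows, cols, drop = FALSE])
    mats <- p$materials[ids]
    agg_n <- tapply(thk, mats, length)
    agg_t <- tapply(thk, mats, mean)
    d <- data.frame(material = names(agg_n),
                    occupancy = as.numeric(agg_n) / n_tot,
                    thickness = as.numeric(agg_t))
    n_air <- n_tot - length(ids)
    if (n_air > 0) {
      if ("air" %in% d$material) {
        d$occupancy[d$material == "air"] <-
          d$occupancy[d$material == "air"] + n_air / n_tot
      } else {
        d <- rbind(d, data.frame(material = "air",
                                 occupancy = n_air / n_tot, thickness = 0))
      }
    }
    rownames(d) <- NULL
    comp[[v]] <- d
  }
  structure(list(y = y, voxel_x = vx, composition = comp),
            class = "fan_slice")
}

#' Dominant material per fan voxel
#'
#' @param slice A [slice_to_fan()] result.
#' @return Character vector, the highest-occupancy material per voxel.
#' @export
slice_dominant_material <- function(slice) {
  vapply(slice$composition, function(d) {
    d$material[which.max(d$occupancy)]
  }, character(1))
}

#' True per-voxel spectral coefficients for a fan slice
#'
#' The thin-sample linear model: each voxel's spectrum is the sum over its
#' material composition of occupancy x thickness x scatter strength x
#' reference spectrum shape.
#'
#' @param slice A [slice_to_fan()] result.
#' @param qgrid A [q_grid()].
#' @param crystalline_width Passed to [reference_spectrum()].
#' @return Matrix (fan voxel x q bin) of nonnegative coefficients.
#' @export
slice_true_spectra <- function(slice, qgrid, crystalline_width = 0.003) {
  n_q <- length(qgrid$centers)
  f <- matrix(0, nrow = length(slice$composition), ncol = n_q)
  refs <- new.env(parent = emptyenv())
  for (v in seq_along(slice$composition)) {
    d <- slice$composition[[v]]
    for (i in seq_len(nrow(d))) {
      m <- d$material[i]
      if (is.null(refs[[m]])) {
        refs[[m]] <- reference_spectrum(m, qgrid, crystalline_width)
      }
      r <- refs[[m]]
      f[v, ] <- f[v, ] +
        d$occupancy[i] * d$thickness[i] * r$strength * r$intensity
    }
  }
  f
}

#' Materials and thicknesses under a transmission ray
#'
#' Nearest-pixel lookup of (material, thickness) at given fan-axis
#' positions for one scan position; positions outside the phantom are air.
#'
#' @param p A [phantom()].
#' @param y Scan position in mm.
#' @param x Fan-axis positions in mm.
#' @return Data frame with columns `material` and `thickness`.
#' @export
slice_profile <- function(p, y, x) {
  ext <- phantom_extent(p)
  ny <- nrow(p$material_map); nx <- ncol(p$material_map)
  iy <- floor((y - ext$y[1]) / p$pixel_size) + 1
  ix <- floor((x - ext$x[1]) / p$pixel_size) + 1
  ok <- iy >= 1 & iy <= ny & ix >= 1 & ix <= nx
  material <- rep("air", length(x))
  thickness <- numeric(length(x))
  if (any(ok)) {
    idx <- cbind(rep(iy, length.out = length(x))[ok], ix[ok])
    material[ok] <- p$materials[p$material_map[idx]]
    thickness[ok] <- p$thickness_map[idx]
  }
  data.frame(material = material, thickness = thickness)
}

#' Write a phantom to a directory
#'
#' Plain-text container: `material_map.csv`, `thickness_map.csv` and a JSON
#' legend (`meta.json`) with materials, pixel size, name and position.
#'
#' @param p A [phantom()].
#' @param dir Output directory (created if needed).
#' @export
write_phantom <- function(p, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(p$material_map, file.path(dir, "material_map.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(format(p$thickness_map, digits = 17, trim = TRUE),
                     file.path(dir, "thickness_map.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(materials = p$materials, pixel_size = p$pixel_size,
               name = p$name, x_center = p$x_center)
  extra <- setdiff(names(p), c("material_map", "thickness_map", "pixel_size",
                               "materials", "name", "x_center"))
  meta$extra <- p[extra]
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param dir Directory path.
#' @return A [phantom()].
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(file.path(dir, "material_map.csv"),
                                     sep = ","))
  thk <- as.matrix(utils::read.table(file.path(dir, "thickness_map.csv"),
                                     sep = ","))
  dimnames(mat) <- NULL; dimnames(thk) <- NULL
  storage.mode(mat) <- "integer"
  storage.mode(thk) <- "double"
  p <- phantom(mat, thk, meta$pixel_size, meta$materials, meta$name,
               meta$x_center)
  for (nm in names(meta$extra)) {
    x <- meta$extra[[nm]]
    p[[nm]] <- if (is.integer(x)) as.numeric(x) else x
  }
  p
}
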