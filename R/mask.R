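# The coded aperture: a random binary pattern of square features in a thick
# copper plate, with a fully open central slit for the primary fan beam.
# Closed cells transmit at the plate's modulation-contrast floor; oblique
# rays see extra closed material because a chord through the plate can cross
# neighboring cells (thickness collimation).

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded component generators do not disturb the
#' global stream.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a coded-aperture mask
#'
#' A 2D random binary pattern: among the non-slit cells, exactly
#' `round(open_fraction * N)` are open, placed by a seeded shuffle.  The
#' central horizontal band of width `slit_width` (the fan-beam slit) is
#' fully open and excluded from the open-fraction bookkeeping.
#'
#' @param feature_size Square feature edge in mm.
#' @param thickness Plate thickness in mm.
#' @param extent_x,extent_y Plate extent in mm (centered on the beam axis).
#' @param open_fraction Target fraction of open non-slit cells in (0, 1].
#' @param slit_width Width of the central open slit band in mm.
#' @param contrast_floor Minimum transmission through a fully closed chord
#'   at the effective energy (the plate's modulation contrast is
#'   `1 / contrast_floor`).
#' @param material Closed-cell material name (bookkeeping only; the
#'   operative contrast is `contrast_floor`).
#' @param seed Integer seed; the grid is reproducible from it.
#' @return Object of class `coded_aperture` with fields `grid` (rows = y,
#'   cols = x, 1 = open), cell center coordinates, and the parameters above.
#' @export
generate_mask <- function(feature_size = 0.75, thickness = 3,
                          extent_x = 228, extent_y = 132,
                          open_fraction = 0.4, slit_width = 8,
                          contrast_floor = 0.01, material = "copper",
                          seed = 1) {
  stopifnot(feature_size > 0, thickness > 0, extent_x > 0, extent_y > 0,
            open_fraction > 0, open_fraction <= 1, slit_width >= 0,
            contrast_floor > 0, contrast_floor < 1)
  nx <- ceiling(extent_x / feature_size)
  ny <- ceiling(extent_y / feature_size)
  xc <- (seq_len(nx) - (nx + 1) / 2) * feature_size
  yc <- (seq_len(ny) - (ny + 1) / 2) * feature_size
  slit_rows <- which(abs(yc) <= slit_width / 2)
  grid <- matrix(0L, nrow = ny, ncol = nx)
  grid[slit_rows, ] <- 1L
  non_slit <- setdiff(seq_len(ny), slit_rows)
  n_cells <- length(non_slit) * nx
  n_open <- round(open_fraction * n_cells)
  open_idx <- with_seed(seed, sample.int(n_cells, n_open))
  sub <- matrix(0L, nrow = length(non_slit), ncol = nx)
  sub[open_idx] <- 1L
  grid[non_slit, ] <- sub
  structure(
    list(grid = grid, x_centers = xc, y_centers = yc,
         feature_size = feature_size, thickness = thickness,
         open_fraction = open_fraction, slit_width = slit_width,
         contrast_floor = contrast_floor, material = material,
         slit_rows = slit_rows, seed = seed),
    class = "coded_aperture"
  )
}

#' @export
print.coded_aperture <- function(x, ...) {
  cat(sprintf(
    "<coded_aperture> %d x %d cells of %g mm, %g mm plate, slit %g mm, seed %d\n",
    nrow(x$grid), ncol(x$grid), x$feature_size, x$thickness, x$slit_width,
    x$seed
  ))
  cat(sprintf("  open fraction (non-slit): %.4f\n", mask_open_fraction(x)))
  invisible(x)
}

#' Achieved open fraction of a mask
#'
#' Fraction of open cells among the non-slit cells.
#'
#' @param mask A [generate_mask()] result.
#' @return Scalar in (0, 1].
#' @export
mask_open_fraction <- function(mask) {
  non_slit <- setdiff(seq_len(nrow(mask$grid)), mask$slit_rows)
  mean(mask$grid[non_slit, ])
}

#' Collimation angular rejection
#'
#' The obliquity beyond which no ray can traverse a single open cell
#' untouched: `atan(feature_size / thickness)` in degrees.
#'
#' @param mask A [generate_mask()] result.
#' @return Angle in degrees.
#' @export
angular_rejection <- function(mask) {
  atan(mask$feature_size / mask$thickness) * 180 / pi
}

# cell lookup: 1 = open, 0 = closed, outside grid = closed (conservative)
.mask_cell_open <- function(mask, x, y) {
  fx <- mask$feature_size
  nx <- ncol(mask$grid); ny <- nrow(mask$grid)
  ix <- floor(x / fx + nx / 2) + 1
  iy <- floor(y / fx + ny / 2) + 1
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  open <- logical(length(x))
  open[ok] <- mask$grid[cbind(iy[ok], ix[ok])] == 1L
  open
}

#' Ray transmission through the coded aperture
#'
#' Traces a chord through the plate thickness and attenuates by the path
#' length crossing closed cells, floored at `contrast_floor`.  The chord is
#' sampled at `n_samples` depths; rays leaving the plate extent are treated
#' as fully closed.  Vectorized over rays.
#'
#' @param mask A [generate_mask()] result.
#' @param entry_x,entry_y Ray entry point on the plate front face (mm, plate
#'   coordinates centered on the beam axis).
#' @param dir_x,dir_y,dir_z Ray direction (need not be normalized;
#'   `dir_z > 0` toward the detector).
#' @param n_samples Chord samples through the thickness.
#' @return Transmission fraction in `[contrast_floor, 1]` per ray (exactly 1
#'   for an all-open chord).
#' @export
ray_transmission <- function(mask, entry_x, entry_y,
                             dir_x = 0, dir_y = 0, dir_z = 1,
                             n_samples = 11) {
  n <- length(entry_x)
  stopifnot(length(entry_y) == n)
  dir_x <- rep_len(dir_x, n); dir_y <- rep_len(dir_y, n)
  dir_z <- rep_len(dir_z, n)
  if (any(dir_z <= 0)) stop("rays must travel toward the detector (dir_z > 0)")
  thk <- mask$thickness
  # chord length through the plate and per-depth lateral offsets
  chord <- thk * sqrt(dir_x^2 + dir_y^2 + dir_z^2) / dir_z
  closed_frac <- numeric(n)
  zs <- (seq_len(n_samples) - 0.5) / n_samples * thk
  for (z in zs) {
    px <- entry_x + dir_x / dir_z * z
    py <- entry_y + dir_y / dir_z * z
    closed_frac <- closed_frac + !.mask_cell_open(mask, px, py)
  }
  closed_frac <- closed_frac / n_samples
  mu_eff <- -log(mask$contrast_floor) / thk
  pmax(exp(-mu_eff * closed_frac * chord), mask$contrast_floor)
}

#' Write a mask to disk
#'
#' The binary grid is written as a CSV of 0/1 plus a JSON sidecar holding
#' feature size, thickness, slit width, contrast floor and seed.
#'
#' @param mask A [generate_mask()] result.
#' @param path Basename for output; writes `<path>.csv` and `<path>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_mask <- function(mask, path) {
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  utils::write.table(mask$grid, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- mask[c("feature_size", "thickness", "open_fraction", "slit_width",
                 "contrast_floor", "material", "seed")]
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Read a mask written by [write_mask()]
#'
#' @param path Basename used in [write_mask()].
#' @return A `coded_aperture` object.
#' @export
read_mask <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  nx <- ncol(grid); ny <- nrow(grid)
  fx <- meta$feature_size
  yc <- (seq_len(ny) - (ny + 1) / 2) * fx
  structure(
    list(grid = grid,
         x_centers = (seq_len(nx) - (nx + 1) / 2) * fx,
         y_centers = yc,
         feature_size = fx, thickness = meta$thickness,
         open_fraction = meta$open_fraction, slit_width = meta$slit_width,
         contrast_floor = meta$contrast_floor, material = meta$material,
         slit_rows = which(abs(yc) <= meta$slit_width / 2), seed = meta$seed),
    class = "coded_aperture"
  )
}
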