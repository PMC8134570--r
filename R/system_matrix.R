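# The measurement model.  For each fan voxel and momentum-transfer bin the
# scatter cone is traced to the detector by a dense per-pixel angle
# computation: every scatter-band pixel is assigned the q bin of its exact
# scattering angle from that voxel, weighted by pixel solid angle, the
# coded-aperture transmission of the voxel-to-pixel ray, and the Thomson
# polarization factor.  Scatter is monoenergetic at the effective energy E0;
# polychromatic blur is emulated separately by a q-smearing kernel.

# cheap structural signatures used to guard scan/matrix pairings
.geometry_signature <- function(geometry) {
  paste(format(unlist(geometry), digits = 12), collapse = "|")
}
.mask_signature <- function(mask) {
  paste(mask$seed, mask$feature_size, mask$thickness, mask$slit_width,
        mask$contrast_floor, nrow(mask$grid), ncol(mask$grid),
        sum(mask$grid), sep = "|")
}

#' Scatter-band detector pixel grid
#'
#' Pixel centers of the scatter readout band (both sides of the fan
#' projection, outside the beam block).
#'
#' @param geometry A [system_geometry()].
#' @return List with vectors `x`, `y` (mm, one entry per pixel), and the
#'   row/column layout (`nx`, `ny`, `x_centers`, `y_centers`).
#' @keywords internal
scatter_pixel_grid <- function(geometry) {
  p <- geometry$pixel_pitch
  nx <- floor(geometry$detector_extent_x / p)
  xc <- (seq_len(nx) - (nx + 1) / 2) * p
  yc <- seq(geometry$scatter_ymin + p / 2, geometry$scatter_ymax - p / 2,
            by = p)
  list(x = rep(xc, times = length(yc)),
       y = rep(yc, each = nx),
       nx = nx, ny = length(yc), x_centers = xc, y_centers = yc)
}

#' Build the system matrix
#'
#' Sparse nonnegative map from (fan voxel, q bin) coefficients to expected
#' detector counts in the scatter band.
#'
#' @param geometry A [system_geometry()].
#' @param mask A [generate_mask()]; must cover the scatter footprint at the
#'   aperture plane.
#' @param qgrid A [q_grid()].
#' @param e0_kev Effective (quasi-monochromatic) scatter energy in keV.
#' @return Object of class `system_matrix`: `H` (dgCMatrix, pixels x
#'   (voxel, q) columns, q fastest), pixel coordinates, `qgrid`, `e0_kev`,
#'   voxel centers and provenance signatures.
#' @export
build_system_matrix <- function(geometry, mask, qgrid = q_grid(),
                                e0_kev = 60) {
  px <- scatter_pixel_grid(geometry)
  vx <- fan_voxel_centers(geometry)
  n_q <- length(qgrid$centers)
  n_pix <- length(px$x)
  lambda <- wavelength_from_energy(e0_kev)
  dz <- geometry$z_detector - geometry$z_object
  s_ap <- (geometry$z_aperture - geometry$z_object) / dz
  area <- geometry$pixel_pitch^2
  # mask must cover the widest aperture-plane footprint
  max_x_ap <- (1 - s_ap) * max(abs(vx)) + s_ap * max(abs(px$x))
  max_y_ap <- s_ap * max(abs(px$y))
  if (max_x_ap > max(abs(mask$x_centers)) + mask$feature_size / 2 ||
      max_y_ap > max(abs(mask$y_centers)) + mask$feature_size / 2) {
    stop("mask extent smaller than the scatter footprint for this geometry")
  }
  trip_i <- vector("list", length(vx))
  trip_j <- vector("list", length(vx))
  trip_x <- vector("list", length(vx))
  for (v in seq_along(vx)) {
    dx <- px$x - vx[v]
    dy <- px$y
    dn2 <- dx^2 + dy^2 + dz^2
    dn <- sqrt(dn2)
    # primary ray direction at this voxel (source at origin)
    un <- sqrt(vx[v]^2 + geometry$z_object^2)
    cos_t <- (dx * vx[v] + dz * geometry$z_object) / (dn * un)
    cos_t <- pmin(1, pmax(-1, cos_t))
    theta <- acos(cos_t)
    q <- sin(theta / 2) / lambda
    bin <- findInterval(q, qgrid$edges)
    keep <- which(bin >= 1 & bin <= n_q)
    if (length(keep) == 0) next
    entry_x <- vx[v] + dx[keep] * s_ap
    entry_y <- dy[keep] * s_ap
    trans <- ray_transmission(mask, entry_x, entry_y,
                              dir_x = dx[keep], dir_y = dy[keep], dir_z = dz)
    w <- area * dz / (dn[keep] * dn2[keep]) *
      trans * (1 + cos_t[keep]^2) / 2
    trip_i[[v]] <- keep
    trip_j[[v]] <- (v - 1L) * n_q + bin[keep]
    trip_x[[v]] <- w
  }
  H <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(n_pix, length(vx) * n_q)
  )
  col_sums <- Matrix::colSums(H)
  design <- rep(
    qgrid$centers >= 0.05 & qgrid$centers <= 0.3, times = length(vx)
  )
  if (any(col_sums[design] <= 0)) {
    stop("empty system-matrix columns inside the design q range: ",
         "a scatter ring misses the detector for this geometry")
  }
  structure(
    list(H = H, pixel_x = px$x, pixel_y = px$y, pixel_layout = px,
         voxel_x = vx, qgrid = qgrid, e0_kev = e0_kev,
         geometry = geometry,
         geometry_sig = .geometry_signature(geometry),
         mask_sig = .mask_signature(mask)),
    class = "system_matrix"
  )
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf(
    "<system_matrix> %d pixels x (%d voxels * %d q bins), %.3g%% dense, E0 = %g keV\n",
    nrow(x$H), length(x$voxel_x), length(x$qgrid$centers),
    100 * Matrix::nnzero(x$H) / prod(dim(x$H)), x$e0_kev
  ))
  invisible(x)
}

#' Momentum-transfer smearing kernel
#'
#' Column-normalized Gaussian kernel emulating polychromatic blur: a line at
#' q spreads with `sigma(q) = q * sigma_e / e0`.  With `sigma_e = 0` the
#' kernel is the identity.
#'
#' @param qgrid A [q_grid()].
#' @param e0_kev Effective energy in keV.
#' @param sigma_e Effective spectral width (sigma) in keV.
#' @return Dense matrix (q bin x q bin); columns sum to 1.
#' @export
q_smear_matrix <- function(qgrid, e0_kev = 60, sigma_e = 0.75) {
  n <- length(qgrid$centers)
  if (sigma_e <= 0) return(diag(n))
  qc <- qgrid$centers
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- qc[j] * sigma_e / e0_kev
    k <- exp(-(qc - qc[j])^2 / (2 * s^2))
    S[, j] <- k / sum(k)
  }
  S
}

#' Apply the smearing kernel to per-voxel spectra
#'
#' @param f Matrix (voxel x q bin).
#' @param S Kernel from [q_smear_matrix()].
#' @return Smeared matrix, same shape.
#' @export
smear_spectra <- function(f, S) f %*% t(S)

#' Expected scatter frame
#'
#' Mean detector counts for per-voxel spectral coefficients: `flux * H f +
#' background`.
#'
#' @param sm A [build_system_matrix()] result.
#' @param f Matrix (voxel x q bin) of nonnegative coefficients.
#' @param flux_scale Photon-flux scale factor.
#' @param background_rate Expected background counts per pixel.
#' @return Numeric vector of expected counts, one per scatter-band pixel.
#' @export
expected_scatter <- function(sm, f, flux_scale = 1, background_rate = 0) {
  if (any(f < 0)) stop("spectral coefficients must be nonnegative")
  stopifnot(nrow(f) == length(sm$voxel_x),
            ncol(f) == length(sm$qgrid$centers))
  as.numeric(flux_scale * (sm$H %*% as.vector(t(f))) + background_rate)
}

#' Flux scale reaching a target peak count
#'
#' @param sm A [build_system_matrix()] result.
#' @param f Matrix (voxel x q bin), typically the smeared true spectra of
#'   the brightest slice.
#' @param target_peak Desired peak expected count per pixel (the hardware
#'   operating point is about 2500).
#' @return Scalar flux multiplier.
#' @export
calibrate_flux <- function(sm, f, target_peak = 2500) {
  mx <- max(expected_scatter(sm, f))
  if (mx <= 0) stop("cannot calibrate flux against an all-zero scene")
  target_peak / mx
}

#' Simulate a Poisson-noisy scatter frame
#'
#' Counts are drawn as `Poisson(flux * H f + background)`, seeded and
#' reproducible.
#'
#' @inheritParams expected_scatter
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @param noise If `FALSE`, returns the expected (mean) frame unsampled.
#' @return Object of class `detector_frame` (mode `"scatter"`) with integer
#'   `counts` per scatter-band pixel.
#' @export
simulate_scatter_frame <- function(sm, f, flux_scale = 1,
                                   background_rate = 0, seed = NULL,
                                   noise = TRUE) {
  if (background_rate < 0) stop("background rate must be nonnegative")
  mu <- expected_scatter(sm, f, flux_scale, background_rate)
  counts <- if (!noise) {
    mu
  } else if (is.null(seed)) {
    stats::rpois(length(mu), mu)
  } else {
    with_seed(seed, stats::rpois(length(mu), mu))
  }
  structure(
    list(counts = counts, mode = "scatter", layout = sm$pixel_layout,
         exposure = 15, flux_scale = flux_scale,
         background_rate = background_rate, seed = seed),
    class = "detector_frame"
  )
}

#' @export
print.detector_frame <- function(x, ...) {
  cat(sprintf("<detector_frame> mode %s, %d pixels, max %g\n",
              x$mode, length(x$counts), max(x$counts)))
  invisible(x)
}

#' Reshape a scatter frame to a 2D image
#'
#' @param frame A `detector_frame` from [simulate_scatter_frame()].
#' @return Matrix (rows = detector y, cols = detector x).
#' @export
frame_as_matrix <- function(frame) {
  matrix(frame$counts, nrow = frame$layout$ny, ncol = frame$layout$nx,
         byrow = TRUE)
}

#' Write a system matrix to a directory
#'
#' Sparse triplet container: `triplets.csv` (row, col, value) plus a JSON
#' attribute file carrying the pixel layout, q grid, voxel centers and the
#' geometry/mask signatures that key the cache.
#'
#' @param sm A [build_system_matrix()] result.
#' @param dir Output directory.
#' @export
write_system_matrix <- function(sm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trip <- Matrix::summary(sm$H)
  utils::write.table(
    data.frame(i = trip$i, j = trip$j,
               x = format(trip$x, digits = 17, trim = TRUE)),
    file.path(dir, "triplets.csv"),
    sep = ",", row.names = FALSE, quote = FALSE
  )
  meta <- list(
    dims = dim(sm$H), pixel_layout = sm$pixel_layout,
    voxel_x = sm$voxel_x, q_edges = sm$qgrid$edges, e0_kev = sm$e0_kev,
    geometry = unclass(sm$geometry),
    geometry_sig = sm$geometry_sig, mask_sig = sm$mask_sig
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a system matrix written by [write_system_matrix()]
#'
#' @param dir Directory path.
#' @return A `system_matrix`.
#' @export
read_system_matrix <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  trip <- utils::read.csv(file.path(dir, "triplets.csv"))
  H <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = meta$dims)
  edges <- meta$q_edges
  qg <- q_grid(edges[1], edges[length(edges)], edges[2] - edges[1])
  geometry <- do.call(system_geometry, as.list(meta$geometry))
  layout <- meta$pixel_layout
  structure(
    list(H = H, pixel_x = layout$x, pixel_y = layout$y,
         pixel_layout = layout, voxel_x = meta$voxel_x, qgrid = qg,
         e0_kev = meta$e0_kev, geometry = geometry,
         geometry_sig = meta$geometry_sig, mask_sig = meta$mask_sig),
    class = "system_matrix"
  )
}

#' Build a system matrix with a disk cache
#'
#' Loads a previously written matrix when the cached geometry and mask
#' signatures match; otherwise builds and caches it.
#'
#' @inheritParams build_system_matrix
#' @param cache_dir Cache directory.
#' @return A `system_matrix`.
#' @export
cached_system_matrix <- function(geometry, mask, qgrid = q_grid(),
                                 e0_kev = 60, cache_dir) {
  meta_path <- file.path(cache_dir, "meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (identical(meta$geometry_sig, .geometry_signature(geometry)) &&
        identical(meta$mask_sig, .mask_signature(mask)) &&
        isTRUE(all.equal(meta$q_edges, qgrid$edges)) &&
        identical(as.numeric(meta$e0_kev), as.numeric(e0_kev))) {
      return(read_system_matrix(cache_dir))
    }
  }
  sm <- build_system_matrix(geometry, mask, qgrid, e0_kev)
  write_system_matrix(sm, cache_dir)
  sm
}
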