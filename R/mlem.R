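# Poisson maximum-likelihood reconstruction.  The classic MLEM
# (Richardson-Lucy) multiplicative update recovers nonnegative per-voxel
# spectral coefficients from an encoded scatter frame:
#   f <- (f / H^T 1) * H^T( m / (H f + b) )
# The Poisson log-likelihood is non-decreasing at every iteration and
# nonnegativity is preserved exactly.

#' MLEM spectral estimate for one fan slice
#'
#' @param H Sparse nonnegative forward operator (pixels x coefficients), a
#'   `system_matrix` or a plain matrix/`dgCMatrix`.
#' @param m Measured counts (nonnegative, one per pixel/row).
#' @param b Expected background per pixel (scalar or vector, >= 0).
#' @param n_iter Maximum iterations.
#' @param init Initial coefficients (positive); default uniform 1.
#' @param tol Stop when the relative log-likelihood change drops below this.
#' @param keep_loglik Record the log-likelihood at every iteration (always
#'   recorded at the iterations actually run; this flag only controls the
#'   full trace when stopping early).
#' @return Object of class `fan_estimate`: `f_hat` (coefficient vector, or
#'   voxel x q matrix when `H` is a `system_matrix`), `iterations`,
#'   `loglik` (trace), `converged`, and `frozen` (indices of coefficients
#'   with negligible sensitivity, held at zero).
#' @export
mlem <- function(H, m, b = 0, n_iter = 150, init = NULL, tol = 1e-6,
                 keep_loglik = TRUE) {
  sm <- NULL
  if (inherits(H, "system_matrix")) {
    sm <- H
    H <- H$H
  }
  m <- as.numeric(m)
  if (any(m < 0)) stop("measured counts must be nonnegative")
  if (any(b < 0)) stop("background must be nonnegative")
  if (length(b) == 1) b <- rep(b, length(m))
  stopifnot(nrow(H) == length(m), length(b) == length(m))
  sens <- as.numeric(Matrix::colSums(H))
  frozen <- which(sens < 1e-12 * max(sens))
  sens_safe <- ifelse(sens > 0, sens, 1)
  f <- if (is.null(init)) rep(1, ncol(H)) else as.numeric(init)
  if (any(f < 0)) stop("initial coefficients must be nonnegative")
  f[frozen] <- 0
  if (all(m == 0)) {
    warning("all-zero measurement: returning zero estimate")
    f <- numeric(ncol(H))
    return(.fan_estimate(f, sm, 0L, NA_real_, TRUE, frozen))
  }
  loglik <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  tH <- Matrix::t(H)
  for (it in seq_len(n_iter)) {
    lambda <- as.numeric(H %*% f) + b
    pos <- lambda > 0
    ll <- sum(m[pos] * log(lambda[pos])) - sum(lambda)
    if (keep_loglik) loglik <- c(loglik, ll)
    ratio <- numeric(length(m))
    ratio[pos] <- m[pos] / lambda[pos]
    f <- f / sens_safe * as.numeric(tH %*% ratio)
    f[frozen] <- 0
    if (is.finite(ll) && is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  .fan_estimate(f, sm, it, if (length(loglik)) loglik else NA_real_,
                converged, frozen)
}

.fan_estimate <- function(f, sm, iterations, loglik, converged, frozen) {
  f_hat <- if (!is.null(sm)) {
    matrix(f, nrow = length(sm$voxel_x), ncol = length(sm$qgrid$centers),
           byrow = TRUE)
  } else f
  structure(
    list(f_hat = f_hat, iterations = iterations, loglik = loglik,
         converged = converged, frozen = frozen,
         q = if (!is.null(sm)) sm$qgrid$centers else NULL,
         voxel_x = if (!is.null(sm)) sm$voxel_x else NULL),
    class = "fan_estimate"
  )
}

#' @export
print.fan_estimate <- function(x, ...) {
  ll <- x$loglik[length(x$loglik)]
  cat(sprintf("<fan_estimate> %s, %d iterations, final loglik %.6g%s\n",
              paste(dim(as.matrix(x$f_hat)), collapse = " x "),
              x$iterations, ll,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Reconstruct a full scan into a hyperspectral datacube
#'
#' Runs [mlem()] per slice and stacks the fan estimates in translation
#' order.  The background rate is estimated from the bracketing air scatter
#' frames (their per-pixel mean).
#'
#' @param scan A [assemble_scan()] result.
#' @param sm The [build_system_matrix()] the scan was simulated with (the
#'   geometry/mask signatures must match).
#' @param n_iter,tol,init Passed to [mlem()].
#' @param verbose Print per-slice progress.
#' @return Object of class `xrd_datacube`: `cube` (slice x voxel x q bin),
#'   `q`, `voxel_x`, `slice_y`, the co-registered normalized transmission
#'   image, and provenance.
#' @export
reconstruct_scan <- function(scan, sm, n_iter = 150, tol = 1e-6,
                             init = NULL, verbose = FALSE) {
  if (!identical(scan$geometry_sig, sm$geometry_sig) ||
      !identical(scan$mask_sig, sm$mask_sig)) {
    stop("scan and system matrix were built for different geometry/mask")
  }
  b <- mean(c(scan$air_scatter[[1]]$counts, scan$air_scatter[[2]]$counts))
  n_slices <- length(scan$slice_y)
  cube <- array(0, dim = c(n_slices, length(sm$voxel_x),
                           length(sm$qgrid$centers)))
  iters <- integer(n_slices)
  for (i in seq_len(n_slices)) {
    est <- mlem(sm, scan$scatter[[i]]$counts, b = b, n_iter = n_iter,
                tol = tol, init = init, keep_loglik = FALSE)
    cube[i, , ] <- est$f_hat
    iters[i] <- est$iterations
    if (verbose) {
      message(sprintf("slice %d/%d: %d iterations", i, n_slices,
                      est$iterations))
    }
  }
  structure(
    list(cube = cube, q = sm$qgrid$centers, voxel_x = sm$voxel_x,
         slice_y = scan$slice_y,
         transmission = scan_transmission_image(scan),
         background = b, iterations = iters,
         flux_scale = scan$flux_scale, seed = scan$seed,
         geometry_sig = sm$geometry_sig, mask_sig = sm$mask_sig),
    class = "xrd_datacube"
  )
}

#' @export
print.xrd_datacube <- function(x, ...) {
  cat(sprintf("<xrd_datacube> %d slices x %d voxels x %d q bins\n",
              dim(x$cube)[1], dim(x$cube)[2], dim(x$cube)[3]))
  invisible(x)
}

#' Paired background subtraction of voxel spectra
#'
#' Elementwise difference of a signal voxel's spectrum and a background
#' voxel's spectrum, clipped at zero (the paired-well scheme that removes
#' the body material's own scatter).
#'
#' @param cube An `xrd_datacube` (or an array indexed the same way).
#' @param signal Integer vector `c(slice, voxel)` of the signal voxel.
#' @param background Integer vector `c(slice, voxel)` of the background
#'   voxel.
#' @return Nonnegative numeric vector over q bins.
#' @export
background_spectrum_subtract <- function(cube, signal, background) {
  arr <- if (inherits(cube, "xrd_datacube")) cube$cube else cube
  pmax(arr[signal[1], signal[2], ] - arr[background[1], background[2], ], 0)
}

#' Write a datacube to a directory
#'
#' Plain-text container: one CSV per slice (voxel x q bin), `q_centers.csv`,
#' the transmission image, and a JSON attribute file.
#'
#' @param cube An `xrd_datacube`.
#' @param dir Output directory.
#' @export
write_datacube <- function(cube, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(q_invA = cube$q), file.path(dir, "q_centers.csv"),
                   row.names = FALSE)
  for (i in seq_len(dim(cube$cube)[1])) {
    utils::write.table(
      format(cube$cube[i, , ], digits = 17, trim = TRUE),
      file.path(dir, sprintf("slice_%04d.csv", i)),
      sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  utils::write.table(
    format(cube$transmission$image, digits = 17, trim = TRUE),
    file.path(dir, "transmission.csv"),
    sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  meta <- cube[c("q", "voxel_x", "slice_y", "background", "iterations",
                 "flux_scale", "seed", "geometry_sig", "mask_sig")]
  meta$transmission_x <- cube$transmission$x
  meta$transmission_y <- cube$transmission$y
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA)
  invisible(dir)
}

#' Read a datacube written by [write_datacube()]
#'
#' @param dir Directory path.
#' @return An `xrd_datacube`.
#' @export
read_datacube <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  slices <- sort(list.files(dir, pattern = "^slice_\\d+\\.csv$",
                            full.names = TRUE))
  mats <- lapply(slices, function(f) {
    m <- as.matrix(utils::read.table(f, sep = ","))
    dimnames(m) <- NULL
    m
  })
  cube <- array(0, dim = c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (i in seq_along(mats)) cube[i, , ] <- mats[[i]]
  timg <- as.matrix(utils::read.table(file.path(dir, "transmission.csv"),
                                      sep = ","))
  dimnames(timg) <- NULL
  structure(
    list(cube = cube, q = meta$q, voxel_x = meta$voxel_x,
         slice_y = meta$slice_y,
         transmission = list(image = timg, x = meta$transmission_x,
                             y = meta$transmission_y),
         background = meta$background, iterations = meta$iterations,
         flux_scale = meta$flux_scale, seed = meta$seed,
         geometry_sig = meta$geometry_sig, mask_sig = meta$mask_sig),
    class = "xrd_datacube"
  )
}
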