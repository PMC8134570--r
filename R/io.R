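# Image export: detector frames as 16-bit grayscale TIFF with a JSON
# sidecar, RGB products as PNG.  Both formats are optional (Suggests); the
# plain-text containers in write_datacube()/write_phantom() carry the full
# numeric state.

#' Write a detector frame as 16-bit TIFF
#'
#' Counts are scaled into the 16-bit range by `scale_max` (default: the
#' frame maximum) and written with a JSON sidecar recording mode, exposure,
#' seed and the scale factor.
#'
#' @param frame A `detector_frame`.
#' @param path Output path ending in `.tif`.
#' @param scale_max Count value mapped to the 16-bit maximum.
#' @return Invisibly, the TIFF path.
#' @export
write_frame_tiff <- function(frame, path, scale_max = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF frames")
  }
  img <- frame_as_matrix(frame)
  if (is.null(scale_max)) scale_max <- max(img, 1)
  tiff::writeTIFF(pmin(img / scale_max, 1), path, bits.per.sample = 16L)
  sidecar <- list(mode = frame$mode, exposure = frame$exposure,
                  seed = frame$seed, scale_max = scale_max,
                  flux_scale = frame$flux_scale,
                  background_rate = frame$background_rate)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write an RGB image array as PNG
#'
#' @param rgb Array (rows x cols x 3) in `[0, 1]`.
#' @param path Output path ending in `.png`.
#' @return Invisibly, the path.
#' @export
write_rgb_png <- function(rgb, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG images")
  }
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}
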