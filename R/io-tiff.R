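#' Write / read an image stack as TIFF with a JSON sidecar
#'
#' Frames are stored as a multi-directory single-channel TIFF. Intensities
#' are scaled to `[0, 1]` for storage; the scale (`intensity_min`,
#' `intensity_max`) and the calibration (`pixel_size_m`, `frame_interval_s`,
#' `channels`, `times_s`) live in `<path>.json`, and the reader restores
#' the original values.
#'
#' @param frames list of [image_frame()] (one channel).
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @return the reader returns a list of [image_frame()]; the writer returns
#'   `path` invisibly.
#' @export
write_image_stack <- function(frames, path) {
  if (length(frames) == 0) stop("no frames")
  stopifnot(all(vapply(frames, inherits, logical(1), "image_frame")))
  lo <- min(vapply(frames, function(f) min(f$intensity), numeric(1)))
  hi <- max(vapply(frames, function(f) max(f$intensity), numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  mats <- lapply(frames, function(f) (f$intensity - lo) / scale)
  tiff::writeTIFF(mats, path, bits.per.sample = 16, compression = "none")
  meta <- list(pixel_size_m = frames[[1]]$pixel_size,
               frame_interval_s = if (length(frames) > 1)
                 frames[[2]]$time - frames[[1]]$time else 0,
               channels = frames[[1]]$channel,
               times_s = vapply(frames, function(f) f$time, numeric(1)),
               intensity_min = lo, intensity_max = lo + scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar metadata (pixel size): ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_m))
    stop("sidecar lacks pixel_size_m: refusing to guess calibration")
  mats <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(mats)) mats <- list(mats)
  lo <- meta$intensity_min %||% 0
  hi <- meta$intensity_max %||% 1
  times <- meta$times_s %||%
    ((seq_along(mats) - 1) * (meta$frame_interval_s %||% 1))
  lapply(seq_along(mats), function(k) {
    image_frame(mats[[k]] * (hi - lo) + lo, meta$pixel_size_m,
                channel = meta$channels %||% "actin", time = times[k])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a kymograph as a single-channel TIFF with sidecar
#'
#' @param kymo a [kymograph()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_kymograph_tiff <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$intensity
  lo <- min(img); hi <- max(img)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img - lo) / scale, path, bits.per.sample = 16,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_m = kymo$pixel_size,
                            frame_interval_s = kymo$frame_interval,
                            intensity_min = lo, intensity_max = lo + scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kymograph_tiff
#' @export
read_kymograph_tiff <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar metadata: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  lo <- meta$intensity_min %||% 0
  hi <- meta$intensity_max %||% 1
  kymograph(img * (hi - lo) + lo, meta$pixel_size_m, meta$frame_interval_s)
}
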