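## File formats: frame stacks as multi-page TIFF or numbered PNG sequences,
## tracks and ground truth as CSV, calibration as JSON, scene configs as
## YAML.

#' Write a frame stack to disk
#'
#' Multi-page grayscale TIFF (16-bit by default) or a directory of numbered
#' 8-bit PNG frames. The frame rate is not stored by either format and must
#' be supplied again when reading.
#'
#' @param stack A [FrameStack].
#' @param path Output file (TIFF) or directory (PNG sequence).
#' @param format `"tiff"` or `"png"`.
#' @param bitsPerSample TIFF bit depth (8 or 16).
#' @return `path`, invisibly.
#' @export
writeFrameStack <- function(stack, path, format = c("tiff", "png"),
                            bitsPerSample = 16) {
  stopifnot(is(stack, "FrameStack"))
  format <- match.arg(format)
  a <- stack@frames
  nT <- dim(a)[3]
  if (format == "tiff") {
    pages <- lapply(seq_len(nT), function(k) a[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample,
                    compression = "none")
  } else {
    if (!dir.exists(path))
      dir.create(path, recursive = TRUE)
    for (k in seq_len(nT))
      png::writePNG(a[, , k],
                    file.path(path, sprintf("frame_%06d.png", k)))
  }
  invisible(path)
}

#' Read a frame stack from disk
#'
#' Reads a multi-page grayscale TIFF or a directory of PNG frames (sorted
#' by file name) written by [writeFrameStack()].
#'
#' @param path TIFF file or PNG directory.
#' @param fps Frame rate in Hz to attach to the stack.
#' @return A [FrameStack].
#' @export
readFrameStack <- function(path, fps) {
  asGray <- function(m) {
    if (length(dim(m)) == 3L) m[, , 1L] else m
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) < 2L)
      stop(sprintf("'%s' holds fewer than 2 PNG frames", path))
    pages <- lapply(files, function(f) asGray(png::readPNG(f)))
  } else {
    if (!file.exists(path))
      stop(sprintf("no such clip: '%s'", path))
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages))
      pages <- list(pages)
    pages <- lapply(pages, asGray)
  }
  h <- nrow(pages[[1L]])
  w <- ncol(pages[[1L]])
  a <- array(0, dim = c(h, w, length(pages)))
  for (k in seq_along(pages))
    a[, , k] <- pages[[k]]
  FrameStack(a, fps)
}

#' Write / read marker tracks as CSV
#'
#' Long-format CSV with columns `frame`, `markerId`, `xPx`, `yPx`,
#' `quality`.
#'
#' @param tracks List of [Track] objects.
#' @param path CSV file path.
#' @return `writeTracks()`: `path`, invisibly. `readTracks()`: a list of
#'   [Track] objects.
#' @export
writeTracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(frame = seq_len(nrow(tr@positions)),
               markerId = tr@markerId,
               xPx = tr@positions[, 1L], yPx = tr@positions[, 2L],
               quality = tr@quality, fps = tr@fps,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$markerId), function(d) {
    d <- d[order(d$frame), ]
    Track(d$markerId[1L], cbind(x = d$xPx, y = d$yPx), d$quality,
          d$fps[1L])
  })
}

#' Write ground truth displacements as CSV
#'
#' @param truth Ground-truth data frame from [simulateClip()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a calibration as JSON
#'
#' @param cal A [Calibration].
#' @param path JSON file path.
#' @return `writeCalibration()`: `path`, invisibly. `readCalibration()`:
#'   a [Calibration].
#' @export
writeCalibration <- function(cal, path) {
  jsonlite::write_json(
    list(mmPerPxX = cal@mmPerPxX, mmPerPxY = cal@mmPerPxY,
         uncertaintyX = cal@uncertaintyX, uncertaintyY = cal@uncertaintyY),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  Calibration(x$mmPerPxX, x$mmPerPxY, x$uncertaintyX, x$uncertaintyY)
}

## ---- scene config YAML ----------------------------------------------------

.toneToList <- function(tone) {
  out <- list(amplitude_um = tone@amplitudeUm,
              frequency_hz = tone@frequencyHz,
              phase_rad = tone@phaseRad, axis = tone@axis)
  if (tone@startS > 0) out$active_from_s <- tone@startS
  if (is.finite(tone@endS)) out$active_until_s <- tone@endS
  out
}

.toneFromList <- function(x) {
  Tone(x$amplitude_um, x$frequency_hz,
       if (is.null(x$phase_rad)) 0 else x$phase_rad,
       if (is.null(x$axis)) "horizontal" else x$axis,
       startS = if (is.null(x$active_from_s)) 0 else x$active_from_s,
       endS = if (is.null(x$active_until_s)) Inf else x$active_until_s)
}

.markerToList <- function(m) {
  list(id = m@id, center_px = as.list(m@centerPx),
       arm_length_mm = m@armLengthMm, arm_width_mm = m@armWidthMm,
       contrast = m@contrast, tones = lapply(m@tones, .toneToList))
}

.markerFromList <- function(x) {
  MarkerSpec(id = x$id, centerPx = unlist(x$center_px),
             armLengthMm = x$arm_length_mm, armWidthMm = x$arm_width_mm,
             contrast = x$contrast,
             tones = lapply(x$tones, .toneFromList))
}

#' Write / read a scene configuration as YAML
#'
#' @param config A [SceneConfig].
#' @param path YAML file path.
#' @return `writeSceneConfig()`: `path`, invisibly. `readSceneConfig()`:
#'   a [SceneConfig].
#' @export
writeSceneConfig <- function(config, path) {
  yaml::write_yaml(
    list(width_px = config@widthPx, height_px = config@heightPx,
         fps = config@fps, duration_s = config@durationS,
         pixel_pitch_mm = as.list(config@pixelPitchMm),
         background_level = config@backgroundLevel,
         texture_amp = config@textureAmp, noise_sigma = config@noiseSigma,
         supersample = config@supersample,
         markers = lapply(config@markers, .markerToList),
         seed = config@seed),
    path)
  invisible(path)
}

#' @rdname writeSceneConfig
#' @export
readSceneConfig <- function(path) {
  x <- yaml::read_yaml(path)
  SceneConfig(widthPx = x$width_px, heightPx = x$height_px, fps = x$fps,
              durationS = x$duration_s,
              pixelPitchMm = unlist(x$pixel_pitch_mm),
              backgroundLevel = x$background_level,
              textureAmp = x$texture_amp, noiseSigma = x$noise_sigma,
              supersample = x$supersample,
              markers = lapply(x$markers, .markerFromList),
              seed = x$seed)
}

#' Write an amplitude spectrum as CSV
#'
#' Columns `freq_hz` and `density_um_per_hz`.
#'
#' @param spectrum An [AmplitudeSpectrum].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  utils::write.csv(
    data.frame(freq_hz = spectrum@freqs,
               density_um_per_hz = spectrum@density),
    path, row.names = FALSE)
  invisible(path)
}
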