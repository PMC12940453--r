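#' @import methods
NULL

## ---------------------------------------------------------------------------
## Scene description
## ---------------------------------------------------------------------------

#' Single vibration tone
#'
#' A pure sinusoidal displacement component of a marker, specified in physical
#' units. A marker vibrates as the sum of its tones, evaluated per frame.
#'
#' @slot amplitudeUm Displacement amplitude in micrometres (>= 0).
#' @slot frequencyHz Tone frequency in Hz (> 0; must stay below half the frame
#'   rate of any clip it is rendered into).
#' @slot phaseRad Initial phase in radians.
#' @slot axis `"horizontal"` (image x, columns) or `"vertical"` (image y,
#'   rows).
#' @slot startS,endS Activity window in seconds (default `0` to `Inf`:
#'   active for the whole clip); lets one clip hold an idle segment
#'   followed by a vibrating one.
#'
#' @export
setClass("Tone",
  representation(
    amplitudeUm = "numeric",
    frequencyHz = "numeric",
    phaseRad    = "numeric",
    axis        = "character",
    startS      = "numeric",
    endS        = "numeric"
  )
)

setValidity("Tone", function(object) {
  msg <- character()
  if (length(object@amplitudeUm) != 1L || !is.finite(object@amplitudeUm) ||
      object@amplitudeUm < 0)
    msg <- c(msg, "'amplitudeUm' must be a single non-negative number")
  if (length(object@frequencyHz) != 1L || !is.finite(object@frequencyHz) ||
      object@frequencyHz <= 0)
    msg <- c(msg, "'frequencyHz' must be a single positive number")
  if (length(object@phaseRad) != 1L || !is.finite(object@phaseRad))
    msg <- c(msg, "'phaseRad' must be a single finite number")
  if (length(object@axis) != 1L ||
      !object@axis %in% c("horizontal", "vertical"))
    msg <- c(msg, "'axis' must be \"horizontal\" or \"vertical\"")
  if (object@endS <= object@startS)
    msg <- c(msg, "need endS > startS")
  if (length(msg)) msg else TRUE
})

#' @rdname Tone-class
#' @param amplitudeUm,frequencyHz,phaseRad,axis,startS,endS See slot
#'   descriptions.
#' @return A `Tone` object.
#' @examples
#' Tone(2.5, 40)
#' @export
Tone <- function(amplitudeUm, frequencyHz, phaseRad = 0,
                 axis = c("horizontal", "vertical"),
                 startS = 0, endS = Inf) {
  axis <- match.arg(axis)
  new("Tone", amplitudeUm = as.numeric(amplitudeUm),
      frequencyHz = as.numeric(frequencyHz),
      phaseRad = as.numeric(phaseRad), axis = axis,
      startS = as.numeric(startS), endS = as.numeric(endS))
}

#' Cross-shaped fiducial marker specification
#'
#' Describes one printed cross marker: its continuous position in the frame,
#' its physical arm dimensions (which also serve for pixel-pitch calibration),
#' its contrast against the background, and the vibration tones it undergoes.
#'
#' @slot id Character marker identifier.
#' @slot centerPx Numeric length-2 `(x, y)` continuous center position in
#'   pixel units (pixel centers at integer coordinates, origin top-left).
#' @slot armLengthMm,armWidthMm Physical cross dimensions in mm
#'   (`armLengthMm > armWidthMm > 0`).
#' @slot contrast Marker-vs-background intensity difference in `[0, 1]`;
#'   the cross is dark on a lighter background.
#' @slot tones List of [Tone] objects.
#'
#' @export
setClass("MarkerSpec",
  representation(
    id          = "character",
    centerPx    = "numeric",
    armLengthMm = "numeric",
    armWidthMm  = "numeric",
    contrast    = "numeric",
    tones       = "list"
  )
)

setValidity("MarkerSpec", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a non-empty string")
  if (length(object@centerPx) != 2L || !all(is.finite(object@centerPx)))
    msg <- c(msg, "'centerPx' must be a finite (x, y) pair")
  if (!(length(object@armLengthMm) == 1L && length(object@armWidthMm) == 1L &&
        is.finite(object@armLengthMm) && is.finite(object@armWidthMm) &&
        object@armLengthMm > object@armWidthMm && object@armWidthMm > 0))
    msg <- c(msg, "need armLengthMm > armWidthMm > 0")
  if (length(object@contrast) != 1L || !is.finite(object@contrast) ||
      object@contrast < 0 || object@contrast > 1)
    msg <- c(msg, "'contrast' must lie in [0, 1]")
  if (!all(vapply(object@tones, is, logical(1), class2 = "Tone")))
    msg <- c(msg, "'tones' must be a list of Tone objects")
  if (length(msg)) msg else TRUE
})

#' @rdname MarkerSpec-class
#' @param id,centerPx,armLengthMm,armWidthMm,contrast,tones See slot
#'   descriptions.
#' @return A `MarkerSpec` object.
#' @export
MarkerSpec <- function(id = "m1", centerPx = c(64, 64), armLengthMm = 10,
                       armWidthMm = 2, contrast = 0.45, tones = list()) {
  new("MarkerSpec", id = id, centerPx = as.numeric(centerPx),
      armLengthMm = as.numeric(armLengthMm),
      armWidthMm = as.numeric(armWidthMm),
      contrast = as.numeric(contrast), tones = tones)
}

#' Synthetic scene configuration
#'
#' Full description of a synthetic high-speed clip: frame geometry, frame
#' rate, physical pixel pitch, background appearance, sensor noise, the
#' markers with their motion, and the RNG seed. Identical configurations
#' (including the seed) render bit-identical clips.
#'
#' @slot widthPx,heightPx Frame size in pixels.
#' @slot fps Frame rate in Hz.
#' @slot durationS Clip length in seconds.
#' @slot pixelPitchMm Numeric length-2 `(x, y)` physical pixel size in
#'   mm/pixel.
#' @slot backgroundLevel Mean background intensity in `[0, 1]`.
#' @slot textureAmp Amplitude (SD) of the static background texture.
#' @slot noiseSigma Per-pixel Gaussian sensor noise SD (in `[0, 0.2)`).
#' @slot supersample Integer rasterization oversampling factor (>= 4).
#' @slot markers List of [MarkerSpec] objects.
#' @slot seed Integer RNG seed.
#'
#' @export
setClass("SceneConfig",
  representation(
    widthPx         = "integer",
    heightPx        = "integer",
    fps             = "numeric",
    durationS       = "numeric",
    pixelPitchMm    = "numeric",
    backgroundLevel = "numeric",
    textureAmp      = "numeric",
    noiseSigma      = "numeric",
    supersample     = "integer",
    markers         = "list",
    seed            = "integer"
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@widthPx < 16L || object@heightPx < 16L)
    msg <- c(msg, "frame must be at least 16 x 16 pixels")
  if (!(object@fps > 0)) msg <- c(msg, "'fps' must be positive")
  if (!(object@durationS > 0)) msg <- c(msg, "'durationS' must be positive")
  if (length(object@pixelPitchMm) != 2L || any(object@pixelPitchMm <= 0))
    msg <- c(msg, "'pixelPitchMm' must be two positive values (x, y)")
  if (object@backgroundLevel < 0 || object@backgroundLevel > 1)
    msg <- c(msg, "'backgroundLevel' must lie in [0, 1]")
  if (object@textureAmp < 0)
    msg <- c(msg, "'textureAmp' must be non-negative")
  if (object@noiseSigma < 0 || object@noiseSigma >= 0.2)
    msg <- c(msg, "'noiseSigma' must lie in [0, 0.2)")
  if (object@supersample < 4L)
    msg <- c(msg, "'supersample' must be >= 4")
  if (!all(vapply(object@markers, is, logical(1), class2 = "MarkerSpec")))
    msg <- c(msg, "'markers' must be a list of MarkerSpec objects")
  if (length(msg)) msg else TRUE
})

#' @rdname SceneConfig-class
#' @param widthPx,heightPx,fps,durationS,pixelPitchMm,backgroundLevel See
#'   slot descriptions.
#' @param textureAmp,noiseSigma,supersample,markers,seed See slot
#'   descriptions.
#' @return A `SceneConfig` object.
#' @export
SceneConfig <- function(widthPx = 128, heightPx = 128, fps = 1000,
                        durationS = 2, pixelPitchMm = c(0.49, 0.46),
                        backgroundLevel = 0.55, textureAmp = 0.02,
                        noiseSigma = 0.005, supersample = 8,
                        markers = list(MarkerSpec()), seed = 1) {
  new("SceneConfig", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx), fps = as.numeric(fps),
      durationS = as.numeric(durationS),
      pixelPitchMm = as.numeric(pixelPitchMm),
      backgroundLevel = as.numeric(backgroundLevel),
      textureAmp = as.numeric(textureAmp),
      noiseSigma = as.numeric(noiseSigma),
      supersample = as.integer(supersample), markers = markers,
      seed = as.integer(seed))
}

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d x %d px, %g fps, %g s, %d marker(s), seed %d\n",
              object@widthPx, object@heightPx, object@fps, object@durationS,
              length(object@markers), object@seed))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## Frame data
## ---------------------------------------------------------------------------

#' Time-ordered luminance frame stack
#'
#' The central video container: a `height x width x frames` numeric array of
#' luminance values in `[0, 1]` plus the frame rate. Frames are grayscale;
#' pixel `[y, x]` addresses row `y`, column `x`.
#'
#' @slot frames Numeric 3D array, values in `[0, 1]`.
#' @slot fps Frame rate in Hz.
#'
#' @export
setClass("FrameStack",
  representation(frames = "array", fps = "numeric")
)

setValidity("FrameStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "'frames' must be a height x width x time 3D array")
  else if (d[3] < 2L)
    msg <- c(msg, "a FrameStack needs at least 2 frames")
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    msg <- c(msg, "'fps' must be a single positive number")
  if (length(d) == 3L) {
    r <- range(object@frames)
    if (!all(is.finite(r)) || r[1] < -1e-9 || r[2] > 1 + 1e-9)
      msg <- c(msg, "frame values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FrameStack-class
#' @param frames Numeric 3D array `height x width x frames` in `[0, 1]`.
#' @param fps Frame rate in Hz.
#' @return A `FrameStack` object.
#' @export
FrameStack <- function(frames, fps) {
  new("FrameStack", frames = frames, fps = as.numeric(fps))
}

#' @rdname fps
#' @export
setMethod("fps", "FrameStack", function(x) x@fps)

#' @rdname frames
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)

#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3])

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d x %d px, %d frames @ %g fps (%.3g s)\n",
              d[1], d[2], d[3], object@fps, d[3] / object@fps))
  invisible(NULL)
})

#' Temporal passband specification
#'
#' Edges of the temporal frequency band, in Hz, preserved by the ideal
#' bandpass filter of the magnification stage.
#'
#' @slot fLo,fHi Passband edges in Hz, `0 < fLo < fHi`; `fHi` must not
#'   exceed half the frame rate of the clip the band is applied to.
#'
#' @export
setClass("BandSpec", representation(fLo = "numeric", fHi = "numeric"))

setValidity("BandSpec", function(object) {
  if (length(object@fLo) != 1L || length(object@fHi) != 1L ||
      !is.finite(object@fLo) || !is.finite(object@fHi) ||
      object@fLo <= 0 || object@fHi <= object@fLo)
    "need 0 < fLo < fHi"
  else TRUE
})

#' @rdname BandSpec-class
#' @param fLo,fHi Passband edges in Hz.
#' @return A `BandSpec` object.
#' @examples
#' BandSpec(10, 1000)
#' @export
BandSpec <- function(fLo = 10, fHi = 1000) {
  new("BandSpec", fLo = as.numeric(fLo), fHi = as.numeric(fHi))
}

#' Magnification parameters
#'
#' Controls the Eulerian magnification stage: the amplification factor applied
#' to the temporally bandpassed signal, the spatial decomposition, and an
#' optional attenuation of the finest pyramid level (where sensor noise
#' concentrates).
#'
#' @slot alpha Amplification factor (>= 0). The effective motion gain of the
#'   output is `1 + alpha`.
#' @slot nLevels Spatial pyramid depth (NA = choose automatically so the
#'   coarsest level is at least 8 px on its short side).
#' @slot mode `"laplacian_pyramid"` (default) or `"gaussian_blur"` (a single
#'   lowpassed band).
#' @slot attenuateFineLevels Logical; scale down the amplification on the
#'   finest level.
#' @slot fineLevelScale Multiplier applied to `alpha` on the finest level when
#'   `attenuateFineLevels` is `TRUE`.
#'
#' @export
setClass("MagParams",
  representation(
    alpha               = "numeric",
    nLevels             = "integer",
    mode                = "character",
    attenuateFineLevels = "logical",
    fineLevelScale      = "numeric"
  )
)

setValidity("MagParams", function(object) {
  msg <- character()
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha < 0)
    msg <- c(msg, "'alpha' must be a single non-negative number")
  if (length(object@nLevels) != 1L ||
      (!is.na(object@nLevels) && object@nLevels < 1L))
    msg <- c(msg, "'nLevels' must be NA or >= 1")
  if (length(object@mode) != 1L ||
      !object@mode %in% c("laplacian_pyramid", "gaussian_blur"))
    msg <- c(msg, "'mode' must be \"laplacian_pyramid\" or \"gaussian_blur\"")
  if (object@fineLevelScale < 0 || object@fineLevelScale > 1)
    msg <- c(msg, "'fineLevelScale' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname MagParams-class
#' @param alpha,nLevels,mode,attenuateFineLevels,fineLevelScale See slot
#'   descriptions.
#' @return A `MagParams` object.
#' @examples
#' MagParams(alpha = 100)
#' @export
MagParams <- function(alpha = 100, nLevels = NA,
                      mode = c("laplacian_pyramid", "gaussian_blur"),
                      attenuateFineLevels = FALSE, fineLevelScale = 0.5) {
  mode <- match.arg(mode)
  new("MagParams", alpha = as.numeric(alpha), nLevels = as.integer(nLevels),
      mode = mode, attenuateFineLevels = isTRUE(attenuateFineLevels),
      fineLevelScale = as.numeric(fineLevelScale))
}

## ---------------------------------------------------------------------------
## Tracking
## ---------------------------------------------------------------------------

#' Matching template for a cross marker
#'
#' Noise-free rendered appearance of a cross marker, used as the normalized
#' cross-correlation template, together with its nominal physical dimensions
#' (the basis of pixel-pitch calibration).
#'
#' @slot patch Odd-sized numeric matrix with the marker centered.
#' @slot armLengthMm,armWidthMm Nominal physical dimensions in mm.
#' @slot pixelPitchMm `(x, y)` pixel pitch the patch was rendered at.
#'
#' @export
setClass("Template",
  representation(
    patch        = "matrix",
    armLengthMm  = "numeric",
    armWidthMm   = "numeric",
    pixelPitchMm = "numeric"
  )
)

setValidity("Template", function(object) {
  msg <- character()
  d <- dim(object@patch)
  if (any(d %% 2L == 0L))
    msg <- c(msg, "'patch' must be odd-sized in both dimensions")
  if (stats::sd(object@patch) == 0)
    msg <- c(msg, "'patch' must not be constant")
  if (length(msg)) msg else TRUE
})

#' Sub-pixel marker track
#'
#' Per-frame continuous marker center positions with the peak correlation that
#' produced each one.
#'
#' @slot markerId Character marker identifier.
#' @slot positions Numeric matrix with columns `x`, `y`, one row per frame.
#' @slot quality Per-frame peak normalized cross-correlation.
#' @slot fps Frame rate of the tracked clip in Hz.
#'
#' @export
setClass("Track",
  representation(
    markerId  = "character",
    positions = "matrix",
    quality   = "numeric",
    fps       = "numeric"
  )
)

setValidity("Track", function(object) {
  msg <- character()
  if (ncol(object@positions) != 2L)
    msg <- c(msg, "'positions' must have two columns (x, y)")
  if (nrow(object@positions) != length(object@quality))
    msg <- c(msg, "'quality' must have one value per frame")
  if (!all(is.finite(object@positions)))
    msg <- c(msg, "'positions' must be finite")
  if (length(object@fps) != 1L || object@fps <= 0)
    msg <- c(msg, "'fps' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname Track-class
#' @param markerId,positions,quality,fps See slot descriptions.
#' @return A `Track` object.
#' @export
Track <- function(markerId, positions, quality, fps) {
  colnames(positions) <- c("x", "y")
  new("Track", markerId = markerId, positions = positions,
      quality = as.numeric(quality), fps = as.numeric(fps))
}

#' @rdname positions
#' @export
setMethod("positions", "Track", function(x) x@positions)

#' @rdname quality
#' @export
setMethod("quality", "Track", function(x) x@quality)

#' @rdname markerId
#' @export
setMethod("markerId", "Track", function(x) x@markerId)

#' @rdname fps
#' @export
setMethod("fps", "Track", function(x) x@fps)

#' @rdname nFrames
#' @export
setMethod("nFrames", "Track", function(x) nrow(x@positions))

setMethod("show", "Track", function(object) {
  cat(sprintf(
    "Track '%s': %d frames @ %g fps, mean quality %.3f\n",
    object@markerId, nrow(object@positions), object@fps,
    mean(object@quality)))
  invisible(NULL)
})

#' Pixel-pitch calibration
#'
#' Physical size of one pixel along each image axis, obtained by dividing the
#' known physical length of a marker by its extent in pixels, with a
#' first-order uncertainty from the +/- 0.5 px extent-measurement error.
#' The defaults are the pitch of the reference acquisition geometry:
#' 0.49 mm/px along x and 0.46 mm/px along y.
#'
#' @slot mmPerPxX,mmPerPxY Pixel pitch in mm/pixel (both > 0).
#' @slot uncertaintyX,uncertaintyY Pitch uncertainty in mm/pixel.
#'
#' @export
setClass("Calibration",
  representation(
    mmPerPxX     = "numeric",
    mmPerPxY     = "numeric",
    uncertaintyX = "numeric",
    uncertaintyY = "numeric"
  )
)

setValidity("Calibration", function(object) {
  if (object@mmPerPxX <= 0 || object@mmPerPxY <= 0)
    "pixel pitch must be positive on both axes"
  else TRUE
})

#' @rdname Calibration-class
#' @param mmPerPxX,mmPerPxY,uncertaintyX,uncertaintyY See slot descriptions.
#' @return A `Calibration` object.
#' @examples
#' Calibration()           # reference-geometry defaults
#' Calibration(0.5, 0.5)
#' @export
Calibration <- function(mmPerPxX = 0.49, mmPerPxY = 0.46,
                        uncertaintyX = 0.01, uncertaintyY = 0.01) {
  new("Calibration", mmPerPxX = as.numeric(mmPerPxX),
      mmPerPxY = as.numeric(mmPerPxY),
      uncertaintyX = as.numeric(uncertaintyX),
      uncertaintyY = as.numeric(uncertaintyY))
}

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: %.4g +/- %.2g (x), %.4g +/- %.2g (y) mm/px\n",
              object@mmPerPxX, object@uncertaintyX,
              object@mmPerPxY, object@uncertaintyY))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## Quantification
## ---------------------------------------------------------------------------

#' Effective motion gain
#'
#' Ratio of apparent (amplified) displacement to true physical displacement.
#' Dividing tracked displacements by `g` reports the estimated physical
#' motion before amplification. For Eulerian magnification with amplification
#' factor `alpha` the first-order gain is `1 + alpha` (default 101).
#'
#' @slot g Gain, dimensionless, >= 1.
#'
#' @export
setClass("GainSpec", representation(g = "numeric"))

setValidity("GainSpec", function(object) {
  if (length(object@g) != 1L || !is.finite(object@g) || object@g < 1)
    "'g' must be a single number >= 1"
  else TRUE
})

#' @rdname GainSpec-class
#' @param g Effective motion gain (>= 1).
#' @return A `GainSpec` object.
#' @export
GainSpec <- function(g = 101) new("GainSpec", g = as.numeric(g))

#' Condition segmentation plan
#'
#' Ordered, non-overlapping time slots labelling the acquisition conditions
#' within one clip (for example idle, b = 0, and each diffusion-encoding
#' direction). Intervals are half-open: a frame at time `t` belongs to the
#' segment with `tStart <= t < tEnd`.
#'
#' @slot condition Character condition labels.
#' @slot tStart,tEnd Segment bounds in seconds.
#'
#' @export
setClass("SegmentPlan",
  representation(condition = "character", tStart = "numeric",
                 tEnd = "numeric")
)

setValidity("SegmentPlan", function(object) {
  msg <- character()
  n <- length(object@condition)
  if (length(object@tStart) != n || length(object@tEnd) != n)
    msg <- c(msg, "'condition', 'tStart' and 'tEnd' must have equal length")
  else {
    if (any(object@tEnd <= object@tStart))
      msg <- c(msg, "each segment needs tEnd > tStart")
    if (n > 1L && any(object@tStart[-1] < object@tEnd[-n]))
      msg <- c(msg, "segments must be non-overlapping and increasing")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SegmentPlan-class
#' @param condition,tStart,tEnd See slot descriptions.
#' @return A `SegmentPlan` object.
#' @examples
#' SegmentPlan(c("idle", "scan"), c(0, 1), c(1, 2))
#' @export
SegmentPlan <- function(condition, tStart, tEnd) {
  new("SegmentPlan", condition = as.character(condition),
      tStart = as.numeric(tStart), tEnd = as.numeric(tEnd))
}

#' @describeIn SegmentPlan-class The segmentation of the reference 87 s
#'   diffusion-weighted acquisition: b = 0 from 0-12 s, then three encoding
#'   directions at 12-37, 37-62 and 62-87 s.
#' @export
acquisitionSegmentPlan <- function() {
  SegmentPlan(c("b0", "dir1", "dir2", "dir3"),
              c(0, 12, 37, 62), c(12, 37, 62, 87))
}

#' Physical displacement series
#'
#' Per-frame displacement of one marker along one axis, in micrometres,
#' relative to the mean position within its condition segment (so the series
#' is zero-mean by construction).
#'
#' @slot markerId Character marker identifier.
#' @slot conditionLabel Condition the segment belongs to.
#' @slot axisLabel Axis label (image `"x"`/`"y"`, or an anatomical relabeling
#'   such as `"X"`, `"Y"`, `"Z"`).
#' @slot values Numeric displacements in micrometres, zero-mean.
#' @slot fps Sampling rate in Hz.
#'
#' @export
setClass("DisplacementSeries",
  representation(
    markerId       = "character",
    conditionLabel = "character",
    axisLabel      = "character",
    values         = "numeric",
    fps            = "numeric"
  )
)

setValidity("DisplacementSeries", function(object) {
  msg <- character()
  if (length(object@values) < 2L)
    msg <- c(msg, "a DisplacementSeries needs at least 2 samples")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  else if (abs(mean(object@values)) > 1e-9 * max(1, max(abs(object@values))))
    msg <- c(msg, "'values' must be zero-mean (re-center on the segment mean)")
  if (length(object@fps) != 1L || object@fps <= 0)
    msg <- c(msg, "'fps' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname DisplacementSeries-class
#' @param markerId,conditionLabel,axisLabel,fps See slot descriptions.
#' @param values Numeric displacement values in micrometres; re-centered on
#'   their mean at construction.
#' @return A `DisplacementSeries` object.
#' @export
DisplacementSeries <- function(values, fps, markerId = "m1",
                               conditionLabel = "all", axisLabel = "x") {
  v <- as.numeric(values)
  v <- v - mean(v)
  new("DisplacementSeries", markerId = markerId,
      conditionLabel = conditionLabel, axisLabel = axisLabel,
      values = v, fps = as.numeric(fps))
}

#' @rdname values
#' @export
setMethod("values", "DisplacementSeries", function(x) x@values)

#' @rdname fps
#' @export
setMethod("fps", "DisplacementSeries", function(x) x@fps)

#' @rdname markerId
#' @export
setMethod("markerId", "DisplacementSeries", function(x) x@markerId)

setMethod("show", "DisplacementSeries", function(object) {
  cat(sprintf(
    "DisplacementSeries '%s' [%s, %s]: %d samples @ %g fps, RMS %.3g um\n",
    object@markerId, object@axisLabel, object@conditionLabel,
    length(object@values), object@fps,
    sqrt(mean(object@values^2))))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## Spectra
## ---------------------------------------------------------------------------

#' Combined amplitude spectrum
#'
#' One-sided amplitude spectral density of a marker's motion, with the two
#' in-plane axes combined per frequency bin as the Euclidean magnitude, in
#' micrometres per Hz.
#'
#' @slot freqs Strictly increasing one-sided frequency grid in Hz.
#' @slot density Combined amplitude density (um/Hz), non-negative.
#' @slot deltaF Frequency bin width `fps / N` in Hz.
#'
#' @export
setClass("AmplitudeSpectrum",
  representation(freqs = "numeric", density = "numeric", deltaF = "numeric")
)

setValidity("AmplitudeSpectrum", function(object) {
  msg <- character()
  if (length(object@freqs) != length(object@density))
    msg <- c(msg, "'freqs' and 'density' must have equal length")
  if (length(object@freqs) && any(diff(object@freqs) <= 0))
    msg <- c(msg, "'freqs' must be strictly increasing")
  if (any(object@density < 0))
    msg <- c(msg, "'density' must be non-negative")
  if (length(object@deltaF) != 1L || object@deltaF <= 0)
    msg <- c(msg, "'deltaF' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname freqs
#' @export
setMethod("freqs", "AmplitudeSpectrum", function(x) x@freqs)

#' @rdname density_um
#' @export
setMethod("density_um", "AmplitudeSpectrum", function(x) x@density)

setMethod("show", "AmplitudeSpectrum", function(object) {
  pk <- which.max(object@density)
  cat(sprintf(
    "AmplitudeSpectrum: %d bins, df = %g Hz, peak %.3g um/Hz at %g Hz\n",
    length(object@freqs), object@deltaF,
    object@density[pk], object@freqs[pk]))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## Resampling
## ---------------------------------------------------------------------------

#' Resampling specification
#'
#' Replicate counts, block length and seed for the block bootstrap and the
#' block permutation test. Displacement series are strongly autocorrelated,
#' so resampling operates on contiguous blocks of frames rather than single
#' frames; the default block length used by the pipeline is 0.1 s of frames.
#'
#' @slot nBoot,nPerm Bootstrap / permutation replicate counts (>= 100).
#' @slot blockLenFrames Block length in frames (>= 1; must stay below half
#'   the series length at use time).
#' @slot seed Integer RNG seed.
#'
#' @export
setClass("ResamplingSpec",
  representation(nBoot = "integer", nPerm = "integer",
                 blockLenFrames = "integer", seed = "integer")
)

setValidity("ResamplingSpec", function(object) {
  msg <- character()
  if (object@nBoot < 100L || object@nPerm < 100L)
    msg <- c(msg, "'nBoot' and 'nPerm' must be >= 100")
  if (object@blockLenFrames < 1L)
    msg <- c(msg, "'blockLenFrames' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname ResamplingSpec-class
#' @param nBoot,nPerm,blockLenFrames,seed See slot descriptions.
#' @return A `ResamplingSpec` object.
#' @examples
#' ResamplingSpec(nBoot = 500, nPerm = 499, blockLenFrames = 100)
#' @export
ResamplingSpec <- function(nBoot = 500, nPerm = 499, blockLenFrames = 100,
                           seed = 1) {
  new("ResamplingSpec", nBoot = as.integer(nBoot), nPerm = as.integer(nPerm),
      blockLenFrames = as.integer(blockLenFrames), seed = as.integer(seed))
}
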