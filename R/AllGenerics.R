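#' Frame rate accessor
#'
#' Returns the frame rate, in Hz, of an object carrying a time base
#' (a [FrameStack], [Track] or [DisplacementSeries]).
#'
#' @param x An object with a frame rate.
#' @return Frame rate in frames per second.
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' Frame data accessor
#'
#' @param x A [FrameStack].
#' @return Numeric array `height x width x frames` of luminance in `[0, 1]`.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Number of frames
#'
#' @param x A [FrameStack] or [Track].
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Tracked positions accessor
#'
#' @param x A [Track].
#' @return Numeric matrix with columns `x` and `y`, one row per frame
#'   (pixel units, pixel centers at integer coordinates).
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' Track quality accessor
#'
#' @param x A [Track].
#' @return Per-frame peak normalized cross-correlation.
#' @export
setGeneric("quality", function(x) standardGeneric("quality"))

#' Marker identifier accessor
#'
#' @param x A [Track] or [DisplacementSeries].
#' @return Character marker id.
#' @export
setGeneric("markerId", function(x) standardGeneric("markerId"))

#' Displacement values accessor
#'
#' @param x A [DisplacementSeries].
#' @return Numeric displacement values in micrometres, re-centered on the
#'   segment mean.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Frequency grid accessor
#'
#' @param x An [AmplitudeSpectrum].
#' @return One-sided frequency grid in Hz.
#' @export
setGeneric("freqs", function(x) standardGeneric("freqs"))

#' Amplitude density accessor
#'
#' @param x An [AmplitudeSpectrum].
#' @return Combined amplitude density in micrometres per Hz.
#' @export
setGeneric("density_um", function(x) standardGeneric("density_um"))
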