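## Conversion of tracks to physical displacement and the displacement
## metrics: RMS, peak-to-peak, condition segmentation, pooled summaries.

#' Convert a track to physical displacement series
#'
#' Per axis, displacement is the tracked position minus its mean, scaled by
#' the pixel pitch and converted to micrometres, then divided by the
#' effective motion gain `g` to report the estimated physical motion before
#' amplification: `delta(t) = (p(t) - mean(p)) * mmPerPx * 1000 / g`.
#'
#' @param track A [Track].
#' @param cal A [Calibration].
#' @param gain A [GainSpec]; use `GainSpec(1)` for unamplified clips.
#' @param conditionLabel Condition label for the resulting series.
#' @param axisLabels Character length-2 labels for the image x and y axes
#'   (anatomical relabeling per marker view, e.g. `c("X", "Z")` for a
#'   mirror-viewed marker).
#' @return Named list of two [DisplacementSeries] (`x` and `y`).
#' @export
toDisplacement <- function(track, cal = Calibration(), gain = GainSpec(),
                           conditionLabel = "all", axisLabels = c("X", "Y")) {
  stopifnot(is(track, "Track"), is(cal, "Calibration"), is(gain, "GainSpec"))
  p <- track@positions
  if (nrow(p) < 2L)
    stop("track must cover at least 2 frames")
  ux <- (p[, 1L] - mean(p[, 1L])) * cal@mmPerPxX * 1000 / gain@g
  uy <- (p[, 2L] - mean(p[, 2L])) * cal@mmPerPxY * 1000 / gain@g
  list(
    x = DisplacementSeries(ux, track@fps, track@markerId, conditionLabel,
                           axisLabels[1L]),
    y = DisplacementSeries(uy, track@fps, track@markerId, conditionLabel,
                           axisLabels[2L])
  )
}

#' Cut a displacement series into condition segments
#'
#' Assigns each sample to the segment whose half-open interval
#' `[tStart, tEnd)` contains its time stamp (sample `k` is at
#' `(k - 1) / fps`), and re-centers each segment on its own mean.
#'
#' @param series A [DisplacementSeries].
#' @param plan A [SegmentPlan] lying within the series duration.
#' @return List of [DisplacementSeries], one per segment, labelled by
#'   condition.
#' @export
segmentSeries <- function(series, plan) {
  stopifnot(is(series, "DisplacementSeries"), is(plan, "SegmentPlan"))
  t <- (seq_along(series@values) - 1L) / series@fps
  out <- vector("list", length(plan@condition))
  names(out) <- plan@condition
  for (i in seq_along(plan@condition)) {
    sel <- t >= plan@tStart[i] & t < plan@tEnd[i]
    if (sum(sel) < 2L)
      stop(sprintf("segment '%s' (%g-%g s) contains fewer than 2 frames",
                   plan@condition[i], plan@tStart[i], plan@tEnd[i]))
    out[[i]] <- DisplacementSeries(series@values[sel], series@fps,
                                   series@markerId, plan@condition[i],
                                   series@axisLabel)
  }
  out
}

#' Root-mean-square displacement
#'
#' `sqrt(mean(delta^2))` of a re-centered displacement series, in
#' micrometres.
#'
#' @param series A [DisplacementSeries] or numeric vector.
#' @return RMS displacement in micrometres.
#' @examples
#' rmsDisplacement(c(1, -1, 1, -1))   # 1
#' @export
rmsDisplacement <- function(series) {
  v <- if (is(series, "DisplacementSeries")) series@values else series
  if (length(v) < 2L)
    stop("need at least 2 samples")
  .rms(v)
}

#' Peak-to-peak displacement
#'
#' `max(delta) - min(delta)` of a displacement series, in micrometres.
#'
#' @param series A [DisplacementSeries] or numeric vector.
#' @return Peak-to-peak displacement in micrometres.
#' @examples
#' peakToPeak(c(1, -1, 1, -1))   # 2
#' @export
peakToPeak <- function(series) {
  v <- if (is(series, "DisplacementSeries")) series@values else series
  if (length(v) < 2L)
    stop("need at least 2 samples")
  max(v) - min(v)
}

#' Tabulate displacement metrics per marker, axis and condition
#'
#' Converts a set of tracks to displacement, cuts them by the segment plan,
#' and reports RMS and peak-to-peak displacement per marker, axis and
#' condition (one row per marker-axis-condition combination).
#'
#' @param tracks List of [Track] objects.
#' @param cal A [Calibration].
#' @param gain A [GainSpec].
#' @param plan A [SegmentPlan]; `NULL` treats the whole clip as one segment
#'   labelled `"all"`.
#' @param axisLabels Length-2 axis labels, or a list of such vectors (one
#'   per marker).
#' @return Data frame with columns `markerId`, `axis`, `condition`, `rmsUm`,
#'   `ppUm`.
#' @export
displacementMetrics <- function(tracks, cal = Calibration(),
                                gain = GainSpec(), plan = NULL,
                                axisLabels = c("X", "Y")) {
  perMarker <- is.list(axisLabels)
  rows <- list()
  for (m in seq_along(tracks)) {
    labs <- if (perMarker) axisLabels[[m]] else axisLabels
    series <- toDisplacement(tracks[[m]], cal, gain, axisLabels = labs)
    for (ax in c("x", "y")) {
      segs <- if (is.null(plan)) list(all = series[[ax]])
              else segmentSeries(series[[ax]], plan)
      for (s in segs)
        rows[[length(rows) + 1L]] <- data.frame(
          markerId = s@markerId, axis = s@axisLabel,
          condition = s@conditionLabel,
          rmsUm = rmsDisplacement(s), ppUm = peakToPeak(s),
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pool displacement metrics across markers and axes
#'
#' Median (midpoint of the two central order statistics for even n), minimum
#' and maximum of a set of metric values, pooling all marker-direction
#' values within a condition.
#'
#' @param x Numeric vector of metric values (micrometres), or the data frame
#'   returned by [displacementMetrics()] together with `column`.
#' @param column Column to pool when `x` is a data frame (`"rmsUm"` or
#'   `"ppUm"`).
#' @return List with elements `median`, `min`, `max`, `n`.
#' @examples
#' poolSummary(c(2.32, 2.24, 3.16, 2.82))
#' @export
poolSummary <- function(x, column = "rmsUm") {
  v <- if (is.data.frame(x)) x[[column]] else as.numeric(x)
  if (length(v) < 1L)
    stop("need at least one value to pool")
  list(median = stats::median(v), min = min(v), max = max(v),
       n = length(v))
}
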