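## Orchestration: a single run configuration drives simulate/load ->
## magnify -> track -> quantify -> spectra -> stats, writing every stage
## artifact and collecting a reproducible report.

#' Pipeline run report
#'
#' Collected outputs of one [runPipeline()] run. Every reported number is
#' also written to a stage output file under the run's output directory.
#'
#' @slot metrics Data frame of RMS / peak-to-peak displacement per marker,
#'   axis and condition.
#' @slot pooled Per-condition pooled summaries (median / min / max).
#' @slot stability Per-condition split-half Bland-Altman results.
#' @slot comparisons Per marker/axis bootstrap CI and permutation p for
#'   each condition against the baseline condition.
#' @slot spectra List of [AmplitudeSpectrum] objects per marker/condition.
#' @slot info Run metadata: package version, config hash, seeds, saturation
#'   warnings, output paths.
#'
#' @export
setClass("RunReport",
  representation(metrics = "data.frame", pooled = "list",
                 stability = "list", comparisons = "list",
                 spectra = "list", info = "list")
)

setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport: %d metric rows, %d condition(s), config %s\n",
              nrow(object@metrics),
              length(unique(object@metrics$condition)),
              substr(object@info$configHash, 1, 8)))
  invisible(NULL)
})

.cfgGet <- function(cfg, key, default = NULL) {
  v <- cfg[[key]]
  if (is.null(v)) default else v
}

#' Run the full vibration-analysis pipeline
#'
#' Executes simulate/load -> magnify -> track -> displacement metrics ->
#' spectra -> stability and significance statistics from one configuration,
#' writing all stage artifacts to `outputDir`. Identical configuration and
#' seeds give identical outputs.
#'
#' The configuration is a named list (or path to a YAML file) with sections
#' `scene` (a scene description as written by [writeSceneConfig()]) or
#' `input` (`clip` path plus `fps`), `magnify` (`f_lo`, `f_hi`, `alpha`,
#' optional `mode`, `n_levels`), optional `gain` (`g`, default `1 + alpha`),
#' `track` (`search_radius_px`, `quality_floor`), optional `calibration`
#' (`mm_per_px_x/y`), optional `segments` (list of `condition`,
#' `t_start_s`, `t_end_s`), optional `stats` (`n_boot`, `n_perm`,
#' `block_len_s`, `baseline_condition`, `seed`) and optional `output`
#' (`write_clips`).
#'
#' @param config Named list or YAML file path.
#' @param outputDir Directory for stage artifacts (created if missing).
#' @return A [RunReport].
#' @export
runPipeline <- function(config, outputDir = tempfile("vibramp-run-")) {
  if (is.character(config))
    config <- yaml::read_yaml(config)
  if (!dir.exists(outputDir))
    dir.create(outputDir, recursive = TRUE)

  ## canonical config copy -> hash
  cfgPath <- file.path(outputDir, "run-config.yaml")
  yaml::write_yaml(config, cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  warningsSeen <- character()

  ## ---- stage 1: clip -----------------------------------------------------
  truth <- NULL
  if (!is.null(config$scene)) {
    sceneCfg <- .sceneFromList(config$scene)
    sim <- simulateClip(sceneCfg,
                        jitterSdUm = .cfgGet(config$scene, "jitter_sd_um", 0))
    clip <- sim$clip
    truth <- sim$truth
    writeGroundTruth(truth, file.path(outputDir, "ground-truth.csv"))
    markers <- sceneCfg@markers
    pitch <- sceneCfg@pixelPitchMm
  } else if (!is.null(config$input)) {
    clip <- readFrameStack(config$input$clip, config$input$fps)
    markers <- lapply(config$input$markers, .markerFromList)
    pitch <- unlist(.cfgGet(config$input, "pixel_pitch_mm",
                            list(0.49, 0.46)))
  } else {
    stop("config needs a 'scene' or an 'input' section")
  }

  ## ---- stage 2: magnify --------------------------------------------------
  mcfg <- .cfgGet(config, "magnify", list())
  band <- BandSpec(.cfgGet(mcfg, "f_lo", 10), .cfgGet(mcfg, "f_hi", 1000))
  alpha <- .cfgGet(mcfg, "alpha", 100)
  params <- MagParams(alpha = alpha,
                      nLevels = .cfgGet(mcfg, "n_levels", NA),
                      mode = .cfgGet(mcfg, "mode", "laplacian_pyramid"))
  amplified <- withCallingHandlers(
    magnifyClip(clip, band, params),
    warning = function(w) {
      warningsSeen <<- c(warningsSeen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (isTRUE(.cfgGet(.cfgGet(config, "output", list()), "write_clips",
                     FALSE))) {
    writeFrameStack(clip, file.path(outputDir, "raw.tiff"))
    writeFrameStack(amplified, file.path(outputDir, "amplified.tiff"))
  }

  ## ---- stage 3: track ----------------------------------------------------
  tcfg <- .cfgGet(config, "track", list())
  tpls <- lapply(markers, makeTemplate, pixelPitchMm = pitch)
  init <- do.call(rbind, lapply(markers, function(m) m@centerPx))
  colnames(init) <- c("x", "y")
  trackOn <- if (identical(.cfgGet(tcfg, "use_raw_clip", FALSE), TRUE))
    clip else amplified
  tracks <- trackClip(trackOn, init, tpls,
                      searchRadiusPx = .cfgGet(tcfg, "search_radius_px", 4),
                      qualityFloor = .cfgGet(tcfg, "quality_floor", 0.3),
                      markerIds = vapply(markers, function(m) m@id,
                                         character(1)))
  writeTracks(tracks, file.path(outputDir, "tracks.csv"))

  ## ---- stage 4: quantify -------------------------------------------------
  ccfg <- .cfgGet(config, "calibration", NULL)
  cal <- if (is.null(ccfg)) Calibration(pitch[1], pitch[2])
         else Calibration(ccfg$mm_per_px_x, ccfg$mm_per_px_y)
  writeCalibration(cal, file.path(outputDir, "calibration.json"))
  gain <- GainSpec(.cfgGet(.cfgGet(config, "gain", list()), "g", 1 + alpha))

  plan <- NULL
  if (!is.null(config$segments)) {
    segs <- config$segments
    plan <- SegmentPlan(vapply(segs, `[[`, character(1), "condition"),
                        vapply(segs, `[[`, numeric(1), "t_start_s"),
                        vapply(segs, `[[`, numeric(1), "t_end_s"))
  }
  axisLabels <- .cfgGet(config, "axis_labels", c("X", "Y"))
  if (is.list(axisLabels) && !is.list(axisLabels[[1]]))
    axisLabels <- unlist(axisLabels)
  metrics <- displacementMetrics(tracks, cal, gain, plan,
                                 axisLabels = axisLabels)
  utils::write.csv(metrics, file.path(outputDir, "metrics.csv"),
                   row.names = FALSE)
  conditions <- unique(metrics$condition)
  pooled <- lapply(stats::setNames(conditions, conditions), function(cn) {
    sub <- metrics[metrics$condition == cn, ]
    list(rms = poolSummary(sub, "rmsUm"), pp = poolSummary(sub, "ppUm"))
  })
  jsonlite::write_json(pooled, file.path(outputDir, "pooled.json"),
                       auto_unbox = TRUE, digits = NA)

  ## ---- stage 5: spectra --------------------------------------------------
  scfgSpec <- .cfgGet(config, "spectra", list())
  fMax <- .cfgGet(scfgSpec, "f_max", NULL)
  spectra <- list()
  segListPerTrack <- lapply(tracks, function(tr) {
    ser <- toDisplacement(tr, cal, gain)
    sx <- if (is.null(plan)) list(all = ser$x) else segmentSeries(ser$x, plan)
    sy <- if (is.null(plan)) list(all = ser$y) else segmentSeries(ser$y, plan)
    list(x = sx, y = sy)
  })
  for (m in seq_along(tracks)) {
    for (cn in names(segListPerTrack[[m]]$x)) {
      sp <- amplitudeSpectrum(segListPerTrack[[m]]$x[[cn]],
                              segListPerTrack[[m]]$y[[cn]], fMax = fMax)
      key <- sprintf("%s_%s", markerId(tracks[[m]]), cn)
      spectra[[key]] <- sp
      writeSpectrum(sp, file.path(outputDir,
                                  sprintf("spectrum_%s.csv", key)))
    }
  }

  ## ---- stage 6: statistics -----------------------------------------------
  stcfg <- .cfgGet(config, "stats", list())
  blockLen <- max(1L, as.integer(round(
    .cfgGet(stcfg, "block_len_s", 0.1) * fps(clip))))
  rspec <- ResamplingSpec(nBoot = .cfgGet(stcfg, "n_boot", 500),
                          nPerm = .cfgGet(stcfg, "n_perm", 499),
                          blockLenFrames = blockLen,
                          seed = .cfgGet(stcfg, "seed", 1))

  stability <- lapply(stats::setNames(conditions, conditions), function(cn) {
    pairs <- do.call(rbind, unlist(lapply(segListPerTrack, function(s) {
      lapply(c("x", "y"), function(ax) splitHalfPairs(s[[ax]][[cn]]))
    }), recursive = FALSE))
    blandAltman(pairs)
  })

  comparisons <- list()
  baseline <- .cfgGet(stcfg, "baseline_condition",
                      if (length(conditions) > 1L) conditions[1L] else NULL)
  if (!is.null(baseline) && baseline %in% conditions) {
    for (m in seq_along(tracks)) {
      for (ax in c("x", "y")) {
        base <- segListPerTrack[[m]][[ax]][[baseline]]
        for (cn in setdiff(conditions, baseline)) {
          other <- segListPerTrack[[m]][[ax]][[cn]]
          key <- sprintf("%s_%s_%s_vs_%s", markerId(tracks[[m]]), ax,
                         cn, baseline)
          comparisons[[key]] <- c(
            blockBootstrapCi(other, base, rspec),
            permutationTestRms(other, base, rspec)["pTwoSided"])
        }
      }
    }
  }
  jsonlite::write_json(
    list(stability = stability, comparisons = comparisons),
    file.path(outputDir, "stats.json"), auto_unbox = TRUE, digits = NA)

  info <- list(
    package = as.character(utils::packageVersion("vibramp")),
    configHash = cfgHash,
    outputDir = outputDir,
    sceneSeed = if (!is.null(config$scene)) .cfgGet(config$scene, "seed", 1)
                else NULL,
    statsSeed = rspec@seed,
    gain = gain@g,
    warnings = warningsSeen)
  jsonlite::write_json(info, file.path(outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  new("RunReport", metrics = metrics, pooled = pooled,
      stability = stability, comparisons = comparisons,
      spectra = spectra, info = info)
}

## Scene section of a run config -> SceneConfig (accepts the same field
## names as writeSceneConfig()).
.sceneFromList <- function(x) {
  SceneConfig(
    widthPx = .cfgGet(x, "width_px", 128),
    heightPx = .cfgGet(x, "height_px", 128),
    fps = .cfgGet(x, "fps", 1000),
    durationS = .cfgGet(x, "duration_s", 2),
    pixelPitchMm = unlist(.cfgGet(x, "pixel_pitch_mm", list(0.49, 0.46))),
    backgroundLevel = .cfgGet(x, "background_level", 0.55),
    textureAmp = .cfgGet(x, "texture_amp", 0.02),
    noiseSigma = .cfgGet(x, "noise_sigma", 0.005),
    supersample = .cfgGet(x, "supersample", 8),
    markers = if (is.null(x$markers)) list(MarkerSpec())
              else lapply(x$markers, .markerFromList),
    seed = .cfgGet(x, "seed", 1))
}
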