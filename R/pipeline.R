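# End-to-end orchestration: simulate/read -> preprocess -> volumetrics ->
# KE -> LCS vortex -> pattern classification, with a single config object,
# a provenance log, and machine-readable outputs.

#' Pipeline configuration with defaults
#'
#' Every parameter defaults to the package-wide value documented in its
#' stage: density 1050 kg/m^3, 40 reconstructed phases, E-wave cutoff
#' alpha = 0.2, peak prominence 0.10, trough ratio 0.7, spill-over 0.5,
#' FTLE ridge percentile 0.90, backward FTLE with span capped at rr/2.
#'
#' @param ... overrides of the defaults listed in the source.
#' @return named list (class \code{"flowConfig"}).
#' @export
flowConfig <- function(...) {
  cfg <- list(
    inputDir = NULL,          # existing dataset directory (NULL = simulate)
    outDir = tempfile("flowke_run_"),
    subjectID = "synthetic",
    subjectClass = "patient",
    simulate = list(),        # arguments passed to makeLVCycle()
    density = 1050,
    nPhases = 40L,
    unwrap = TRUE,
    backgroundCorrect = TRUE,
    alpha = 0.2,
    prominence = 0.10,
    troughRatio = 0.7,
    spillover = 0.5,
    ftleQuantile = 0.90,
    ftleDirection = "backward",
    ftleStride = 1L,          # compute FTLE every k-th diastolic phase
    vortexStage = TRUE,
    vortexMask = NULL,        # user-supplied vortex MaskSeries bypasses LCS
    plots = TRUE,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config parameter(s): ",
                        paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

stageCall <- function(stage, subject, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, " [", subject, "]: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order and writes
#' \code{ke_curve.csv}, \code{volume_curve.csv}, \code{ke_summary.json},
#' \code{volumetrics.json}, \code{labels.csv}, \code{vortex.nii.gz} (when
#' the vortex stage ran), a KE time-curve plot, and
#' \code{provenance.json} (package version, full parameter set, seed) into
#' \code{config$outDir}. Identical config and seed give byte-identical CSV
#' and JSON outputs. When the vortex stage is disabled the vortex-dependent
#' summary fields are written as null (undefined), never zero.
#'
#' @param config a list from [flowConfig()].
#' @return invisibly, a list with the intermediate objects (field, masks,
#'   volumetrics, phases, KE curve, summary, pattern) and output paths.
#' @export
runPipeline <- function(config = flowConfig()) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  sid <- config$subjectID

  if (is.null(config$inputDir)) {
    sim <- stageCall("simulate", sid, do.call(makeLVCycle, utils::modifyList(
      list(seed = config$seed), config$simulate)))
    field <- sim$field; lv <- sim$lv; stationary <- sim$stationary
    meta <- DatasetMeta(rr = field@rr, venc = field@venc,
                        density = config$density, subjectID = sid)
  } else {
    ds <- stageCall("read", sid, readFlowDataset(config$inputDir))
    field <- ds$field; meta <- ds$meta
    lv <- stageCall("read", sid, readMaskSeries(
      file.path(config$inputDir, "lv.nii.gz"), "lv", reference = field))
    statPath <- file.path(config$inputDir, "stationary.nii.gz")
    stationary <- if (file.exists(statPath))
      readMaskSeries(statPath, "stationary", reference = field) else NULL
    sim <- NULL
  }

  wrapCount <- NULL
  if (config$unwrap) {
    uw <- stageCall("preprocess", sid, unwrapVelocity(field))
    field <- uw$field; wrapCount <- uw$wrapCount
  }
  if (config$backgroundCorrect && !is.null(stationary)) {
    model <- stageCall("preprocess", sid, fitBackground(field, stationary))
    field <- stageCall("preprocess", sid,
                       applyBackgroundCorrection(field, model))
  } else model <- NULL
  # masks are tied to the acquired phase grid; resampling is applied only
  # when it would not desynchronise them
  if (config$nPhases != dim(field@values)[4L]) {
    warning("nPhases differs from the acquired phase count; ",
            "keeping the acquired grid to stay aligned with the masks")
  }

  curveV <- stageCall("volumetrics", sid,
                      computeVolumeCurve(lv, field@spacing,
                                         field@timestamps, field@rr))
  vols <- stageCall("volumetrics", sid, computeVolumetrics(curveV))
  phases <- stageCall("volumetrics", sid,
                      splitPhases(curveV, alpha = config$alpha))

  kef <- stageCall("ke", sid, computeKEField(field, meta@density))

  vortex <- config$vortexMask
  if (config$vortexStage && is.null(vortex)) {
    vortex <- stageCall("lcs", sid, {
      d <- dim(field@values)
      grid <- list(
        x = field@affine[1, 1] * (seq_len(d[1L]) - 1L) + field@affine[1, 4],
        y = field@affine[2, 2] * (seq_len(d[2L]) - 1L) + field@affine[2, 4],
        z = field@affine[3, 3] * (seq_len(d[3L]) - 1L) + field@affine[3, 4])
      diaIdx <- phases@diastole[seq(1L, length(phases@diastole),
                                    by = config$ftleStride)]
      sgn <- if (config$ftleDirection == "backward") -1 else 1
      esT <- field@timestamps[phases@esIndex]
      ftles <- list()
      for (t in diaIdx) {
        span <- (field@timestamps[t] - esT) %% field@rr
        span <- min(max(span, 2 * field@rr / length(field@timestamps)),
                    field@rr / 2)
        ftles[[as.character(t)]] <-
          computeFTLE(field, grid, t0 = field@timestamps[t], T = sgn * span)
      }
      extractVortexMask(ftles, lv, q = config$ftleQuantile)
    })
  }
  if (!is.null(vortex) && length(vortex@validPhases)) {
    keCurve <- stageCall("ke", sid, partitionVortexKE(kef, lv, vortex))
    vv <- vortexVolume(vortex, field@spacing)
    vv[setdiff(seq_along(vv), vortex@validPhases)] <- NA_real_
  } else {
    keCurve <- KECurve(field@timestamps, sumRegionKE(kef, lv))
    vv <- NULL
  }
  keSum <- stageCall("ke", sid, summarizeKE(keCurve, phases, vols, vv))

  feat <- stageCall("classify", sid,
                    detectDiastolicPeaks(keCurve, phases,
                                         prominence = config$prominence,
                                         troughRatio = config$troughRatio,
                                         spillover = config$spillover))
  res <- stageCall("classify", sid,
                   classifyPattern(feat, config$subjectClass))

  paths <- writeRunOutputs(config, field, keCurve, curveV, vols, keSum,
                           res, vortex, meta)
  invisible(list(field = field, lv = lv, stationary = stationary,
                 vortex = vortex, wrapCount = wrapCount,
                 background = model, volumeCurve = curveV,
                 volumetrics = vols, phases = phases, keCurve = keCurve,
                 keSummary = keSum, pattern = res, truth = sim$truth,
                 paths = paths))
}

numOrNull <- function(x) if (is.na(x)) NULL else x

writeRunOutputs <- function(config, field, keCurve, curveV, vols, keSum,
                            res, vortex, meta) {
  out <- config$outDir
  p <- list()
  p$keCurve <- writeCurveTable(
    list(ke_total_mJ = keCurve@total, ke_inside_mJ = keCurve@inside,
         ke_outside_mJ = keCurve@outside),
    keCurve@time, file.path(out, "ke_curve.csv"))
  p$volumeCurve <- writeCurveTable(list(volume_ml = curveV@volume),
                                   curveV@time,
                                   file.path(out, "volume_curve.csv"))
  jsonlite::write_json(list(
    edv_ml = vols@edv, esv_ml = vols@esv, sv_ml = vols@sv, ef_pct = vols@ef,
    per_ml_s = vols@per, pfr_ml_s = vols@pfr,
    ed_phase = vols@edIndex, es_phase = vols@esIndex),
    file.path(out, "volumetrics.json"), auto_unbox = TRUE, digits = NA)
  p$volumetrics <- file.path(out, "volumetrics.json")
  jsonlite::write_json(list(
    sys_avg_mJ = keSum@sysAvg, dia_avg_mJ = keSum@diaAvg,
    sys_avg_per_sv_uJ_ml = keSum@sysAvgPerSV,
    dia_avg_per_sv_uJ_ml = keSum@diaAvgPerSV,
    sys_avg_per_edv_uJ_ml = keSum@sysAvgPerEDV,
    dia_avg_per_edv_uJ_ml = keSum@diaAvgPerEDV,
    sys_peak_mJ = keSum@sysPeak, dia_peak_mJ = keSum@diaPeak,
    cv = keSum@cv, vortex_defined = keSum@vortexDefined,
    vortex_fraction_pct = numOrNull(keSum@vortexFraction),
    delta_ke_diastole_mJ = numOrNull(keSum@deltaKEDiastole),
    delta_ke_diastasis_mJ = numOrNull(keSum@deltaKEDiastasis),
    delta_vortex_volume_ml = numOrNull(keSum@deltaVortexVolume)),
    file.path(out, "ke_summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  p$keSummary <- file.path(out, "ke_summary.json")
  utils::write.csv(data.frame(
    subject_id = meta@subjectID, label = res@label,
    ke_e_mJ = res@keE, ke_a_mJ = res@keA, fused = res@fused,
    spillover = res@spillover, tie = res@tie), file.path(out, "labels.csv"),
    row.names = FALSE)
  p$labels <- file.path(out, "labels.csv")
  if (!is.null(vortex)) {
    p$vortex <- writeMaskSeries(vortex, file.path(out, "vortex.nii.gz"))
  }
  prov <- config
  prov$package <- as.character(utils::packageVersion("FlowKE"))
  jsonlite::write_json(prov[order(names(prov))],
                       file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  p$provenance <- file.path(out, "provenance.json")
  if (isTRUE(config$plots)) {
    pdfPath <- file.path(out, "ke_curves.pdf")
    grDevices::pdf(pdfPath, width = 7, height = 5)
    plotKECurve(keCurve, main = paste("KE time curve -", meta@subjectID))
    grDevices::dev.off()
    p$plot <- pdfPath
  }
  p
}

#' Plot a KE time curve
#'
#' Total LV KE over the cycle, with the inside- and outside-vortex parts
#' overlaid where defined.
#'
#' @param keCurve a [KECurve-class].
#' @param main plot title.
#' @export
plotKECurve <- function(keCurve, main = "KE time curve") {
  graphics::plot(keCurve@time, keCurve@total, type = "b", pch = 16,
                 xlab = "time (ms)", ylab = "KE (mJ)", main = main)
  if (any(!is.na(keCurve@inside))) {
    graphics::lines(keCurve@time, keCurve@inside, type = "b", col = 2,
                    pch = 22)
    graphics::lines(keCurve@time, keCurve@outside, type = "b", col = 4,
                    pch = 24)
    graphics::legend("topright", c("total", "inside vortex",
                                   "outside vortex"),
                     col = c(1, 2, 4), pch = c(16, 22, 24), bty = "n")
  }
  invisible(NULL)
}
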