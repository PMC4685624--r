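# Accessor generics and show methods.

#' @rdname VelocityField4D-class
#' @param object,x a FlowKE object
#' @export
setGeneric("velocities", function(x) standardGeneric("velocities"))
#' @rdname VelocityField4D-class
#' @export
setMethod("velocities", "VelocityField4D", function(x) x@values)

#' @rdname VelocityField4D-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname VelocityField4D-class
#' @export
setMethod("voxelSpacing", "VelocityField4D", function(x) x@spacing)
#' @rdname MaskSeries-class
#' @export
setMethod("voxelSpacing", "MaskSeries", function(x)
  sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @rdname VelocityField4D-class
#' @export
setGeneric("phaseTimes", function(x) standardGeneric("phaseTimes"))
#' @rdname VelocityField4D-class
#' @export
setMethod("phaseTimes", "VelocityField4D", function(x) x@timestamps)
#' @rdname KECurve-class
#' @export
setMethod("phaseTimes", "KECurve", function(x) x@time)

#' @rdname VelocityField4D-class
#' @export
setGeneric("venc", function(x) standardGeneric("venc"))
#' @rdname VelocityField4D-class
#' @export
setMethod("venc", "VelocityField4D", function(x) x@venc)

#' @rdname VelocityField4D-class
#' @export
setGeneric("rrInterval", function(x) standardGeneric("rrInterval"))
#' @rdname VelocityField4D-class
#' @export
setMethod("rrInterval", "VelocityField4D", function(x) x@rr)
#' @rdname DatasetMeta-class
#' @export
setMethod("rrInterval", "DatasetMeta", function(x) x@rr)

#' @rdname MaskSeries-class
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))
#' @rdname MaskSeries-class
#' @export
setMethod("masks", "MaskSeries", function(x) x@masks)

#' @rdname MaskSeries-class
#' @export
setGeneric("validPhases", function(x) standardGeneric("validPhases"))
#' @rdname MaskSeries-class
#' @export
setMethod("validPhases", "MaskSeries", function(x) x@validPhases)

#' @rdname MaskSeries-class
#' @export
setGeneric("maskRole", function(x) standardGeneric("maskRole"))
#' @rdname MaskSeries-class
#' @export
setMethod("maskRole", "MaskSeries", function(x) x@role)

#' Tidy view of a KE curve
#' @param x a [KECurve-class]
#' @return data.frame with time_ms, ke_total_mJ, ke_inside_mJ, ke_outside_mJ.
#' @export
setGeneric("asCurveFrame", function(x) standardGeneric("asCurveFrame"))
#' @rdname asCurveFrame
#' @export
setMethod("asCurveFrame", "KECurve", function(x)
  data.frame(time_ms = x@time, ke_total_mJ = x@total,
             ke_inside_mJ = x@inside, ke_outside_mJ = x@outside))

setMethod("show", "VelocityField4D", function(object) {
  d <- dim(object@values)
  cat("VelocityField4D:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4L], "phases\n")
  cat("  spacing (mm):", paste(signif(object@spacing, 4), collapse = " x "),
      " RR (ms):", object@rr, " VENC (cm/s):", object@venc, "\n")
  spd <- sqrt(object@values[, , , , 1]^2 + object@values[, , , , 2]^2 +
                object@values[, , , , 3]^2)
  cat("  peak speed (cm/s):", signif(max(spd), 4), "\n")
})

setMethod("show", "MaskSeries", function(object) {
  d <- dim(object@masks)
  cat("MaskSeries (", object@role, "): ",
      paste(d[1:3], collapse = " x "), " voxels, ", d[4L], " phases, ",
      length(object@validPhases), " valid\n", sep = "")
})

setMethod("show", "KECurve", function(object) {
  cat("KECurve:", length(object@time), "phases, total KE",
      signif(min(object@total), 3), "-", signif(max(object@total), 3),
      "mJ;", sum(!is.na(object@inside)), "vortex phases\n")
})

setMethod("show", "KESummary", function(object) {
  cat("KESummary\n")
  cat(sprintf("  systolic avg %.3g mJ (peak %.3g), diastolic avg %.3g mJ (peak %.3g)\n",
              object@sysAvg, object@sysPeak, object@diaAvg, object@diaPeak))
  cat(sprintf("  per SV: %.3g / %.3g uJ/ml; per EDV: %.3g / %.3g uJ/ml; cv %.3g\n",
              object@sysAvgPerSV, object@diaAvgPerSV, object@sysAvgPerEDV,
              object@diaAvgPerEDV, object@cv))
  if (object@vortexDefined)
    cat(sprintf("  vortex: %.3g%% of diastolic KE inside; dKE diastole %.3g mJ, diastasis %.3g mJ\n",
                object@vortexFraction, object@deltaKEDiastole,
                object@deltaKEDiastasis))
  else cat("  vortex quantities undefined (no vortex mask supplied)\n")
})

setMethod("show", "VolumetricsSummary", function(object) {
  cat(sprintf("VolumetricsSummary: EDV %.1f ml, ESV %.1f ml, SV %.1f ml, EF %.1f%%\n",
              object@edv, object@esv, object@sv, object@ef))
  cat(sprintf("  PER %.1f ml/s, PFR %.1f ml/s (ED phase %d, ES phase %d)\n",
              object@per, object@pfr, object@edIndex, object@esIndex))
})

setMethod("show", "CardiacPhases", function(object) {
  cat(sprintf("CardiacPhases: %d phases; systole %d, diastole %d (E %d, diastasis %d, A %d)\n",
              object@nPhases, length(object@systole), length(object@diastole),
              length(object@eWave), length(object@diastasis),
              length(object@aWave)))
})

setMethod("show", "FTLEField", function(object) {
  cat(sprintf("FTLEField (%s): %s seeds, t0 %.0f ms, span %.0f ms, sigma max %.3g 1/s\n",
              object@direction, paste(dim(object@sigma), collapse = " x "),
              object@t0, object@T, max(object@sigma, na.rm = TRUE)))
})

setMethod("show", "PatternResult", function(object) {
  cat(sprintf("PatternResult: label %s (E %.3g mJ, A %.3g mJ, fused %s, spillover %s)\n",
              object@label, object@keE, object@keA, object@fused,
              object@spillover))
})
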