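# Voxel-wise kinetic energy and KE time-curve summaries. KE per voxel is
# (1/2) m v^2 with m = density * voxel volume; region curves are spatial
# sums (mJ) per phase, temporal averages are taken over the systolic or
# diastolic index sets.

#' Voxel-wise kinetic-energy field
#'
#' \code{KE = 1/2 * (density * voxel_volume) * |v|^2} per voxel, with the
#' velocity converted from cm/s to m/s, giving joules per voxel.
#'
#' @param field a [VelocityField4D-class].
#' @param density blood density, kg/m^3 (default 1050).
#' @return A [KEField-class].
#' @examples
#' # one 3 mm voxel moving at 100 cm/s: KE = 0.5*1050*2.7e-8*1 J ~ 0.0142 mJ
#' f <- VelocityField4D(array(c(100, 0, 0)[rep(1:3, each = 2)],
#'                            c(1, 1, 1, 2, 3)), spacing = c(3, 3, 3))
#' computeKEField(f)@ke[1, 1, 1, 1] * 1000
#' @export
computeKEField <- function(field, density = 1050) {
  if (density <= 0) stop("density must be positive")
  voxvolM3 <- prod(field@spacing) * 1e-9
  v <- field@values * 0.01              # cm/s -> m/s
  speed2 <- v[, , , , 1]^2 + v[, , , , 2]^2 + v[, , , , 3]^2
  d <- dim(field@values)
  ke <- array(0.5 * density * voxvolM3 * speed2, d[1:4])
  new("KEField", ke = ke, time = field@timestamps)
}

#' Region-summed KE time series
#'
#' @param kef a [KEField-class].
#' @param region a [MaskSeries-class] on the same grid.
#' @return numeric per-phase series, mJ; NA on phases where the region is
#'   undefined (no set voxel). Summation is in fixed voxel-index order.
#' @export
sumRegionKE <- function(kef, region) {
  d <- dim(kef@ke)
  if (!identical(dim(region@masks), d))
    stop("region grid does not match the KE field grid")
  nt <- d[4L]
  out <- rep(NA_real_, nt)
  for (t in region@validPhases)
    out[t] <- sum(kef@ke[, , , t][region@masks[, , , t]]) * 1000
  out
}

#' Partition LV KE into inside- and outside-vortex parts
#'
#' On every vortex-valid phase, \code{inside} is the KE summed over the
#' vortex voxels, \code{outside} over \code{lv \\ vortex}, and
#' \code{total = inside + outside} by construction (exact conservation in
#' the fixed summation order). On other phases \code{total} is the plain LV
#' sum and inside/outside are NA.
#'
#' @param kef a [KEField-class].
#' @param lv LV [MaskSeries-class].
#' @param vortex vortex [MaskSeries-class]; must satisfy
#'   \code{vortex \\subseteq lv} voxel-wise on its valid phases.
#' @param vortexPhases phases on which the vortex is considered defined;
#'   defaults to the mask's \code{validPhases}. A phase listed here with an
#'   empty vortex gives \code{inside = 0}, \code{outside = total}.
#' @return A [KECurve-class].
#' @export
partitionVortexKE <- function(kef, lv, vortex,
                              vortexPhases = vortex@validPhases) {
  d <- dim(kef@ke)
  if (!identical(dim(lv@masks), d) || !identical(dim(vortex@masks), d))
    stop("mask grids do not match the KE field grid")
  for (t in vortexPhases)
    if (any(vortex@masks[, , , t] & !lv@masks[, , , t]))
      stop("vortex mask extends outside the LV at phase ", t)
  nt <- d[4L]
  total <- sumRegionKE(kef, lv)
  inside <- rep(NA_real_, nt)
  outside <- rep(NA_real_, nt)
  for (t in vortexPhases) {
    keT <- kef@ke[, , , t]
    vx <- vortex@masks[, , , t]
    inside[t] <- sum(keT[vx]) * 1000
    outside[t] <- sum(keT[lv@masks[, , , t] & !vx]) * 1000
    total[t] <- inside[t] + outside[t]
  }
  KECurve(kef@time, total, inside, outside)
}

#' Temporal summary of a KE time curve
#'
#' Systolic/diastolic averages and peaks of total KE, averages indexed to
#' SV and EDV (uJ/ml), curve variability (sample SD / mean over the full
#' curve), the percentage of diastolic vortex-phase KE inside the vortex,
#' and the signed maximal-magnitude changes of inside-vortex KE from vortex
#' formation to end-diastole and across diastasis. Vortex-dependent fields
#' are NA with \code{vortexDefined = FALSE} when the curve carries no vortex
#' partition.
#'
#' @param curve a [KECurve-class].
#' @param phases a [CardiacPhases-class] on the same phase axis.
#' @param vols a [VolumetricsSummary-class] (for SV/EDV indexing).
#' @param vortexVolumes optional per-phase vortex volume series (ml, NA
#'   where undefined) for the delta-volume summary.
#' @return A [KESummary-class].
#' @export
summarizeKE <- function(curve, phases, vols, vortexVolumes = NULL) {
  n <- length(curve@total)
  if (n != phases@nPhases)
    stop("curve and phase partition do not share one phase axis")
  if (vols@sv == 0 || vols@edv == 0)
    stop("SV and EDV must be nonzero for indexed KE values")
  tot <- curve@total
  sysAvg <- mean(tot[phases@systole])
  diaAvg <- mean(tot[phases@diastole])
  cv <- stats::sd(tot) / mean(tot)
  vortexPhases <- intersect(which(!is.na(curve@inside)), phases@diastole)
  # order vortex phases along diastole (cyclic order from ES)
  vortexPhases <- phases@diastole[phases@diastole %in% vortexPhases]
  if (length(vortexPhases)) {
    insideAvg <- mean(curve@inside[vortexPhases])
    bothAvg <- mean(curve@inside[vortexPhases] + curve@outside[vortexPhases])
    vf <- 100 * insideAvg / bothAvg
    dkeDia <- signedMaxDelta(curve@inside[vortexPhases])
    diastasisPath <- phases@diastasis[phases@diastasis %in% vortexPhases]
    dkeDs <- signedMaxDelta(curve@inside[diastasisPath])
    dvv <- if (!is.null(vortexVolumes))
      signedMaxDelta(vortexVolumes[vortexPhases]) else NA_real_
    vdef <- TRUE
  } else {
    vf <- dkeDia <- dkeDs <- dvv <- NA_real_
    vdef <- FALSE
  }
  new("KESummary",
      sysAvg = sysAvg, diaAvg = diaAvg,
      sysAvgPerSV = sysAvg * 1000 / vols@sv,
      diaAvgPerSV = diaAvg * 1000 / vols@sv,
      sysAvgPerEDV = sysAvg * 1000 / vols@edv,
      diaAvgPerEDV = diaAvg * 1000 / vols@edv,
      sysPeak = max(tot[phases@systole]), diaPeak = max(tot[phases@diastole]),
      cv = cv, vortexFraction = vf,
      deltaKEDiastole = dkeDia, deltaKEDiastasis = dkeDs,
      deltaVortexVolume = dvv, vortexDefined = vdef)
}
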