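# LV volumetrics: volume time curve from the segmentation series, global
# volumes and rates, and the systole/diastole/diastasis phase partition.

#' LV volume time curve from a mask series
#'
#' @param lv a [MaskSeries-class] with role \code{"lv"}, defined (nonempty)
#'   on every phase.
#' @param spacing numeric(3), voxel spacing in mm; defaults to the mask's
#'   affine spacing.
#' @param time numeric per-phase timestamps, ms.
#' @param rr cycle length, ms.
#' @return A [VolumeCurve-class]; \code{volume[t] = count * dx*dy*dz / 1000}
#'   ml.
#' @export
computeVolumeCurve <- function(lv, spacing = NULL, time, rr) {
  if (is.null(spacing)) spacing <- voxelSpacing(lv)
  nt <- dim(lv@masks)[4L]
  counts <- apply(lv@masks, 4L, sum)
  if (any(counts == 0))
    stop("LV mask is empty at phase ", which(counts == 0)[1L])
  if (length(time) != nt)
    stop("time axis length does not match the mask phases")
  VolumeCurve(counts * prod(spacing) / 1000, time, rr)
}

#' Global LV volumetrics
#'
#' ED is the phase of maximum volume and ES the phase of minimum volume
#' (ties broken toward the earliest phase). SV = EDV - ESV, EF = 100 SV/EDV.
#' PER is the maximum of -dV/dt over systole and PFR the maximum of dV/dt
#' over diastole, with derivatives by cyclic central differences.
#'
#' @param curve a [VolumeCurve-class]; must not be constant.
#' @return A [VolumetricsSummary-class].
#' @examples
#' # the heart-failure cohort means: EDV 348 ml, ESV 264 ml -> SV 84 ml
#' v <- VolumeCurve(c(348, 300, 264, 310), seq(0, 750, 250), 1000)
#' computeVolumetrics(v)
#' @export
computeVolumetrics <- function(curve) {
  v <- curve@volume
  if (diff(range(v)) == 0)
    stop("constant volume curve: ED and ES are undefined")
  ed <- which.max(v)
  es <- which.min(v)
  edv <- v[ed]; esv <- v[es]
  dvdt <- cyclicDerivative(v, curve@time, curve@rr) * 1000  # ml/ms -> ml/s
  n <- length(v)
  sys <- cyclicSpan(ed, es, n)          # [ED, ES)
  dia <- cyclicSpan(es, ed, n)          # [ES, ED)
  new("VolumetricsSummary", edv = edv, esv = esv, sv = edv - esv,
      ef = 100 * (edv - esv) / edv,
      per = max(-dvdt[sys]), pfr = max(dvdt[dia]),
      edIndex = as.integer(ed), esIndex = as.integer(es))
}

# Cyclic half-open index span [from, to) on 1..n.
cyclicSpan <- function(from, to, n) {
  len <- (to - from) %% n
  if (len == 0L) len <- n
  ((from - 1L + seq_len(len) - 1L) %% n) + 1L
}

#' Partition the cycle into cardiac phases
#'
#' Systole is \code{[ED, ES)} and diastole \code{[ES, ED)}. Within diastole,
#' the E-wave runs from ES until the filling rate dV/dt first falls below
#' \code{alpha * PFR} after the PFR peak; the A-wave runs from the onset of
#' the last diastolic dV/dt local maximum to ED; diastasis is the (possibly
#' empty) remainder between them. The dV/dt-based E/A timing is a surrogate
#' for transmitral-flow timing and is documented as such.
#'
#' @param curve a [VolumeCurve-class].
#' @param alpha fraction of PFR terminating the E-wave (default 0.2).
#' @param smooth if TRUE, apply a cyclic 3-point moving average to the
#'   volume curve before differentiation (for noisy manual masks; default
#'   FALSE).
#' @return A [CardiacPhases-class] with indices on the original phase axis.
#' @export
splitPhases <- function(curve, alpha = 0.2, smooth = FALSE) {
  v <- curve@volume
  n <- length(v)
  if (smooth) {
    v <- (v[c(n, 1:(n - 1L))] + v + v[c(2:n, 1L)]) / 3
    curve@volume <- v
  }
  vols <- computeVolumetrics(curve)
  ed <- vols@edIndex; es <- vols@esIndex
  sys <- cyclicSpan(ed, es, n)
  dia <- cyclicSpan(es, ed, n)
  if (length(dia) < 2L)
    stop("diastole spans fewer than 2 phases")
  dvdt <- cyclicDerivative(curve@volume, curve@time, curve@rr) * 1000
  d <- dvdt[dia]                        # filling rate along diastole
  pfr <- vols@pfr
  pk <- which.max(d)
  thr <- alpha * pfr
  after <- which(seq_along(d) > pk & d < thr)
  eEnd <- if (length(after)) after[1L] - 1L else length(d)  # last E index
  # last local maximum of d after the E-wave (candidates for the A-peak)
  aStart <- NA_integer_
  if (eEnd < length(d)) {
    dd <- d
    isMax <- vapply(seq_along(dd), function(i) {
      left <- if (i > 1L) dd[i - 1L] else -Inf
      right <- if (i < length(dd)) dd[i + 1L] else -Inf
      dd[i] > left && dd[i] >= right
    }, logical(1))
    cand <- which(isMax & seq_along(dd) > eEnd & dd > thr)
    if (length(cand)) {
      aPk <- cand[length(cand)]
      m <- aPk
      while (m > eEnd + 1L && d[m - 1L] >= thr) m <- m - 1L
      aStart <- m
    }
  }
  if (is.na(aStart)) {
    eWave <- dia[seq_len(eEnd)]
    diastasis <- if (eEnd < length(d)) dia[(eEnd + 1L):length(d)] else integer()
    aWave <- integer()
  } else {
    eWave <- dia[seq_len(eEnd)]
    aWave <- dia[aStart:length(d)]
    diastasis <- if (aStart > eEnd + 1L) dia[(eEnd + 1L):(aStart - 1L)]
      else integer()
  }
  new("CardiacPhases", systole = as.integer(sys), diastole = as.integer(dia),
      eWave = as.integer(eWave), diastasis = as.integer(diastasis),
      aWave = as.integer(aWave), edIndex = as.integer(ed),
      esIndex = as.integer(es), nPhases = as.integer(n))
}
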