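#' Construct a VelocityField4D
#'
#' @param values numeric array \code{(nx, ny, nz, nt, 3)}, cm/s.
#' @param spacing numeric(3), mm.
#' @param timestamps numeric(nt), ms; defaults to uniform phases over
#'   \code{[0, rr)}.
#' @param rr cycle length, ms.
#' @param venc velocity-encoding limit, cm/s.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal scaling
#'   by \code{spacing}.
#' @return A [VelocityField4D-class] object.
#' @examples
#' v <- VelocityField4D(array(0, c(4, 4, 4, 5, 3)), spacing = c(3, 3, 3),
#'                      rr = 1000, venc = 100)
#' dim(velocities(v))
#' @export
VelocityField4D <- function(values, spacing, timestamps = NULL, rr = 1000,
                            venc = 100, affine = NULL) {
  nt <- dim(values)[4L]
  if (is.null(timestamps))
    timestamps <- seq(0, rr, length.out = nt + 1L)[seq_len(nt)]
  if (is.null(affine)) affine <- defaultAffine(spacing)
  new("VelocityField4D", values = values, spacing = as.numeric(spacing),
      timestamps = as.numeric(timestamps), rr = as.numeric(rr),
      venc = as.numeric(venc), affine = affine)
}

#' Construct a MaskSeries
#'
#' @param masks logical (or 0/1) array \code{(nx, ny, nz, nt)}.
#' @param role \code{"lv"}, \code{"stationary"} or \code{"vortex"}.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @return A [MaskSeries-class]; \code{validPhases} are the phases with at
#'   least one set voxel.
#' @export
MaskSeries <- function(masks, role = c("lv", "stationary", "vortex"),
                       affine = NULL) {
  role <- match.arg(role)
  storage.mode(masks) <- "logical"
  if (is.null(affine)) affine <- defaultAffine(c(1, 1, 1))
  vp <- which(apply(masks, 4L, any))
  new("MaskSeries", role = role, masks = masks,
      validPhases = as.integer(vp), affine = affine)
}

#' Construct dataset metadata
#' @param rr RR interval, ms.
#' @param venc cm/s.
#' @param density blood density, kg/m^3; 1050 by default.
#' @param subjectID character label.
#' @export
DatasetMeta <- function(rr = 1000, venc = 100, density = 1050,
                        subjectID = "anonymous") {
  new("DatasetMeta", rr = as.numeric(rr), venc = as.numeric(venc),
      density = as.numeric(density), subjectID = subjectID)
}

#' Construct a KECurve
#' @param time ms per phase.
#' @param total mJ per phase.
#' @param inside,outside mJ per phase, NA where the vortex is undefined.
#' @export
KECurve <- function(time, total, inside = rep(NA_real_, length(time)),
                    outside = rep(NA_real_, length(time))) {
  new("KECurve", time = as.numeric(time), total = as.numeric(total),
      inside = as.numeric(inside), outside = as.numeric(outside))
}

#' Construct a VolumeCurve
#' @param volume ml per phase.
#' @param time ms per phase.
#' @param rr cycle length, ms.
#' @export
VolumeCurve <- function(volume, time, rr) {
  new("VolumeCurve", volume = as.numeric(volume), time = as.numeric(time),
      rr = as.numeric(rr))
}
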