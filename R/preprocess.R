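# Phase-contrast preprocessing: temporal velocity unwrapping, linear
# background-phase correction from stationary tissue, and cyclic resampling
# of the cardiac cycle to a fixed number of phases. The stage order fixed by
# this package is unwrap -> fit -> correct -> resample.

#' Temporal velocity unwrapping
#'
#' Phase-contrast velocities alias modulo \code{2 * venc}. This corrects
#' aliasing voxel-wise along the phase axis: wherever the difference between
#' consecutive phases exceeds VENC, integer multiples of \code{2 * venc} are
#' added to minimise temporal jumps. The first phase is taken as unaliased,
#' so a voxel aliased at every phase (no temporal jump) is not recovered -
#' the documented limitation of purely temporal unwrapping.
#'
#' @param field a [VelocityField4D-class] with at least 3 phases.
#' @return \code{list(field, wrapCount)} where \code{wrapCount} is an
#'   integer \code{(nx, ny, nz)} lattice counting applied corrections
#'   (summed over components and phases).
#' @export
unwrapVelocity <- function(field) {
  d <- dim(field@values)
  nt <- d[4L]
  if (nt < 3L)
    stop("temporal unwrapping requires at least 3 phases (nt >= 3)")
  twoVenc <- 2 * field@venc
  nvox <- prod(d[1:3])
  out <- field@values
  wrapCount <- integer(nvox)
  for (c in 1:3) {
    v <- matrix(field@values[, , , , c], nvox, nt)
    for (t in 2:nt) {
      k <- round((v[, t] - v[, t - 1L]) / twoVenc)
      nz <- k != 0
      if (any(nz)) {
        v[nz, t] <- v[nz, t] - twoVenc * k[nz]
        wrapCount[nz] <- wrapCount[nz] + 1L
      }
    }
    out[, , , , c] <- v
  }
  corrected <- field
  corrected@values <- out
  list(field = corrected, wrapCount = array(wrapCount, d[1:3]))
}

#' Apply the velocity-aliasing wrap model
#'
#' Maps true velocities to their measured (aliased) values,
#' \code{((v + venc) mod 2*venc) - venc}. Used by the synthetic generator to
#' inject wraps; exposed because it is the exact inverse model the unwrapper
#' assumes.
#'
#' @param v numeric, true velocities (cm/s).
#' @param venc velocity-encoding limit (cm/s).
#' @export
wrapModel <- function(v, venc) {
  ((v + venc) %% (2 * venc)) - venc
}

#' Fit the linear background-phase model
#'
#' Least-squares fit of \code{v ~ a + b x + c y + d z} per phase and
#' velocity component over stationary-tissue voxel centres (physical mm,
#' centred on the per-phase stationary centroid for conditioning).
#'
#' @param field a [VelocityField4D-class].
#' @param stationary a [MaskSeries-class] with role \code{"stationary"};
#'   at least 16 voxels per phase, not coplanar.
#' @return A [BackgroundModel-class].
#' @export
fitBackground <- function(field, stationary) {
  d <- dim(field@values)
  if (!identical(dim(stationary@masks), d[1:4]))
    stop("stationary mask grid does not match the velocity grid")
  nt <- d[4L]
  coeffs <- array(NA_real_, c(nt, 3L, 4L))
  center <- matrix(NA_real_, nt, 3L)
  nvox <- prod(d[1:3])
  for (t in seq_len(nt)) {
    idx <- which(stationary@masks[, , , t])
    if (length(idx) < 16L)
      stop("phase ", t, ": fewer than 16 stationary voxels (",
           length(idx), ")")
    xyz <- voxelCoords(field@affine, d[1:3], idx)
    ctr <- colMeans(xyz)
    X <- cbind(1, sweep(xyz, 2L, ctr))
    qrX <- qr(X)
    if (qrX$rank < 4L)
      stop("phase ", t, ": stationary voxels are coplanar/collinear, ",
           "background fit is rank-deficient")
    for (c in 1:3) {
      v <- field@values[, , , t, c][idx]
      coeffs[t, c, ] <- qr.coef(qrX, v)
    }
    center[t, ] <- ctr
  }
  new("BackgroundModel", coeffs = coeffs, center = center,
      timestamps = field@timestamps)
}

#' Background-model coefficients
#'
#' @param model a [BackgroundModel-class].
#' @param centered if FALSE (default), the offset is re-expressed in
#'   absolute physical coordinates: \code{a_abs = a - b cx - c cy - d cz}.
#' @return numeric array \code{(nt, 3, 4)}, (offset cm/s, slopes cm/s/mm).
#' @export
backgroundCoefficients <- function(model, centered = FALSE) {
  out <- model@coeffs
  if (!centered) {
    for (t in seq_len(dim(out)[1L]))
      out[t, , 1L] <- out[t, , 1L] - out[t, , 2:4] %*% model@center[t, ]
  }
  out
}

#' Subtract the fitted background field
#'
#' @param field a [VelocityField4D-class].
#' @param model a [BackgroundModel-class] fitted on the same phase axis.
#' @return Corrected [VelocityField4D-class].
#' @export
applyBackgroundCorrection <- function(field, model) {
  d <- dim(field@values)
  nt <- d[4L]
  if (dim(model@coeffs)[1L] != nt ||
      !isTRUE(all.equal(model@timestamps, field@timestamps)))
    stop("background model phases do not match the field phases")
  cc <- latticeCoords(field@affine, d[1:3])
  out <- field@values
  for (t in seq_len(nt)) {
    xc <- cc$x - model@center[t, 1L]
    yc <- cc$y - model@center[t, 2L]
    zc <- cc$z - model@center[t, 3L]
    for (c in 1:3) {
      b <- model@coeffs[t, c, ]
      out[, , , t, c] <- out[, , , t, c] -
        (b[1L] + b[2L] * xc + b[3L] * yc + b[4L] * zc)
    }
  }
  field@values <- out
  field
}

#' Resample the cardiac cycle to a fixed number of phases
#'
#' Periodic (cyclic) linear interpolation in time, voxel-wise and per
#' component, onto \code{nTarget} uniformly spaced timestamps over
#' \code{[0, rr)}. 40 phases is the conventional reconstruction target.
#'
#' @param field a [VelocityField4D-class].
#' @param nTarget integer >= 2, number of output phases (default 40).
#' @return A [VelocityField4D-class] with \code{nTarget} phases.
#' @export
resamplePhases <- function(field, nTarget = 40L) {
  nTarget <- as.integer(nTarget)
  if (nTarget < 2L) stop("nTarget must be at least 2")
  d <- dim(field@values)
  nt <- d[4L]
  ts <- field@timestamps
  newTs <- seq(0, field@rr, length.out = nTarget + 1L)[seq_len(nTarget)]
  if (nTarget == nt && isTRUE(all.equal(newTs, ts))) return(field)
  out <- array(0, c(d[1:3], nTarget, 3L))
  for (p in seq_len(nTarget)) {
    u <- newTs[p]
    i <- findInterval(u, ts)
    if (i == 0L) {
      t1 <- ts[nt] - field@rr; t2 <- ts[1L]; i1 <- nt; i2 <- 1L
    } else if (i == nt) {
      t1 <- ts[nt]; t2 <- ts[1L] + field@rr; i1 <- nt; i2 <- 1L
    } else {
      t1 <- ts[i]; t2 <- ts[i + 1L]; i1 <- i; i2 <- i + 1L
    }
    w <- (u - t1) / (t2 - t1)
    out[, , , p, ] <- (1 - w) * field@values[, , , i1, ] +
      w * field@values[, , , i2, ]
  }
  VelocityField4D(out, spacing = field@spacing, timestamps = newTs,
                  rr = field@rr, venc = field@venc, affine = field@affine)
}
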