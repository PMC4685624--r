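# I/O for 4D-flow datasets: three scalar 4D NIfTI component volumes plus a
# JSON sidecar (no interchange standard exists for 4D flow, so the package
# fixes this convention), segmentation series as 4D NIfTI label volumes, and
# CSV tables for time curves.

sidecarName <- "flow.json"
componentFiles <- c(vx = "vx.nii.gz", vy = "vy.nii.gz", vz = "vz.nii.gz")

writeNiftiVolume <- function(arr, path, spacing, affine) {
  img <- RNifti::asNifti(arr, pixdim = c(spacing, 1))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  attr(aff, "code") <- NULL
  attr(aff, "imagedim") <- NULL
  list(data = as.array(img), affine = unclass(aff)[1:4, 1:4])
}

#' Write a 4D-flow dataset
#'
#' Writes the three velocity components as scalar 4D NIfTI files
#' (\code{vx/vy/vz.nii.gz}, cm/s, patient frame of the affine) and a JSON
#' sidecar \code{flow.json} holding \code{rr_ms}, \code{venc_cm_s},
#' \code{timestamps_ms}, \code{density_kg_m3} and \code{subject_id}.
#'
#' @param field a [VelocityField4D-class].
#' @param meta a [DatasetMeta-class]; its rr/venc must agree with the field.
#' @param path output directory (created if absent).
#' @return \code{path}, invisibly.
#' @seealso [readFlowDataset()]
#' @export
writeFlowDataset <- function(field, meta, path) {
  stopifnot(is(field, "VelocityField4D"), is(meta, "DatasetMeta"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (c in 1:3)
    writeNiftiVolume(field@values[, , , , c, drop = TRUE],
                     file.path(path, componentFiles[c]),
                     field@spacing, field@affine)
  sidecar <- list(rr_ms = field@rr, venc_cm_s = field@venc,
                  timestamps_ms = field@timestamps,
                  density_kg_m3 = meta@density, subject_id = meta@subjectID)
  jsonlite::write_json(sidecar, file.path(path, sidecarName),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 4D-flow dataset
#'
#' Expects the directory layout written by [writeFlowDataset()]. All three
#' component grids must be identical; the sidecar supplies timing and VENC.
#' Violations are rejected with the offending field named.
#'
#' @param path dataset directory.
#' @return \code{list(field = VelocityField4D, meta = DatasetMeta)}.
#' @export
readFlowDataset <- function(path) {
  side <- file.path(path, sidecarName)
  if (!file.exists(side)) stop("missing sidecar file: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (key in c("rr_ms", "venc_cm_s", "timestamps_ms"))
    if (is.null(meta[[key]])) stop("sidecar field missing: ", key)
  ts <- as.numeric(meta$timestamps_ms)
  if (is.unsorted(ts, strictly = TRUE))
    stop("sidecar field timestamps_ms: timestamps not strictly increasing")
  comps <- vector("list", 3L)
  aff <- NULL; dims <- NULL
  for (c in 1:3) {
    f <- file.path(path, componentFiles[c])
    if (!file.exists(f))
      stop("missing component file: ", names(componentFiles)[c],
           " (", f, ")")
    vol <- readNiftiVolume(f)
    if (is.null(dims)) {
      dims <- dim(vol$data); aff <- vol$affine
    } else if (!identical(dim(vol$data), dims)) {
      stop("grid shape mismatch in component ", names(componentFiles)[c],
           ": ", paste(dim(vol$data), collapse = "x"), " vs ",
           paste(dims, collapse = "x"))
    }
    comps[[c]] <- vol$data
  }
  if (length(dims) != 4L) stop("component volumes must be 4D (x, y, z, phase)")
  if (length(ts) != dims[4L])
    stop("sidecar field timestamps_ms: length ", length(ts),
         " does not match ", dims[4L], " phases")
  values <- array(0, c(dims, 3L))
  for (c in 1:3) values[, , , , c] <- comps[[c]]
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  field <- VelocityField4D(values, spacing = spacing, timestamps = ts,
                           rr = as.numeric(meta$rr_ms),
                           venc = as.numeric(meta$venc_cm_s), affine = aff)
  dm <- DatasetMeta(rr = field@rr, venc = field@venc,
                    density = as.numeric(meta$density_kg_m3 %||% 1050),
                    subjectID = as.character(meta$subject_id %||% "anonymous"))
  list(field = field, meta = dm)
}

#' Read a segmentation series
#'
#' Reads a 4D NIfTI of 0/1 integers into a [MaskSeries-class]. Phases
#' without any set voxel are excluded from \code{validPhases}.
#'
#' @param path NIfTI file.
#' @param role \code{"lv"}, \code{"stationary"} or \code{"vortex"}.
#' @param reference optional [VelocityField4D-class]; the mask grid must
#'   match its grid.
#' @return A [MaskSeries-class].
#' @export
readMaskSeries <- function(path, role = c("lv", "stationary", "vortex"),
                           reference = NULL) {
  role <- match.arg(role)
  vol <- readNiftiVolume(path)
  vals <- vol$data
  if (length(dim(vals)) == 3L) dim(vals) <- c(dim(vals), 1L)
  if (length(dim(vals)) != 4L) stop("mask volume must be 3D or 4D")
  if (any(!vals %in% c(0, 1)))
    stop("mask contains non-binary values (expected 0/1 integers)")
  if (!is.null(reference)) {
    refDims <- dim(reference@values)[1:4]
    if (!identical(dim(vals), refDims))
      stop("mask grid ", paste(dim(vals), collapse = "x"),
           " does not match reference field grid ",
           paste(refDims, collapse = "x"))
  }
  MaskSeries(vals == 1, role = role, affine = vol$affine)
}

#' Write a segmentation series
#' @param mask a [MaskSeries-class].
#' @param path output NIfTI file.
#' @export
writeMaskSeries <- function(mask, path) {
  arr <- array(as.integer(mask@masks), dim(mask@masks))
  spacing <- sqrt(colSums(mask@affine[1:3, 1:3]^2))
  writeNiftiVolume(arr, path, spacing, mask@affine)
  invisible(path)
}

#' Write per-phase time curves to CSV
#'
#' Column names are fixed: \code{time_ms} followed by one column per series.
#'
#' @param curves named list of numeric per-phase series (may be empty), all
#'   sharing the phase axis of \code{time}.
#' @param time numeric, ms per phase.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeCurveTable <- function(curves, time, path) {
  if (length(curves)) {
    len <- vapply(curves, length, integer(1))
    bad <- which(len != length(time))
    if (length(bad))
      stop("series length mismatch: '", names(curves)[bad[1L]], "' has ",
           len[bad[1L]], " values for ", length(time), " phases")
  }
  df <- data.frame(time_ms = time)
  for (nm in names(curves)) df[[nm]] <- curves[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a curve table written by [writeCurveTable()]
#' @param path CSV file.
#' @return data.frame with a \code{time_ms} column.
#' @export
readCurveTable <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
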