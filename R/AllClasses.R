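#' @import methods
NULL

#' Time-resolved three-directional velocity field
#'
#' Container for a 4D-flow velocity lattice: three velocity components on a
#' regular voxel grid, resolved over the cardiac cycle. Velocities are stored
#' in cm/s (the acquisition unit); positions are physical millimetres obtained
#' through the voxel-to-world affine.
#'
#' @slot values numeric array of dimension \code{(nx, ny, nz, nt, 3)}; the
#'   last axis holds the x/y/z velocity components in the physical frame of
#'   the affine, cm/s.
#' @slot spacing numeric(3), voxel edge lengths in mm.
#' @slot timestamps numeric(nt), trigger times of the cardiac phases in ms,
#'   strictly increasing and all smaller than \code{rr}.
#' @slot rr numeric(1), cardiac cycle length (RR interval) in ms.
#' @slot venc numeric(1), velocity-encoding limit in cm/s; measured
#'   velocities alias modulo \code{2 * venc}.
#' @slot affine 4x4 matrix mapping 0-based voxel indices to physical mm.
#'
#' @seealso [readFlowDataset()], [writeFlowDataset()], [computeKEField()]
#' @export
setClass("VelocityField4D",
  representation(
    values     = "array",
    spacing    = "numeric",
    timestamps = "numeric",
    rr         = "numeric",
    venc       = "numeric",
    affine     = "matrix"
  )
)

setValidity("VelocityField4D", function(object) {
  d <- dim(object@values)
  msgs <- character()
  if (length(d) != 5L || d[5L] != 3L)
    msgs <- c(msgs, "values must be a 5D array (nx, ny, nz, nt, 3)")
  else if (d[4L] < 2L)
    msgs <- c(msgs, "at least two cardiac phases are required (nt >= 2)")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be three positive values (mm)")
  if (length(object@rr) != 1L || object@rr <= 0)
    msgs <- c(msgs, "rr must be a single positive cycle length (ms)")
  if (length(d) == 5L && length(object@timestamps) != d[4L])
    msgs <- c(msgs, "timestamps length must equal the number of phases")
  if (is.unsorted(object@timestamps, strictly = TRUE))
    msgs <- c(msgs, "timestamps must be strictly increasing")
  if (any(object@timestamps < 0) || any(object@timestamps >= object@rr))
    msgs <- c(msgs, "timestamps must lie within [0, rr)")
  if (length(object@venc) != 1L || object@venc <= 0)
    msgs <- c(msgs, "venc must be a single positive value (cm/s)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msgs <- c(msgs, "affine must be a 4x4 matrix")
  if (length(msgs)) msgs else TRUE
})

#' Per-phase binary segmentation series
#'
#' Binary region labels on the same grid as a [VelocityField4D-class], one
#' volume per cardiac phase. Roles: \code{"lv"} (LV blood pool),
#' \code{"stationary"} (static tissue used for background-phase fitting) and
#' \code{"vortex"} (diastolic vortex-ring region).
#'
#' @slot role character(1), one of \code{"lv"}, \code{"stationary"},
#'   \code{"vortex"}.
#' @slot masks logical array \code{(nx, ny, nz, nt)}.
#' @slot validPhases integer vector of phase indices on which the mask is
#'   defined (has at least one set voxel).
#' @slot affine 4x4 voxel-to-world matrix (mm), matching the paired field.
#'
#' @export
setClass("MaskSeries",
  representation(
    role        = "character",
    masks       = "array",
    validPhases = "integer",
    affine      = "matrix"
  )
)

setValidity("MaskSeries", function(object) {
  msgs <- character()
  if (!object@role %in% c("lv", "stationary", "vortex"))
    msgs <- c(msgs, "role must be one of 'lv', 'stationary', 'vortex'")
  if (length(dim(object@masks)) != 4L)
    msgs <- c(msgs, "masks must be a 4D array (nx, ny, nz, nt)")
  if (!is.logical(object@masks))
    msgs <- c(msgs, "masks must be logical")
  nt <- dim(object@masks)[4L]
  if (any(object@validPhases < 1L) || any(object@validPhases > nt))
    msgs <- c(msgs, "validPhases out of range")
  if (length(msgs)) msgs else TRUE
})

#' Acquisition and subject metadata
#'
#' @slot rr numeric(1), RR interval, ms.
#' @slot venc numeric(1), velocity-encoding limit, cm/s.
#' @slot density numeric(1), blood density, kg/m^3 (default 1050).
#' @slot subjectID character(1).
#' @export
setClass("DatasetMeta",
  representation(rr = "numeric", venc = "numeric", density = "numeric",
                 subjectID = "character"),
  prototype(density = 1050, subjectID = "anonymous")
)

setValidity("DatasetMeta", function(object) {
  msgs <- character()
  if (object@density <= 0) msgs <- c(msgs, "density must be positive")
  if (object@rr <= 0) msgs <- c(msgs, "rr must be positive")
  if (object@venc <= 0) msgs <- c(msgs, "venc must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Linear background-phase model
#'
#' Per phase and velocity component, a first-order spatial model
#' \eqn{v \approx a + b x + c y + d z} fitted over stationary-tissue voxels,
#' used to remove eddy-current-like phase offsets. Coefficients are stored
#' relative to spatial coordinates centred on the per-phase stationary-voxel
#' centroid (for conditioning); [backgroundCoefficients()] converts to
#' absolute coordinates.
#'
#' @slot coeffs numeric array \code{(nt, 3, 4)}: phase x component x
#'   (offset, slope_x, slope_y, slope_z), units cm/s and cm/s/mm.
#' @slot center numeric matrix \code{(nt, 3)}, per-phase centroid (mm) about
#'   which the spatial regressors were centred.
#' @slot timestamps numeric(nt), ms, copied from the fitted field.
#' @export
setClass("BackgroundModel",
  representation(coeffs = "array", center = "matrix", timestamps = "numeric")
)

#' LV volume time curve
#'
#' @slot volume numeric, ml per phase (non-negative).
#' @slot time numeric, ms per phase.
#' @slot rr numeric(1), cycle length in ms (needed for cyclic derivatives).
#' @export
setClass("VolumeCurve",
  representation(volume = "numeric", time = "numeric", rr = "numeric")
)

setValidity("VolumeCurve", function(object) {
  msgs <- character()
  if (length(object@volume) != length(object@time))
    msgs <- c(msgs, "volume and time must have equal length")
  if (any(object@volume < 0)) msgs <- c(msgs, "volumes must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Global LV volumetric summary
#'
#' @slot edv,esv,sv numeric(1), end-diastolic/end-systolic/stroke volume, ml;
#'   \code{sv == edv - esv} exactly.
#' @slot ef numeric(1), ejection fraction, percent.
#' @slot per,pfr numeric(1), peak emptying and peak filling rate, ml/s.
#' @slot edIndex,esIndex integer(1), phase indices of ED and ES.
#' @export
setClass("VolumetricsSummary",
  representation(edv = "numeric", esv = "numeric", sv = "numeric",
                 ef = "numeric", per = "numeric", pfr = "numeric",
                 edIndex = "integer", esIndex = "integer")
)

setValidity("VolumetricsSummary", function(object) {
  msgs <- character()
  if (!isTRUE(all.equal(object@sv, object@edv - object@esv)))
    msgs <- c(msgs, "sv must equal edv - esv")
  if (object@ef < 0 || object@ef > 100)
    msgs <- c(msgs, "ef must lie in [0, 100]")
  if (length(msgs)) msgs else TRUE
})

#' Cardiac phase partition
#'
#' Index sets (1-based, on the original phase axis) partitioning the cycle
#' into systole \code{[ED, ES)} and diastole \code{[ES, ED)}, with diastole
#' further split into E-wave, diastasis and A-wave subsets (any of which may
#' be empty).
#'
#' @slot systole,diastole integer index vectors; together they cover every
#'   phase exactly once.
#' @slot eWave,diastasis,aWave disjoint integer subsets of \code{diastole}.
#' @slot edIndex,esIndex integer(1).
#' @slot nPhases integer(1).
#' @export
setClass("CardiacPhases",
  representation(systole = "integer", diastole = "integer",
                 eWave = "integer", diastasis = "integer", aWave = "integer",
                 edIndex = "integer", esIndex = "integer",
                 nPhases = "integer")
)

setValidity("CardiacPhases", function(object) {
  msgs <- character()
  allp <- sort(c(object@systole, object@diastole))
  if (!identical(allp, seq_len(object@nPhases)))
    msgs <- c(msgs, "systole and diastole must partition all phases")
  sub <- c(object@eWave, object@diastasis, object@aWave)
  if (anyDuplicated(sub))
    msgs <- c(msgs, "eWave/diastasis/aWave must be disjoint")
  if (!all(sub %in% object@diastole))
    msgs <- c(msgs, "eWave/diastasis/aWave must be subsets of diastole")
  if (length(msgs)) msgs else TRUE
})

#' Voxel-wise kinetic-energy field
#'
#' @slot ke numeric array \code{(nx, ny, nz, nt)}, joules per voxel.
#' @slot time numeric(nt), ms.
#' @export
setClass("KEField", representation(ke = "array", time = "numeric"))

setValidity("KEField", function(object) {
  if (any(object@ke < 0)) "kinetic energy must be non-negative" else TRUE
})

#' Kinetic-energy time curve
#'
#' Total KE inside the LV per phase, optionally partitioned into the part
#' inside and outside the diastolic vortex ring (NA on phases where the
#' vortex is not defined).
#'
#' @slot time numeric, ms.
#' @slot total numeric, mJ per phase.
#' @slot inside,outside numeric, mJ per phase or NA where undefined; where
#'   defined, \code{inside + outside == total}.
#' @export
setClass("KECurve",
  representation(time = "numeric", total = "numeric",
                 inside = "numeric", outside = "numeric")
)

setValidity("KECurve", function(object) {
  n <- length(object@time)
  if (length(object@total) != n || length(object@inside) != n ||
      length(object@outside) != n)
    return("time, total, inside, outside must share one phase axis")
  if (any(object@total < 0, na.rm = TRUE))
    return("total KE must be non-negative")
  TRUE
})

#' Temporal KE summary
#'
#' Systolic/diastolic temporal averages and peaks of the LV KE time curve,
#' values indexed to SV and EDV, curve variability, and diastolic-vortex
#' quantities. Vortex-dependent fields are NA (with \code{vortexDefined ==
#' FALSE}) when no vortex mask was supplied - never silently zero.
#'
#' @slot sysAvg,diaAvg numeric(1), mJ.
#' @slot sysAvgPerSV,diaAvgPerSV,sysAvgPerEDV,diaAvgPerEDV numeric(1), uJ/ml.
#' @slot sysPeak,diaPeak numeric(1), mJ.
#' @slot cv numeric(1), SD/mean of the full KE time curve (sample SD).
#' @slot vortexFraction numeric(1), percent of diastolic vortex-phase KE
#'   residing inside the vortex ring.
#' @slot deltaKEDiastole,deltaKEDiastasis numeric(1), mJ, signed change of
#'   maximal magnitude of inside-vortex KE from vortex formation to
#'   end-diastole / across diastasis.
#' @slot deltaVortexVolume numeric(1), ml, same rule applied to the vortex
#'   volume series.
#' @slot vortexDefined logical(1).
#' @export
setClass("KESummary",
  representation(sysAvg = "numeric", diaAvg = "numeric",
                 sysAvgPerSV = "numeric", diaAvgPerSV = "numeric",
                 sysAvgPerEDV = "numeric", diaAvgPerEDV = "numeric",
                 sysPeak = "numeric", diaPeak = "numeric", cv = "numeric",
                 vortexFraction = "numeric",
                 deltaKEDiastole = "numeric", deltaKEDiastasis = "numeric",
                 deltaVortexVolume = "numeric", vortexDefined = "logical")
)

#' Traced particle trajectories
#'
#' @slot seeds numeric matrix \code{(n, 3)}, initial positions, mm.
#' @slot times numeric, integration time grid, ms.
#' @slot positions numeric array \code{(n, length(times), 3)}, mm.
#' @slot leftDomain logical(n), TRUE where the particle exited the grid and
#'   was frozen at its last in-domain position.
#' @export
setClass("TrajectorySet",
  representation(seeds = "matrix", times = "numeric",
                 positions = "array", leftDomain = "logical")
)

#' Finite-time Lyapunov exponent field
#'
#' @slot sigma numeric 3D array, FTLE in 1/s on the seed grid; NA on the
#'   boundary layer and where trajectories (or their neighbours) left the
#'   domain.
#' @slot coords list of numeric vectors \code{x}, \code{y}, \code{z}: seed
#'   grid coordinates, mm.
#' @slot t0 numeric(1), seeding time, ms.
#' @slot T numeric(1), signed integration span, ms (negative = backward).
#' @slot direction character(1), \code{"forward"} or \code{"backward"}.
#' @export
setClass("FTLEField",
  representation(sigma = "array", coords = "list", t0 = "numeric",
                 T = "numeric", direction = "character")
)

setValidity("FTLEField", function(object) {
  msgs <- character()
  if (object@T == 0) msgs <- c(msgs, "integration span T must be nonzero")
  if (!object@direction %in% c("forward", "backward"))
    msgs <- c(msgs, "direction must be 'forward' or 'backward'")
  if (length(msgs)) msgs else TRUE
})

#' Diastolic KE curve pattern features and label
#'
#' @slot keE,keA numeric(1), diastolic peak KE at the E- and A-wave, mJ
#'   (NA when the peaks are fused).
#' @slot fused logical(1), fewer than two separable diastolic peaks.
#' @slot spillover logical(1), late-diastolic KE persisting into the onset
#'   of systole.
#' @slot label character(1), one of \code{"control_like"}, \code{"p1"},
#'   \code{"p2"}, \code{"p3"} or NA before classification.
#' @slot tie logical(1), TRUE when keE == keA exactly (label forced).
#' @slot params list of detector thresholds used.
#' @export
setClass("PatternResult",
  representation(keE = "numeric", keA = "numeric", fused = "logical",
                 spillover = "logical", label = "character", tie = "logical",
                 params = "list")
)

#' Pattern-vs-grade agreement table
#'
#' @slot counts square integer matrix, KE-curve pattern x
#'   diastolic-dysfunction grade.
#' @slot excluded integer(1), subjects excluded for undetermined grade.
#' @export
setClass("AgreementTable",
  representation(counts = "matrix", excluded = "integer")
)

setValidity("AgreementTable", function(object) {
  msgs <- character()
  if (nrow(object@counts) != ncol(object@counts))
    msgs <- c(msgs, "counts must be square")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})
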