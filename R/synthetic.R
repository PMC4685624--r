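# Synthetic flow generator: analytic benchmark fields (Hill's spherical
# vortex, the time-periodic double gyre) and a beating-LV phantom whose
# volume curve, background coefficients, vortex sphere and KE-curve pattern
# are known exactly. The LV is an axis-aligned ellipsoid with time-varying
# semi-axes: geometric realism is traded for exact volume control, which is
# what downstream tests need.

logistic <- function(t, mu, w) 1 / (1 + exp(-(t - mu) / w))
gaussBump <- function(t, mu, sig) exp(-0.5 * ((t - mu) / sig)^2)

#' Hill's spherical vortex velocity field
#'
#' Classic Hill vortex of radius \code{a} translating at speed \code{U}
#' along +z: rotational interior flow matched to potential (dipole) flow
#' outside the sphere; divergence-free analytically. In the \code{"lab"}
#' frame the fluid is at rest at infinity; in the \code{"comoving"} frame a
#' uniform \code{-U} stream is added, making the sphere an invariant
#' surface of the (steady) flow.
#'
#' @param dims integer(3) grid size (default 32^3).
#' @param spacing numeric(3) voxel spacing, mm (default 3).
#' @param center sphere centre, mm; default the grid centre.
#' @param radius sphere radius \code{a}, mm (default 18); the sphere must
#'   lie inside the grid.
#' @param U translation speed, cm/s (default 30).
#' @param nPhases number of (identical) phases to emit (default 2).
#' @param rr cycle length, ms.
#' @param frame \code{"lab"} or \code{"comoving"}.
#' @return \code{list(field, sphere, center, radius, U)}: the
#'   [VelocityField4D-class], a logical 3D array marking voxels with centre
#'   inside the sphere, and the generating parameters.
#' @seealso [hillVortexKE()] for the closed-form interior kinetic energy.
#' @export
makeHillVortex <- function(dims = c(32L, 32L, 32L), spacing = c(3, 3, 3),
                           center = NULL, radius = 18, U = 30,
                           nPhases = 2L, rr = 1000,
                           frame = c("lab", "comoving")) {
  frame <- match.arg(frame)
  affine <- defaultAffine(spacing)
  if (is.null(center)) center <- (dims - 1) * spacing / 2
  ext <- (dims - 1) * spacing
  if (any(center - radius < 0) || any(center + radius > ext))
    stop("vortex sphere intersects the grid boundary")
  cc <- latticeCoords(affine, dims)
  v <- hillVelocity(cc$x - center[1L], cc$y - center[2L],
                    cc$z - center[3L], radius, U)
  if (frame == "comoving") v$vz <- v$vz - U
  values <- array(0, c(dims, nPhases, 3L))
  for (t in seq_len(nPhases)) {
    values[, , , t, 1L] <- v$vx
    values[, , , t, 2L] <- v$vy
    values[, , , t, 3L] <- v$vz
  }
  r2 <- (cc$x - center[1L])^2 + (cc$y - center[2L])^2 +
    (cc$z - center[3L])^2
  field <- VelocityField4D(values, spacing = spacing, rr = rr,
                           venc = max(100, 3 * abs(U)), affine = affine)
  list(field = field, sphere = r2 <= radius^2, center = center,
       radius = radius, U = U)
}

# Lab-frame Hill vortex velocities (cm/s) at coordinates relative to the
# sphere centre (mm); translation along +z.
hillVelocity <- function(x, y, z, a, U) {
  s2 <- x^2 + y^2
  r2 <- s2 + z^2
  inside <- r2 <= a^2
  vx <- vy <- vz <- array(0, dim(x))
  k <- 1.5 * U / a^2
  vx[inside] <- k * x[inside] * z[inside]
  vy[inside] <- k * y[inside] * z[inside]
  vz[inside] <- k * (a^2 - z[inside]^2 - 2 * s2[inside]) + U
  out <- !inside
  r5 <- r2[out]^2.5
  q <- 1.5 * U * a^3 * z[out] / r5
  vx[out] <- q * x[out]
  vy[out] <- q * y[out]
  vz[out] <- 0.5 * U * a^3 * (2 / r2[out]^1.5 - 3 * s2[out] / r5)
  list(vx = vx, vy = vy, vz = vz)
}

#' Closed-form kinetic energy inside Hill's spherical vortex
#'
#' Lab-frame kinetic energy of the fluid inside the sphere:
#' \deqn{E = \frac{23}{21} \pi \rho U^2 a^3.}
#' (The exterior potential flow carries a further
#' \eqn{\frac{1}{3}\pi\rho U^2 a^3}, the added-mass energy, making up the
#' classical total \eqn{\frac{10}{7}\pi\rho U^2 a^3}.)
#'
#' @param radius sphere radius, mm.
#' @param U translation speed, cm/s.
#' @param density kg/m^3.
#' @return energy in joules.
#' @export
hillVortexKE <- function(radius, U, density = 1050) {
  23 / 21 * pi * density * (U * 0.01)^2 * (radius * 1e-3)^3
}

#' Time-periodic double-gyre benchmark flow
#'
#' The standard two-cell stream-function flow with a periodically
#' oscillating divider, extruded to a thin 3D slab (zero z velocity). The
#' wall-normal velocity component vanishes on the domain boundary (the
#' tangential slip of the stream-function flow is nonzero). Parameters are
#' recorded as attributes of the returned field.
#'
#' @param nx,ny,nz grid size (default 65 x 33 x 3).
#' @param Ly domain height, mm (width is \code{2 Ly}); default 100.
#' @param A velocity amplitude scale, cm/s (peak speed ~ pi A); default 10.
#' @param eps divider oscillation amplitude (0 = steady); default 0.25.
#' @param nPhases phases per cycle (default 21).
#' @param rr oscillation period = cycle length, ms.
#' @return A [VelocityField4D-class].
#' @export
makeDoubleGyre <- function(nx = 65L, ny = 33L, nz = 3L, Ly = 100, A = 10,
                           eps = 0.25, nPhases = 21L, rr = 1000) {
  dx <- 2 * Ly / (nx - 1L)
  dy <- Ly / (ny - 1L)
  spacing <- c(dx, dy, dy)
  dims <- c(nx, ny, nz)
  affine <- defaultAffine(spacing)
  cc <- latticeCoords(affine, dims)
  xi <- cc$x / Ly                      # 0..2
  eta <- cc$y / Ly                     # 0..1
  ts <- seq(0, rr, length.out = nPhases + 1L)[seq_len(nPhases)]
  values <- array(0, c(dims, nPhases, 3L))
  om <- 2 * pi / rr
  for (p in seq_len(nPhases)) {
    st <- eps * sin(om * ts[p])
    f <- st * xi^2 + (1 - 2 * st) * xi
    dfdxi <- 2 * st * xi + (1 - 2 * st)
    values[, , , p, 1L] <- -pi * A * sin(pi * f) * cos(pi * eta)
    values[, , , p, 2L] <- pi * A * cos(pi * f) * sin(pi * eta) * dfdxi
  }
  field <- VelocityField4D(values, spacing = spacing, timestamps = ts,
                           rr = rr, venc = max(100, 5 * A), affine = affine)
  attr(field, "doubleGyre") <- list(A = A, eps = eps, Ly = Ly, rr = rr)
  field
}

#' Synthetic KE time curve with known pattern
#'
#' Sum of smooth bumps over the cycle: a systolic peak plus diastolic E-
#' and A-wave peaks shaped by the requested pattern (p3 fuses the two into
#' one broad hump). Optional additive Gaussian noise (truncated at zero).
#'
#' @param pattern \code{"control_like"}, \code{"p1"}, \code{"p2"} or
#'   \code{"p3"}.
#' @param nPhases phases per cycle (default 40).
#' @param rr cycle length, ms (default 1000).
#' @param noise noise SD as a fraction of the curve maximum (default 0).
#' @param seed RNG seed used when \code{noise > 0}.
#' @param amplitudes optional named list overriding mJ amplitudes
#'   (\code{sys}, \code{e}, \code{a}, \code{fusedAmp}, \code{baseline}).
#' @return \code{list(curve, phases, label, keE, keA)}: the
#'   [KECurve-class], a matching [CardiacPhases-class] (systole = first 40%
#'   of the cycle), and the generating truth.
#' @export
makeKECurve <- function(pattern = c("control_like", "p1", "p2", "p3"),
                        nPhases = 40L, rr = 1000, noise = 0, seed = 1L,
                        amplitudes = list()) {
  pattern <- match.arg(pattern)
  amp <- utils::modifyList(list(sys = 3.3, baseline = 0.15,
                                e = switch(pattern, control_like = 6.3,
                                           p1 = 1.5, p2 = 3.0, p3 = NA),
                                a = switch(pattern, control_like = 2.0,
                                           p1 = 3.0, p2 = 1.2, p3 = NA),
                                fusedAmp = 2.5), amplitudes)
  ts <- seq(0, rr, length.out = nPhases + 1L)[seq_len(nPhases)]
  tot <- amp$baseline + amp$sys * gaussBump(ts, 0.18 * rr, 0.055 * rr)
  if (pattern == "p3") {
    tot <- tot + amp$fusedAmp * gaussBump(ts, 0.66 * rr, 0.13 * rr)
    keE <- keA <- NA_real_
  } else {
    tot <- tot + amp$e * gaussBump(ts, 0.54 * rr, 0.045 * rr) +
      amp$a * gaussBump(ts, 0.88 * rr, 0.04 * rr)
    keE <- amp$e; keA <- amp$a
  }
  if (noise > 0) {
    set.seed(seed)
    tot <- pmax(0, tot + stats::rnorm(nPhases, sd = noise * max(tot)))
  }
  nSys <- max(2L, round(0.4 * nPhases))
  sys <- seq_len(nSys)
  dia <- (nSys + 1L):nPhases
  phases <- new("CardiacPhases", systole = as.integer(sys),
                diastole = as.integer(dia), eWave = integer(),
                diastasis = integer(), aWave = integer(),
                edIndex = 1L, esIndex = as.integer(nSys + 1L),
                nPhases = as.integer(nPhases))
  list(curve = KECurve(ts, tot), phases = phases,
       label = if (pattern == "control_like") "control_like" else pattern,
       keE = keE, keA = keA)
}

#' Synthetic beating-LV 4D-flow dataset with ground truth
#'
#' Emulates one cardiac cycle on a voxel grid: an ellipsoidal LV whose
#' volume follows a prescribed curve from EDV through ESV with E- and
#' A-wave filling shaped by the requested pattern; a diastolic inflow
#' carrying a translating Hill-type vortex ring toward the apex during the
#' E-wave (basal side = +z); a basal inflow jet during the A-wave; a
#' systolic outflow; a stationary tissue shell around the LV; an injected
#' linear background velocity field added to every voxel (the shell shows
#' only this background); and optional additive Gaussian noise and
#' velocity-wrap injection beyond VENC.
#'
#' The LV mask at each phase is the set of voxels with smallest ellipsoidal
#' coordinate, cut to exactly \code{round(V / voxel volume)} voxels, so the
#' emitted mask volume equals the prescribed curve to within half a voxel.
#'
#' @param dims,spacing grid (default 48^3 at 3 mm, the acquisition-like
#'   resolution).
#' @param nPhases phases per cycle (default 40).
#' @param rr cycle length, ms (default 1000).
#' @param edv,esv end-diastolic and end-systolic volume, ml (default
#'   150/60, a textbook-normal LV).
#' @param pattern KE curve pattern to emulate (default
#'   \code{"control_like"}).
#' @param eaRatio E/A filling-volume ratio (default 2).
#' @param vortexRadius Hill vortex radius, mm (default 12).
#' @param vortexSpeed peak vortex translation speed, cm/s (default 55 for
#'   E-dominant patterns; see details in the source).
#' @param background 3 x 4 matrix of injected background coefficients per
#'   component: offset (cm/s) and x/y/z slopes (cm/s/mm); constant over
#'   phases. Default small nonzero values.
#' @param noiseSD additive Gaussian velocity noise SD, cm/s (default 0).
#' @param wrapInject apply the VENC wrap model to the final field
#'   (default FALSE).
#' @param venc velocity-encoding limit, cm/s (default 100).
#' @param seed RNG seed for the noise.
#' @return \code{list(field, lv, stationary, truth)} where \code{truth}
#'   records the prescribed volume curve, the true vortex sphere mask
#'   series and per-phase centres, the injected background coefficients,
#'   the generating pattern, and the pre-wrap field (\code{unwrapped}).
#' @export
makeLVCycle <- function(dims = c(48L, 48L, 48L), spacing = c(3, 3, 3),
                        nPhases = 40L, rr = 1000, edv = 150, esv = 60,
                        pattern = c("control_like", "p1", "p2", "p3"),
                        eaRatio = 2, vortexRadius = 12, vortexSpeed = NULL,
                        background = rbind(c(1.0, 0.020, -0.010, 0.015),
                                           c(-0.6, -0.012, 0.018, 0.008),
                                           c(0.4, 0.010, 0.014, -0.016)),
                        noiseSD = 0, wrapInject = FALSE, venc = 100,
                        seed = 1L) {
  pattern <- match.arg(pattern)
  if (edv <= esv || esv <= 0) stop("requires edv > esv > 0")
  if (nPhases < 8L) stop("at least 8 phases are required")
  affine <- defaultAffine(spacing)
  voxvol <- prod(spacing) / 1000       # ml
  ts <- seq(0, rr, length.out = nPhases + 1L)[seq_len(nPhases)]
  fE <- eaRatio / (1 + eaRatio)
  # normalized volume shape: systolic emptying, then E- and A-wave refilling
  g <- 1 - logistic(ts, 0.18 * rr, 0.045 * rr)
  if (pattern == "p3") {
    g <- g + logistic(ts, 0.66 * rr, 0.055 * rr)
  } else {
    g <- g + fE * logistic(ts, 0.54 * rr, 0.030 * rr) +
      (1 - fE) * logistic(ts, 0.87 * rr, 0.020 * rr)
  }
  g <- (g - min(g)) / (max(g) - min(g))
  V <- esv + (edv - esv) * g           # ml, exact ground-truth curve
  if (any(V <= 0)) stop("infeasible volume curve (non-positive volumes)")

  # ellipsoid semi-axes: fixed aspect, scaled for exact volume
  aspect <- c(0.75, 0.75, 1.3)
  c0 <- (dims - 1) * spacing / 2
  cc <- latticeCoords(affine, dims)
  Rt <- (3 * V * 1000 / (4 * pi * prod(aspect)))^(1 / 3)  # mm
  rEDV <- max(Rt) * aspect

  # stationary shell: between 1.12x and 1.32x the EDV ellipsoid
  qEDV <- ((cc$x - c0[1L]) / rEDV[1L])^2 +
    ((cc$y - c0[2L]) / rEDV[2L])^2 + ((cc$z - c0[3L]) / rEDV[3L])^2
  shell <- qEDV >= 1.12^2 & qEDV <= 1.32^2

  # amplitude schedule (cm/s): systolic outflow, E vortex, A jet
  if (is.null(vortexSpeed))
    vortexSpeed <- switch(pattern, p1 = 20, 55)
  vS <- 35
  vA <- switch(pattern, control_like = 45, p1 = 55, p2 = 45, p3 = 0)
  wS <- gaussBump(ts, 0.16 * rr, 0.05 * rr)
  if (pattern == "p3") {
    wE <- gaussBump(ts, 0.68 * rr, 0.11 * rr)
    wA <- rep(0, nPhases)
  } else {
    wE <- gaussBump(ts, 0.54 * rr, 0.045 * rr)
    wA <- gaussBump(ts, 0.88 * rr, 0.035 * rr)
  }

  # vortex translation path: from the basal half toward the centre
  active <- wE >= 0.2 * max(wE)
  prog <- cumsum(wE) / sum(wE)
  values <- array(0, c(dims, nPhases, 3L))
  lvMasks <- array(FALSE, c(dims, nPhases))
  vortexMasks <- array(FALSE, c(dims, nPhases))
  vortexCenter <- matrix(NA_real_, nPhases, 3L)
  ord <- NULL
  for (t in seq_len(nPhases)) {
    ax <- Rt[t] * aspect
    q <- ((cc$x - c0[1L]) / ax[1L])^2 + ((cc$y - c0[2L]) / ax[2L])^2 +
      ((cc$z - c0[3L]) / ax[3L])^2
    k <- round(V[t] / voxvol)
    sel <- order(q)[seq_len(k)]
    lvm <- array(FALSE, dims)
    lvm[sel] <- TRUE
    lvMasks[, , , t] <- lvm
    vx <- vy <- vz <- array(0, dims)
    if (wS[t] > 1e-3) {                 # systolic outflow toward the base
      w <- vS * wS[t] * pmax(0, 1 - q)
      vz <- vz + w
    }
    if (wE[t] > 1e-3) {                 # E-wave Hill vortex ring
      ctr <- c(c0[1L], c0[2L],
               c0[3L] + ax[3L] * (0.55 - 0.6 * min(1, prog[t])))
      hv <- hillVelocity(cc$x - ctr[1L], cc$y - ctr[2L], cc$z - ctr[3L],
                         vortexRadius, -vortexSpeed * wE[t])
      vx <- vx + hv$vx; vy <- vy + hv$vy; vz <- vz + hv$vz
      if (active[t]) {
        vortexCenter[t, ] <- ctr
        vortexMasks[, , , t] <- lvm &
          ((cc$x - ctr[1L])^2 + (cc$y - ctr[2L])^2 +
             (cc$z - ctr[3L])^2 <= vortexRadius^2)
      }
    }
    if (wA[t] > 1e-3) {                 # A-wave basal inflow jet
      s2 <- (cc$x - c0[1L])^2 + (cc$y - c0[2L])^2
      rj <- 0.5 * ax[1L]
      jet <- pmax(0, 1 - s2 / rj^2) * (cc$z > c0[3L])
      vz <- vz - vA * wA[t] * jet
    }
    # flow exists only inside the LV blood pool
    vx[!lvm] <- 0; vy[!lvm] <- 0; vz[!lvm] <- 0
    values[, , , t, 1L] <- vx
    values[, , , t, 2L] <- vy
    values[, , , t, 3L] <- vz
  }

  truthClean <- values
  # injected linear background, added to every voxel of every phase
  bg <- vector("list", 3L)
  for (c in 1:3)
    bg[[c]] <- background[c, 1L] + background[c, 2L] * cc$x +
      background[c, 3L] * cc$y + background[c, 4L] * cc$z
  for (t in seq_len(nPhases)) for (c in 1:3)
    values[, , , t, c] <- values[, , , t, c] + bg[[c]]
  if (noiseSD > 0) {
    set.seed(seed)
    values <- values + array(stats::rnorm(length(values), sd = noiseSD),
                             dim(values))
  }
  preWrap <- values
  if (wrapInject) values <- wrapModel(values, venc)

  field <- VelocityField4D(values, spacing = spacing, timestamps = ts,
                           rr = rr, venc = venc, affine = affine)
  unwrappedField <- VelocityField4D(preWrap, spacing = spacing,
                                    timestamps = ts, rr = rr, venc = venc,
                                    affine = affine)
  lv <- MaskSeries(lvMasks, role = "lv", affine = affine)
  stat <- MaskSeries(array(shell, c(dims, nPhases)), role = "stationary",
                     affine = affine)
  vortex <- MaskSeries(vortexMasks, role = "vortex", affine = affine)
  list(field = field, lv = lv, stationary = stat,
       truth = list(volume = V, time = ts, pattern = pattern,
                    background = background, vortex = vortex,
                    vortexCenter = vortexCenter,
                    vortexRadius = vortexRadius,
                    cleanValues = truthClean, unwrapped = unwrappedField))
}
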