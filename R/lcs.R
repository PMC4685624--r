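# Particle tracing and finite-time Lyapunov exponents (FTLE) on the
# time-resolved velocity field. Ridges of the backward-time FTLE mark
# attracting Lagrangian coherent structures, which bound the diastolic
# inflow vortex ring.

# Trilinear interpolation of one phase volume at continuous 0-based voxel
# coordinates p (n x 3). Returns n x 3 velocities (cm/s); rows of `bad`
# are zero.
interpPhase <- function(values, ti, p, bad) {
  d <- dim(values)
  n <- nrow(p)
  out <- matrix(0, n, 3L)
  ok <- !bad
  if (!any(ok)) return(out)
  pq <- p[ok, , drop = FALSE]
  f <- floor(pq)
  f[, 1L] <- pmin(pmax(f[, 1L], 0), d[1L] - 2L)
  f[, 2L] <- pmin(pmax(f[, 2L], 0), d[2L] - 2L)
  f[, 3L] <- pmin(pmax(f[, 3L], 0), d[3L] - 2L)
  w <- pq - f
  nx <- d[1L]; nxy <- d[1L] * d[2L]; nxyz <- nxy * d[3L]
  base <- 1 + f[, 1L] + nx * f[, 2L] + nxy * f[, 3L] +
    nxyz * (ti - 1L)
  for (c in 1:3) {
    off <- nxyz * d[4L] * (c - 1L)
    v000 <- values[base + off]
    v100 <- values[base + 1 + off]
    v010 <- values[base + nx + off]
    v110 <- values[base + nx + 1 + off]
    v001 <- values[base + nxy + off]
    v101 <- values[base + nxy + 1 + off]
    v011 <- values[base + nxy + nx + off]
    v111 <- values[base + nxy + nx + 1 + off]
    wx <- w[, 1L]; wy <- w[, 2L]; wz <- w[, 3L]
    c00 <- v000 * (1 - wx) + v100 * wx
    c10 <- v010 * (1 - wx) + v110 * wx
    c01 <- v001 * (1 - wx) + v101 * wx
    c11 <- v011 * (1 - wx) + v111 * wx
    out[ok, c] <- (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
      (c01 * (1 - wy) + c11 * wy) * wz
  }
  out
}

#' Sample the velocity field at arbitrary positions and time
#'
#' Trilinear interpolation in space and linear interpolation in time
#' between the bracketing cardiac phases, with periodic wrap (time is taken
#' modulo the RR interval). Positions outside the spatial grid are reported
#' through \code{inDomain}, not as an error.
#'
#' @param field a [VelocityField4D-class].
#' @param x numeric matrix \code{(n, 3)} of positions, mm (a single
#'   position may be given as a length-3 vector).
#' @param t time, ms (scalar).
#' @return \code{list(v, inDomain)}: velocities in m/s \code{(n, 3)} (zero
#'   rows where out of domain) and a logical flag per query.
#' @export
sampleVelocity <- function(field, x, t) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  d <- dim(field@values)
  p <- worldToVoxel(field@affine, x)
  bad <- p[, 1L] < 0 | p[, 1L] > d[1L] - 1L |
    p[, 2L] < 0 | p[, 2L] > d[2L] - 1L |
    p[, 3L] < 0 | p[, 3L] > d[3L] - 1L
  ts <- field@timestamps
  nt <- d[4L]
  tm <- t %% field@rr
  i <- findInterval(tm, ts)
  if (i == 0L) {
    t1 <- ts[nt] - field@rr; t2 <- ts[1L]; i1 <- nt; i2 <- 1L
  } else if (i == nt) {
    t1 <- ts[nt]; t2 <- ts[1L] + field@rr; i1 <- nt; i2 <- 1L
  } else {
    t1 <- ts[i]; t2 <- ts[i + 1L]; i1 <- i; i2 <- i + 1L
  }
  w <- (tm - t1) / (t2 - t1)
  v <- interpPhase(field@values, i1, p, bad)
  if (w > 0) v <- (1 - w) * v + w * interpPhase(field@values, i2, p, bad)
  list(v = v * 0.01, inDomain = !bad)   # cm/s -> m/s
}

#' Trace particles through the time-resolved velocity field
#'
#' Classic fourth-order Runge-Kutta integration of \code{dx/dt = v(x, t)}
#' from \code{t0} over the signed span \code{T} (negative span = backward
#' time). Particles leaving the spatial domain are frozen at their last
#' in-domain position and flagged. Positions are mm, time ms; velocities in
#' m/s equal mm/ms numerically, so no unit factor appears in the update.
#'
#' @param field a [VelocityField4D-class].
#' @param seeds numeric \code{(n, 3)} initial positions, mm.
#' @param t0 start time, ms.
#' @param T signed integration span, ms.
#' @param dt requested step, ms (sign is taken from \code{T}); the actual
#'   step divides \code{T} exactly. Must not exceed the inter-phase spacing.
#' @return A [TrajectorySet-class].
#' @export
traceParticles <- function(field, seeds, t0, T, dt) {
  if (dt == 0) stop("dt must be nonzero")
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3L)
  nsteps <- max(1L, as.integer(round(abs(T / dt))))
  h <- T / nsteps
  n <- nrow(seeds)
  times <- t0 + h * (0:nsteps)
  pos <- array(NA_real_, c(n, nsteps + 1L, 3L))
  pos[, 1L, ] <- seeds
  x <- seeds
  frozen <- rep(FALSE, n)
  for (s in seq_len(nsteps)) {
    t <- times[s]
    k1 <- sampleVelocity(field, x, t)
    k2 <- sampleVelocity(field, x + (h / 2) * k1$v, t + h / 2)
    k3 <- sampleVelocity(field, x + (h / 2) * k2$v, t + h / 2)
    k4 <- sampleVelocity(field, x + h * k3$v, t + h)
    ok <- k1$inDomain & k2$inDomain & k3$inDomain & k4$inDomain & !frozen
    frozen <- frozen | !ok
    x[ok, ] <- x[ok, , drop = FALSE] +
      (h / 6) * (k1$v[ok, , drop = FALSE] + 2 * k2$v[ok, , drop = FALSE] +
                   2 * k3$v[ok, , drop = FALSE] + k4$v[ok, , drop = FALSE])
    pos[, s + 1L, ] <- x
  }
  new("TrajectorySet", seeds = seeds, times = times, positions = pos,
      leftDomain = frozen)
}

#' Finite-time Lyapunov exponent field
#'
#' Integrates the flow map on a regular seed grid with [traceParticles()],
#' forms its spatial gradient by central differences over neighbouring
#' seeds, and returns \eqn{\sigma = \ln\sqrt{\lambda_{max}(C)} / |T|} with
#' the right Cauchy-Green tensor \eqn{C = (\nabla\Phi)^T \nabla\Phi} and
#' \code{T} in seconds. The seed-grid boundary layer, and seeds whose own
#' or neighbouring trajectories left the domain, are NA.
#'
#' @param field a [VelocityField4D-class].
#' @param seedGrid list with numeric vectors \code{x}, \code{y}, \code{z}:
#'   seed coordinates (mm) of a regular lattice.
#' @param t0 seeding time, ms.
#' @param T signed integration span, ms (negative = backward).
#' @param dt integration step, ms; default half the smallest inter-phase
#'   spacing.
#' @return An [FTLEField-class].
#' @export
computeFTLE <- function(field, seedGrid, t0, T, dt = NULL) {
  if (T == 0) stop("integration span T must be nonzero")
  if (is.null(dt)) {
    ts <- field@timestamps
    gaps <- diff(c(ts, ts[1L] + field@rr))
    dt <- min(gaps) / 2
  }
  gx <- seedGrid$x; gy <- seedGrid$y; gz <- seedGrid$z
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  seeds <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dimnames(seeds) <- NULL
  traj <- traceParticles(field, seeds, t0, T, dt)
  endpt <- traj@positions[, dim(traj@positions)[2L], ]
  lost <- traj@leftDomain
  Fx <- array(endpt[, 1L], c(nx, ny, nz))
  Fy <- array(endpt[, 2L], c(nx, ny, nz))
  Fz <- array(endpt[, 3L], c(nx, ny, nz))
  lostA <- array(lost, c(nx, ny, nz))
  sigma <- array(NA_real_, c(nx, ny, nz))
  if (nx < 3L || ny < 3L || nz < 3L)
    stop("seed grid must be at least 3 seeds wide in every direction")
  ix <- 2:(nx - 1L); iy <- 2:(ny - 1L); iz <- 2:(nz - 1L)
  hx <- gx[3:nx] - gx[1:(nx - 2L)]
  hy <- gy[3:ny] - gy[1:(ny - 2L)]
  hz <- gz[3:nz] - gz[1:(nz - 2L)]
  dX <- function(A) sweep(A[3:nx, iy, iz, drop = FALSE] -
                            A[1:(nx - 2L), iy, iz, drop = FALSE], 1L, hx, "/")
  dY <- function(A) sweep(A[ix, 3:ny, iz, drop = FALSE] -
                            A[ix, 1:(ny - 2L), iz, drop = FALSE], 2L, hy, "/")
  dZ <- function(A) sweep(A[ix, iy, 3:nz, drop = FALSE] -
                            A[ix, iy, 1:(nz - 2L), drop = FALSE], 3L, hz, "/")
  J11 <- dX(Fx); J12 <- dY(Fx); J13 <- dZ(Fx)
  J21 <- dX(Fy); J22 <- dY(Fy); J23 <- dZ(Fy)
  J31 <- dX(Fz); J32 <- dY(Fz); J33 <- dZ(Fz)
  c11 <- J11^2 + J21^2 + J31^2
  c12 <- J11 * J12 + J21 * J22 + J31 * J32
  c13 <- J11 * J13 + J21 * J23 + J31 * J33
  c22 <- J12^2 + J22^2 + J32^2
  c23 <- J12 * J13 + J22 * J23 + J32 * J33
  c33 <- J13^2 + J23^2 + J33^2
  lmax <- eigMaxSym3(as.vector(c11), as.vector(c12), as.vector(c13),
                     as.vector(c22), as.vector(c23), as.vector(c33))
  Ts <- abs(T) / 1000
  sig <- log(sqrt(pmax(lmax, .Machine$double.eps))) / Ts
  sigma[ix, iy, iz] <- array(sig, c(nx - 2L, ny - 2L, nz - 2L))
  # invalidate seeds whose central-difference stencil touched a lost particle
  touched <- lostA
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    touched <- touched | shiftMask(lostA, o[1L], o[2L], o[3L])
  sigma[touched] <- NA_real_
  new("FTLEField", sigma = sigma, coords = list(x = gx, y = gy, z = gz),
      t0 = t0, T = T,
      direction = if (T < 0) "backward" else "forward")
}
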