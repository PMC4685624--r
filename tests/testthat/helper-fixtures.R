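# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Uniform-velocity field (cm/s) on an isotropic grid.
uniformField <- function(u = c(10, 5, 0), n = 9L, spacing = 10, nt = 2L,
                         rr = 1000) {
  vals <- array(rep(u, each = n^3 * nt), c(n, n, n, nt, 3))
  VelocityField4D(vals, spacing = rep(spacing, 3), rr = rr, venc = 1000)
}

# Steady affine velocity field v = v0 + A %*% (x - x0), with A in 1/ms and
# coordinates in mm (velocities converted to cm/s for storage). Trilinear
# interpolation reproduces it exactly, so particle-tracing error is pure
# time-integration error.
affineField <- function(A, v0 = c(0, 0, 0), x0 = c(0, 0, 0), n = 17L,
                        spacing = 4, nt = 2L, rr = 1000,
                        originAtCenter = TRUE) {
  aff <- diag(c(rep(spacing, 3), 1))
  if (originAtCenter) aff[1:3, 4] <- -spacing * (n - 1) / 2
  x <- aff[1, 1] * (0:(n - 1)) + aff[1, 4]
  X <- array(x, rep(n, 3))
  Y <- array(rep(x, each = n), rep(n, 3))
  Z <- array(rep(x, each = n^2), rep(n, 3))
  vals <- array(0, c(n, n, n, nt, 3))
  for (t in seq_len(nt)) for (c in 1:3) {
    vals[, , , t, c] <- 100 * (v0[c] + A[c, 1] * (X - x0[1]) +
                                 A[c, 2] * (Y - x0[2]) +
                                 A[c, 3] * (Z - x0[3]))
  }
  VelocityField4D(vals, spacing = rep(spacing, 3), rr = rr, venc = 1e6,
                  affine = aff)
}

# Linear saddle v = lambda * (x, -y, 0), lambda in 1/s.
saddleField <- function(lambda = 1, ...) {
  affineField(diag(c(lambda, -lambda, 0)) * 1e-3, ...)
}

# Rigid rotation about the z axis, period `period` ms.
rotationField <- function(period = 1000, ...) {
  om <- 2 * pi / period
  affineField(rbind(c(0, -om, 0), c(om, 0, 0), c(0, 0, 0)), ...)
}

# Small synthetic LV cycle shared by several files.
smallLVCycle <- function() {
  fixture("smallLVCycle", function()
    makeLVCycle(dims = c(32L, 32L, 32L), spacing = c(4, 4, 4),
                nPhases = 30L))
}

# Translating Hill vortex (lab frame) inside a physiologically proportioned
# spherical "LV": the vortex sphere is ~12.5% of the LV volume.
translatingHillFixture <- function() {
  fixture("translatingHill", function() {
    sp <- 3; n <- 32L; a <- 15; U <- 30
    nt <- 9L
    ts <- seq(0, 120, length.out = nt)
    x <- sp * (0:(n - 1))
    # the ring translates toward the basal third (+z), so that at the
    # seeding phase it sits where the anatomical prior of the extractor
    # looks for it (mitral inflow side)
    ctr0 <- c(46.5, 46.5, 28)
    vals <- array(0, c(n, n, n, nt, 3))
    ctrs <- matrix(NA_real_, nt, 3)
    for (t in seq_len(nt)) {
      ctr <- ctr0 + c(0, 0, 0.01 * U * ts[t])    # cm/s -> mm/ms
      ctrs[t, ] <- ctr
      hv <- makeHillVortex(dims = rep(n, 3), spacing = rep(sp, 3),
                           center = ctr, radius = a, U = U, nPhases = 2)
      vals[, , , t, ] <- hv$field@values[, , , 1, ]
    }
    field <- VelocityField4D(vals, spacing = rep(sp, 3), timestamps = ts,
                             rr = 1000, venc = 200)
    X <- array(x, rep(n, 3))
    Y <- array(rep(x, each = n), rep(n, 3))
    Z <- array(rep(x, each = n^2), rep(n, 3))
    lvm <- (X - 46.5)^2 + (Y - 46.5)^2 + (Z - 46.5)^2 <= 30^2
    lv <- MaskSeries(array(lvm, c(n, n, n, nt)), role = "lv",
                     affine = field@affine)
    list(field = field, lv = lv, centers = ctrs, radius = a, U = U,
         coords = list(X = X, Y = Y, Z = Z), grid = x, seedPhase = 8L)
  })
}

# Printed pattern-vs-grade contingency counts (n = 25).
patternGradeCounts <- function() {
  rbind(p1 = c(7, 3, 0), p2 = c(0, 2, 2), p3 = c(1, 4, 6))
}
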