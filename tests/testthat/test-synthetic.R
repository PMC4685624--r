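test_that("Hill vortex field has the analytic structure", {
  hv <- makeHillVortex(dims = rep(25L, 3), spacing = rep(4, 3),
                       radius = 20, U = 30)
  v <- hv$field@values
  # on the symmetry axis the velocity is purely axial
  ctrIdx <- round(hv$center / 4) + 1
  axial <- v[ctrIdx[1], ctrIdx[2], , 1, ]
  expect_lt(max(abs(axial[, 1:2])), 1e-9)
  # the centre moves fastest: 5U/2 in the lab frame
  expect_equal(v[ctrIdx[1], ctrIdx[2], ctrIdx[3], 1, 3], 2.5 * 30,
               tolerance = 1e-6)
  # comoving frame subtracts the translation speed
  hc <- makeHillVortex(dims = rep(25L, 3), spacing = rep(4, 3),
                       radius = 20, U = 30, frame = "comoving")
  expect_equal(hc$field@values[, , , , 3], v[, , , , 3] - 30)
  expect_error(makeHillVortex(dims = rep(16L, 3), spacing = rep(3, 3),
                              radius = 40), "boundary")
})

test_that("discrete divergence of the Hill field vanishes under refinement", {
  rms <- vapply(c(4, 2), function(h) {
    n <- as.integer(96 / h)
    hv <- makeHillVortex(dims = rep(n, 3), spacing = rep(h, 3),
                         center = rep(46, 3) + c(0.4, 0.7, 0.2),
                         radius = 18, U = 30)
    v <- hv$field@values
    d <- dim(v)[1:3]
    i <- 2:(d[1] - 1)
    # central-difference divergence, cm/s per mm, away from the sphere
    # surface (the field is continuous but not differentiable there)
    div <- (v[i + 1, i, i, 1, 1] - v[i - 1, i, i, 1, 1]) / (2 * h) +
      (v[i, i + 1, i, 1, 2] - v[i, i - 1, i, 1, 2]) / (2 * h) +
      (v[i, i, i + 1, 1, 3] - v[i, i, i - 1, 1, 3]) / (2 * h)
    ctr <- rep(46, 3) + c(0.4, 0.7, 0.2)
    x <- h * (i - 1)
    X <- array(x, rep(length(i), 3))
    Y <- array(rep(x, each = length(i)), rep(length(i), 3))
    Z <- array(rep(x, each = length(i)^2), rep(length(i), 3))
    r <- sqrt((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2)
    interior <- abs(r - 18) > 2 * h
    sqrt(mean(div[interior]^2))
  }, numeric(1))
  expect_lt(rms[2], rms[1] / 2)   # second-order differences on a smooth field
})

test_that("double gyre respects its boundary and symmetry properties", {
  # steady (eps = 0) flow is symmetric about the mid-plane x = Lx/2
  dg0 <- makeDoubleGyre(nx = 41, ny = 21, nz = 3, eps = 0, nPhases = 3)
  v <- dg0@values
  expect_equal(v[1:20, , , 1, 1], -v[41:22, , , 1, 1], tolerance = 1e-10)
  expect_equal(v[1:20, , , 1, 2], v[41:22, , , 1, 2], tolerance = 1e-10)
  # wall-normal velocity vanishes on every boundary
  dg <- makeDoubleGyre(nx = 41, ny = 21, nz = 3, eps = 0.25, nPhases = 5)
  vv <- dg@values
  expect_lt(max(abs(vv[c(1, 41), , , , 1])), 1e-10)   # u on x walls
  expect_lt(max(abs(vv[, c(1, 21), , , 2])), 1e-10)   # v on y walls
  expect_true(all(vv[, , , , 3] == 0))
  # the oscillation period equals the cycle: sampling at t and t + rr agrees
  s0 <- sampleVelocity(dg, c(55, 40, 3), t = 130)
  s1 <- sampleVelocity(dg, c(55, 40, 3), t = 130 + 1000)
  expect_equal(s0$v, s1$v)
  expect_identical(attr(dg, "doubleGyre")$eps, 0.25)
})

test_that("synthetic KE curves have the requested morphology", {
  mk <- makeKECurve("p2")
  dia <- mk$curve@total[mk$phases@diastole]
  pk <- which(diff(sign(diff(dia))) == -2) + 1
  expect_identical(length(pk), 2L)            # two separated maxima
  expect_equal(max(dia), 3.0, tolerance = 0.1)
  expect_equal(mk$keE, 3.0)
  expect_equal(mk$keA, 1.2)

  fused <- makeKECurve("p3")
  diaF <- fused$curve@total[fused$phases@diastole]
  expect_identical(length(which(diff(sign(diff(diaF))) == -2) + 1), 1L)

  # determinism under a fixed seed
  a <- makeKECurve("p1", noise = 0.1, seed = 33)
  b <- makeKECurve("p1", noise = 0.1, seed = 33)
  expect_identical(a$curve@total, b$curve@total)
})

test_that("the LV phantom volume curve is met voxel-exactly", {
  sim <- smallLVCycle()
  vc <- computeVolumeCurve(sim$lv, sim$field@spacing,
                           sim$field@timestamps, sim$field@rr)
  voxvol <- prod(sim$field@spacing) / 1000
  expect_lt(max(abs(vc@volume - sim$truth$volume)), voxvol)
  vols <- computeVolumetrics(vc)
  expect_lt(abs(vols@edv - max(sim$truth$volume)), voxvol)
  expect_lt(abs(vols@esv - min(sim$truth$volume)), voxvol)
  # vortex truth is confined to the LV and to diastole
  vp <- sim$truth$vortex@validPhases
  expect_gt(length(vp), 2)
  expect_false(any(sim$truth$vortex@masks & !sim$lv@masks))
})

test_that("the LV phantom is deterministic and patterns flow through", {
  a <- makeLVCycle(dims = c(20L, 20L, 20L), spacing = c(6, 6, 6),
                   nPhases = 20L, noiseSD = 1, seed = 4)
  b <- makeLVCycle(dims = c(20L, 20L, 20L), spacing = c(6, 6, 6),
                   nPhases = 20L, noiseSD = 1, seed = 4)
  expect_identical(a$field@values, b$field@values)
  expect_error(makeLVCycle(edv = 50, esv = 60), "edv > esv")

  # a generated p1 phantom classifies as p1 through the KE pipeline
  sim <- makeLVCycle(dims = c(32L, 32L, 32L), spacing = c(4, 4, 4),
                     nPhases = 30L, pattern = "p1")
  bm <- fitBackground(sim$field, sim$stationary)
  f <- applyBackgroundCorrection(sim$field, bm)
  kc <- KECurve(f@timestamps, sumRegionKE(computeKEField(f), sim$lv))
  vc <- computeVolumeCurve(sim$lv, f@spacing, f@timestamps, f@rr)
  lab <- classifyPattern(detectDiastolicPeaks(kc, splitPhases(vc)),
                         "patient")@label
  expect_identical(lab, "p1")
})
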