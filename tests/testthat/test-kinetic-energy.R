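singleVoxelField <- function(speed = 100, spacing = 3) {
  vals <- array(0, c(1, 1, 1, 2, 3))
  vals[1, 1, 1, , 1] <- speed
  VelocityField4D(vals, spacing = rep(spacing, 3), venc = 10 * speed)
}

test_that("voxel KE matches the hand-computed 1/2 m v^2 value", {
  # 3 mm voxel at 100 cm/s, rho = 1050: 0.5 * 1050 * 2.7e-8 * 1 J
  kef <- computeKEField(singleVoxelField(), density = 1050)
  expect_equal(kef@ke[1, 1, 1, 1], 1.4175e-5, tolerance = 1e-12)
  # zero velocity -> zero KE everywhere
  z <- computeKEField(uniformField(u = c(0, 0, 0)))
  expect_true(all(z@ke == 0))
  # doubling speed quadruples KE
  k2 <- computeKEField(singleVoxelField(speed = 200), density = 1050)
  expect_equal(k2@ke[1, 1, 1, 1], 4 * kef@ke[1, 1, 1, 1])
  expect_error(computeKEField(singleVoxelField(), density = 0), "density")
})

test_that("region sums are additive and honour undefined phases", {
  kef <- computeKEField(singleVoxelField())
  whole <- MaskSeries(array(TRUE, c(1, 1, 1, 2)), role = "lv",
                      affine = diag(c(3, 3, 3, 1)))
  expect_equal(sumRegionKE(kef, whole), rep(0.014175, 2))   # mJ

  set.seed(3)
  f <- VelocityField4D(array(rnorm(5^3 * 2 * 3, sd = 30),
                             c(5, 5, 5, 2, 3)), spacing = c(3, 3, 3))
  kef2 <- computeKEField(f)
  mA <- array(FALSE, c(5, 5, 5, 2)); mA[1:2, , , ] <- TRUE
  mB <- array(FALSE, c(5, 5, 5, 2)); mB[4:5, , , ] <- TRUE
  aff <- diag(c(3, 3, 3, 1))
  sumA <- sumRegionKE(kef2, MaskSeries(mA, "lv", aff))
  sumB <- sumRegionKE(kef2, MaskSeries(mB, "lv", aff))
  sumAB <- sumRegionKE(kef2, MaskSeries(mA | mB, "lv", aff))
  expect_equal(sumAB, sumA + sumB)
  # phases where the region is undefined are NA, not zero
  mC <- mA; mC[, , , 2] <- FALSE
  sC <- sumRegionKE(kef2, MaskSeries(mC, "lv", aff))
  expect_false(is.na(sC[1]))
  expect_true(is.na(sC[2]))
})

test_that("vortex partition conserves KE exactly and checks containment", {
  sim <- smallLVCycle()
  kef <- computeKEField(sim$field)
  kc <- partitionVortexKE(kef, sim$lv, sim$truth$vortex)
  vp <- sim$truth$vortex@validPhases
  expect_true(all(kc@inside[vp] + kc@outside[vp] == kc@total[vp]))
  expect_true(all(is.na(kc@inside[-vp])))

  # vortex == lv -> outside identically zero
  kcAll <- partitionVortexKE(kef, sim$lv, {
    v <- sim$lv; v@role <- "vortex"; v
  })
  expect_true(all(kcAll@outside[validPhases(sim$lv)] == 0))

  # uniform KE density: inside fraction equals the voxel-count fraction
  u <- uniformField(u = c(50, 0, 0), n = 9L, nt = 2L)
  kefU <- computeKEField(u)
  lvm <- array(FALSE, c(9, 9, 9, 2)); lvm[2:8, 2:8, 2:8, ] <- TRUE
  vxm <- array(FALSE, c(9, 9, 9, 2)); vxm[2:8, 2:8, 2:4, ] <- TRUE
  aff <- diag(c(10, 10, 10, 1))
  kcU <- partitionVortexKE(kefU, MaskSeries(lvm, "lv", aff),
                           MaskSeries(vxm, "vortex", aff))
  expect_equal(kcU@inside[1] / kcU@total[1], 3 / 7)

  # an empty phase listed as defined gives inside 0, outside total
  vxE <- vxm; vxE[, , , 2] <- FALSE
  kcE <- partitionVortexKE(kefU, MaskSeries(lvm, "lv", aff),
                           MaskSeries(vxE, "vortex", aff),
                           vortexPhases = 1:2)
  expect_identical(kcE@inside[2], 0)
  expect_equal(kcE@outside[2], kcE@total[2])

  # containment violation names the first offending phase
  bad <- vxm; bad[1, 1, 1, 2] <- TRUE
  expect_error(partitionVortexKE(kefU, MaskSeries(lvm, "lv", aff),
                                 MaskSeries(bad, "vortex", aff)),
               "outside the LV at phase 2")
})

test_that("discrete Hill-vortex KE approaches the closed form", {
  hv <- makeHillVortex(dims = rep(48L, 3), spacing = rep(2, 3),
                       center = rep(47, 3) + c(0.37, 0.61, 0.29),
                       radius = 18, U = 30)
  kef <- computeKEField(hv$field)
  msk <- MaskSeries(array(hv$sphere, c(dim(hv$sphere), 2)), "lv",
                    hv$field@affine)
  ke <- sumRegionKE(kef, msk)[1] / 1000     # back to joules
  expect_equal(ke, hillVortexKE(18, 30), tolerance = 0.01)
})

test_that("KE summaries follow their definitions and roll consistently", {
  n <- 10L
  time <- seq(0, 900, 100)
  phases <- new("CardiacPhases", systole = 1:4, diastole = 5:10,
                eWave = 5:7, diastasis = 8L, aWave = 9:10,
                edIndex = 1L, esIndex = 5L, nPhases = n)
  vols <- new("VolumetricsSummary", edv = 200, esv = 100, sv = 100,
              ef = 50, per = 300, pfr = 250, edIndex = 1L, esIndex = 5L)

  # constant curve: averages equal the constant, cv = 0
  kc <- KECurve(time, rep(2, n))
  s <- summarizeKE(kc, phases, vols)
  expect_equal(s@sysAvg, 2); expect_equal(s@diaAvg, 2)
  expect_equal(s@cv, 0)
  expect_false(s@vortexDefined)
  expect_true(is.na(s@vortexFraction))
  # dia avg 2 mJ at EDV 200 ml -> 10 uJ/ml
  expect_equal(s@diaAvgPerEDV, 10)
  expect_equal(s@diaAvgPerSV, 20)

  # inside-vortex series (1, 3, 2) from formation to ED -> delta +2
  inside <- rep(NA_real_, n); outside <- rep(NA_real_, n)
  inside[8:10] <- c(1, 3, 2); outside[8:10] <- 0.5
  kc2 <- KECurve(time, {
    tot <- rep(2, n); tot[8:10] <- inside[8:10] + 0.5; tot
  }, inside, outside)
  s2 <- summarizeKE(kc2, phases, vols)
  expect_equal(s2@deltaKEDiastole, 2)
  expect_true(s2@vortexDefined)
  expect_equal(s2@vortexFraction, 100 * 2 / 2.5)

  # all summary fields invariant under a consistent phase roll
  sim <- smallLVCycle()
  kef <- computeKEField(sim$field)
  kcS <- partitionVortexKE(kef, sim$lv, sim$truth$vortex)
  vc <- computeVolumeCurve(sim$lv, sim$field@spacing,
                           sim$field@timestamps, sim$field@rr)
  phS <- splitPhases(vc)
  volsS <- computeVolumetrics(vc)
  ref <- summarizeKE(kcS, phS, volsS)
  nS <- 30L; shift <- 7L
  perm <- ((seq_len(nS) - 1L + shift) %% nS) + 1L   # new index -> old index
  inv <- order(perm)                                 # old index -> new index
  kcR <- KECurve(kcS@time, kcS@total[perm], kcS@inside[perm],
                 kcS@outside[perm])
  roll <- function(ix) as.integer(sort(inv[ix]))
  phR <- new("CardiacPhases", systole = inv[phS@systole],
             diastole = inv[phS@diastole], eWave = inv[phS@eWave],
             diastasis = inv[phS@diastasis], aWave = inv[phS@aWave],
             edIndex = inv[phS@edIndex], esIndex = inv[phS@esIndex],
             nPhases = nS)
  sR <- summarizeKE(kcR, phR, volsS)
  for (sl in c("sysAvg", "diaAvg", "sysPeak", "diaPeak", "cv",
               "vortexFraction", "deltaKEDiastole"))
    expect_equal(slot(sR, sl), slot(ref, sl), tolerance = 1e-12,
                 label = sl)
})
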