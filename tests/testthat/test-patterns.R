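twoPeakCurve <- function(e = 4, a = 2, trough = 0.5, n = 40L) {
  # systole flat low, diastole with two triangular peaks
  tot <- rep(trough, n)
  tot[1:16] <- 0.4
  tot[22] <- e
  tot[c(21, 23)] <- (e + trough) / 2
  tot[34] <- a
  tot[c(33, 35)] <- (a + trough) / 2
  phases <- new("CardiacPhases", systole = 1:16, diastole = 17:40,
                eWave = integer(), diastasis = integer(),
                aWave = integer(), edIndex = 1L, esIndex = 17L,
                nPhases = n)
  list(curve = KECurve(seq(0, 975, 25), tot), phases = phases)
}

test_that("peak detection extracts E/A features and the fusion flag", {
  tp <- twoPeakCurve(e = 4, a = 2, trough = 0.5)
  f <- detectDiastolicPeaks(tp$curve, tp$phases, smooth = FALSE)
  expect_false(f@fused)
  expect_equal(f@keE, 4)
  expect_equal(f@keA, 2)
  expect_false(f@spillover)

  # single broad hump: fewer than two candidates -> fused
  mk <- makeKECurve("p3")
  f3 <- detectDiastolicPeaks(mk$curve, mk$phases)
  expect_true(f3@fused)

  # shallow inter-peak trough (0.9 x the smaller peak) -> fused
  tpF <- twoPeakCurve(e = 4, a = 2, trough = 1.8)
  fF <- detectDiastolicPeaks(tpF$curve, tpF$phases, smooth = FALSE)
  expect_true(fF@fused)

  zero <- twoPeakCurve()
  zero$curve@total[] <- 0
  expect_error(detectDiastolicPeaks(zero$curve, zero$phases), "all-zero")
})

test_that("classification implements the three pattern criteria", {
  base <- twoPeakCurve(e = 2, a = 4)
  f1 <- detectDiastolicPeaks(base$curve, base$phases, smooth = FALSE)
  expect_identical(classifyPattern(f1, "patient")@label, "p1")

  hi <- twoPeakCurve(e = 4, a = 2)
  f2 <- detectDiastolicPeaks(hi$curve, hi$phases, smooth = FALSE)
  expect_identical(classifyPattern(f2, "patient")@label, "p2")
  expect_identical(classifyPattern(f2, "control")@label, "control_like")

  fused <- detectDiastolicPeaks(makeKECurve("p3")$curve,
                                makeKECurve("p3")$phases)
  expect_identical(classifyPattern(fused, "patient")@label, "p3")
  expect_identical(classifyPattern(fused, "control")@label, "p3")

  tie <- twoPeakCurve(e = 3, a = 3)
  ft <- detectDiastolicPeaks(tie$curve, tie$phases, smooth = FALSE)
  res <- classifyPattern(ft, "patient")
  expect_identical(res@label, "p2")
  expect_true(res@tie)
})

test_that("the classifier is invariant to positive rescaling", {
  for (pat in c("control_like", "p1", "p2", "p3")) {
    mk <- makeKECurve(pat, noise = 0.05, seed = 11)
    ref <- classifyPattern(detectDiastolicPeaks(mk$curve, mk$phases),
                           "patient")@label
    for (k in c(0.02, 5, 400)) {
      sc <- KECurve(mk$curve@time, k * mk$curve@total)
      lab <- classifyPattern(detectDiastolicPeaks(sc, mk$phases),
                             "patient")@label
      expect_identical(lab, ref)
    }
  }
})

test_that("pattern labels are recovered under noise", {
  # 50 seeded replicates per pattern at 10% noise (the full 200-replicate
  # sweep runs in the acceptance suite)
  for (pat in c("control_like", "p1", "p2", "p3")) {
    hits <- 0L
    for (s in 1:50) {
      mk <- makeKECurve(pat, noise = 0.10, seed = s)
      lab <- classifyPattern(
        detectDiastolicPeaks(mk$curve, mk$phases),
        if (pat == "control_like") "control" else "patient")@label
      hits <- hits + (lab == mk$label)
    }
    expect_gte(hits / 50, 0.95)
  }
})

test_that("Cohen's kappa matches closed forms and an independent oracle", {
  # perfect agreement
  expect_equal(cohenKappa(diag(5, 3))$kappa, 1)
  # independence (outer-product counts) gives kappa 0
  m <- outer(c(10, 20, 30), c(12, 18, 30)) / 60
  expect_equal(cohenKappa(m)$kappa, 0, tolerance = 1e-12)
  # kappa stays within [-1, 1] on random tables, and equals 1 only when
  # diagonal
  set.seed(9)
  for (i in 1:20) {
    tb <- matrix(rpois(9, 4) + 1, 3, 3)
    k <- cohenKappa(tb)$kappa
    expect_gte(k, -1); expect_lt(k, 1)
  }
  expect_error(cohenKappa(matrix(1:6, 2, 3)), "square")
  expect_error(cohenKappa(matrix(c(5, 0, 0, 0), 2, 2)), "degenerate")

  skip_if_not_installed("e1071")
  tb <- patternGradeCounts()
  expect_equal(cohenKappa(tb)$kappa,
               e1071::classAgreement(tb)$kappa, tolerance = 1e-10)
})

test_that("agreement table aligns categories and excludes undetermined", {
  labels <- c("p1", "p1", "p2", "p3", "p3", "p3")
  grades <- c("impaired", "pseudonormal", "pseudonormal", "restrictive",
              "undetermined", "impaired")
  at <- buildAgreementTable(labels, grades)
  expect_identical(at@excluded, 1L)
  expect_identical(sum(at@counts), 5L)
  expect_identical(at@counts["p1", "impaired"], 1L)
  expect_identical(at@counts["p3", "restrictive"], 1L)
})

test_that("curve CV is SD over mean and scale-free", {
  flat <- KECurve(c(0, 500), c(2, 2))
  spread <- KECurve(c(0, 500), c(0, 2))
  tab <- curveCVCompare(list(flat = flat, spread = spread))
  expect_equal(tab$cv[tab$subject == "flat"], 0)
  expect_equal(tab$cv[tab$subject == "spread"], sqrt(2), tolerance = 1e-12)
  scaled <- KECurve(c(0, 500), 7 * c(0, 2))
  expect_equal(curveCVCompare(list(s = scaled))$cv, sqrt(2),
               tolerance = 1e-12)
  expect_error(curveCVCompare(list(z = KECurve(c(0, 500), c(0, 0)))),
               "positive")
})
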