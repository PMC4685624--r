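test_that("temporal unwrapping restores aliased jumps and flags no-ops", {
  # true series crosses VENC: (90, 120, 90) wraps to (90, -80, 90)
  truth <- c(90, 120, 90)
  wrapped <- wrapModel(truth, 100)
  expect_equal(wrapped, c(90, -80, 90))
  vals <- array(0, c(1, 1, 1, 3, 3))
  vals[1, 1, 1, , 1] <- wrapped
  f <- VelocityField4D(vals, spacing = c(3, 3, 3), venc = 100)
  uw <- unwrapVelocity(f)
  expect_equal(uw$field@values[1, 1, 1, , 1], truth)
  # one correction: the jump into the wrap; the return jump is then
  # consistent with the already-corrected neighbour
  expect_identical(uw$wrapCount[1, 1, 1], 1L)

  # all speeds below VENC: identity, zero corrections
  set.seed(1)
  vals2 <- array(rnorm(4^3 * 5 * 3, sd = 10), c(4, 4, 4, 5, 3))
  f2 <- VelocityField4D(vals2, spacing = c(3, 3, 3), venc = 100)
  uw2 <- unwrapVelocity(f2)
  expect_identical(uw2$field@values, vals2)
  expect_true(all(uw2$wrapCount == 0L))

  # constant aliased series (true 120 everywhere) has no temporal jump:
  # not recoverable, by design
  vals3 <- array(0, c(1, 1, 1, 4, 3))
  vals3[1, 1, 1, , 1] <- wrapModel(rep(120, 4), 100)
  f3 <- VelocityField4D(vals3, spacing = c(3, 3, 3), venc = 100)
  uw3 <- unwrapVelocity(f3)
  expect_equal(uw3$field@values[1, 1, 1, , 1], rep(-80, 4))
  expect_identical(uw3$wrapCount[1, 1, 1], 0L)

  expect_error(unwrapVelocity(uniformField(nt = 2L)), "nt >= 3")
})

test_that("unwrapping only ever shifts by integer multiples of 2 VENC", {
  set.seed(42)
  for (rep in 1:5) {
    nt <- sample(5:12, 1)
    vals <- array(rnorm(3^3 * nt * 3, sd = 150), c(3, 3, 3, nt, 3))
    f <- VelocityField4D(vals, spacing = c(3, 3, 3), venc = 100)
    uw <- unwrapVelocity(f)
    k <- (uw$field@values - vals) / 200
    expect_true(all(abs(k - round(k)) < 1e-9))
  }
})

test_that("background fit recovers an exact linear field", {
  sim <- smallLVCycle()
  bm <- fitBackground(sim$field, sim$stationary)
  co <- backgroundCoefficients(bm)
  for (t in c(1, 10, 25))
    expect_equal(co[t, , ], unname(sim$truth$background), tolerance = 1e-9)

  # zero stationary velocities -> all-zero coefficients
  f0 <- sim$field
  f0@values[] <- 0
  co0 <- backgroundCoefficients(fitBackground(f0, sim$stationary))
  expect_true(max(abs(co0)) < 1e-12)
})

test_that("background fit rejects degenerate stationary geometry", {
  f <- uniformField(n = 9L, nt = 3L)
  planar <- array(FALSE, c(9, 9, 9, 3))
  planar[2:8, 2:8, 4, ] <- TRUE              # all voxels share one z plane
  ms <- MaskSeries(planar, role = "stationary",
                   affine = diag(c(10, 10, 10, 1)))
  expect_error(fitBackground(f, ms), "phase 1.*rank-deficient")

  few <- array(FALSE, c(9, 9, 9, 3))
  few[1:2, 1, 1, ] <- TRUE
  ms2 <- MaskSeries(few, role = "stationary",
                    affine = diag(c(10, 10, 10, 1)))
  expect_error(fitBackground(f, ms2), "fewer than 16")
})

test_that("background correction zeroes stationary tissue and is idempotent", {
  sim <- smallLVCycle()
  bm <- fitBackground(sim$field, sim$stationary)
  corr <- applyBackgroundCorrection(sim$field, bm)
  for (t in c(1, 15)) {
    m <- sim$stationary@masks[, , , t]
    for (c in 1:3)
      expect_lt(abs(mean(corr@values[, , , t, c][m])), 1e-10)
  }
  # least-squares optimality: stationary RMS never increases
  rms <- function(f) {
    m <- sim$stationary@masks
    sqrt(mean(f@values[, , , , 1][m]^2 + f@values[, , , , 2][m]^2 +
                f@values[, , , , 3][m]^2))
  }
  expect_lte(rms(corr), rms(sim$field))

  # refitting on the corrected field changes nothing appreciable
  bm2 <- fitBackground(corr, sim$stationary)
  corr2 <- applyBackgroundCorrection(corr, bm2)
  expect_lt(max(abs(corr2@values - corr@values)), 1e-9)

  # all-zero model is the identity
  bm0 <- bm
  bm0@coeffs[] <- 0
  expect_identical(applyBackgroundCorrection(sim$field, bm0)@values,
                   sim$field@values)

  short <- resamplePhases(sim$field, 10)
  expect_error(applyBackgroundCorrection(short, bm), "phases")
})

test_that("phase resampling interpolates cyclically and preserves means", {
  # temporally constant field -> identical at all 40 output phases
  f <- uniformField(u = c(12, -3, 7), n = 5L, nt = 4L)
  r <- resamplePhases(f, 40)
  expect_identical(dim(r@values)[4], 40L)
  for (t in 1:40) expect_equal(r@values[, , , t, ], f@values[, , , 1, ])

  # identity when the target grid equals the source grid
  g <- uniformField(n = 5L, nt = 5L)
  expect_identical(resamplePhases(g, 5)@values, g@values)

  # sinusoid of the cycle period: error bounded by the 10-phase linear
  # interpolation bound max|f''| h^2 / 8
  nt <- 10L
  ts <- seq(0, 1000, length.out = nt + 1L)[1:nt]
  om <- 2 * pi / 1000
  vals <- array(0, c(2, 2, 2, nt, 3))
  for (t in seq_len(nt)) vals[, , , t, 1] <- 50 * sin(om * ts[t])
  f10 <- VelocityField4D(vals, spacing = c(3, 3, 3), rr = 1000, venc = 100)
  r40 <- resamplePhases(f10, 40)
  truth <- 50 * sin(om * r40@timestamps)
  bound <- 50 * om^2 * (1000 / nt)^2 / 8
  expect_lt(max(abs(r40@values[1, 1, 1, , 1] - truth)), bound * 1.0001)

  # temporal mean preserved within the same interpolation error
  expect_lt(abs(mean(r40@values[1, 1, 1, , 1]) -
                  mean(vals[1, 1, 1, , 1])), bound)

  expect_error(resamplePhases(f, 1), "at least 2")
})
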