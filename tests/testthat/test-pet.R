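test_that("pSUV mapping assigns class uptake values", {
  g <- makeFixture("two-phase")
  p <- agentToPsuv(g)
  v <- imageValues(p)
  expect_equal(unname(v[1, 1]), 1)        # normal background
  expect_equal(unname(v[30, 30]), 8)      # normoxic tumor
  expect_equal(unname(v[30, 60]), 12)     # hypoxic tumor
  expect_equal(12 / 8, 1.5)               # hypoxic/normoxic uptake ratio
  st <- g@states; st[1, 1] <- agentStates[["TUMOR_NECROTIC"]]
  st[1, 2] <- agentStates[["VESSEL"]]
  g@states <- st
  v <- imageValues(agentToPsuv(g))
  expect_equal(unname(v[1, 1]), 0)        # necrotic
  expect_equal(unname(v[1, 2]), 1)        # vessel = blood pool background
  # an all-normal grid maps to a constant image
  gAll <- g; gAll@states[] <- agentStates[["NORMAL"]]
  expect_true(all(imageValues(agentToPsuv(gAll)) == 1))
})

test_that("noise-free reconstruction round-trips a uniform phantom", {
  ph <- makeFixture("uniform-phantom-2.37")
  rec <- simulatePet(ph)
  roiMean <- mean(imageValues(rec)[21:48, 21:48])
  expect_equal(roiMean, 2.37, tolerance = 0.01)
  expect_lt(measureNstd(rec), 1e-6)
  # zero activity in, zero image out
  z <- simulatePet(matrix(0, 68, 68), cellMm = 0.58)
  expect_equal(max(imageValues(z)), 0)
})

test_that("reconstructed point source has the nominal 2.35 mm FWHM", {
  pt <- matrix(0, 1972, 1972)
  pt[986, 986] <- 1000
  rec <- simulatePet(pt, cellMm = 0.02)
  expect_equal(measureFwhm(rec), 2.35, tolerance = 0.05)
})

test_that("OSEM preserves sinogram counts and is linear in activity", {
  acq <- acquisitionSettings()
  set.seed(2)
  img <- matrix(runif(68 * 68, 0.5, 3), 68, 68)
  rec1 <- simulatePet(img, acq, cellMm = 0.58)
  # EM fixed point: total reconstructed counts match the sinogram within 0.5%
  sys <- phenopet:::petSystemMatrix(acq)
  xb <- phenopet:::gaussianBlurPx(img, acq$preFwhm / acq$pixelMm)
  y <- as.numeric(sys$A %*% as.numeric(xb))
  recRaw <- phenopet:::osem(y, sys, acq)
  expect_lt(abs(sum(sys$A %*% recRaw) - sum(y)) / sum(y), 0.005)
  # scaling the input by k scales the noise-free reconstruction by k
  rec3 <- simulatePet(3 * img, acq, cellMm = 0.58)
  expect_equal(imageValues(rec3), 3 * imageValues(rec1), tolerance = 0.01)
})

test_that("NSTD measures noise and follows the Poisson scaling law", {
  ph <- makeFixture("uniform-phantom-2.37")
  acq <- acquisitionSettings(noiseFree = FALSE, countScale = 0.25)
  set.seed(31)
  n1 <- mean(replicate(12, measureNstd(simulatePet(ph, acq))))
  acq2 <- acq; acq2$countScale <- 4 * acq$countScale
  n2 <- mean(replicate(12, measureNstd(simulatePet(ph, acq2))))
  # quadrupling expected counts halves the NSTD (1/sqrt scaling)
  expect_equal(n2 / n1, 0.5, tolerance = 0.15)
  expect_error(measureNstd(simulatePet(ph, acq),
                           roi = matrix(FALSE, 68, 68)), "empty")
})

test_that("noise calibration hits the requested NSTD and is reproducible", {
  set.seed(41)
  acq <- calibrateNoise(0.10, nReal = 15L)
  expect_false(acq$noiseFree)
  ph <- makeFixture("uniform-phantom-2.37")
  set.seed(42)
  m <- mean(replicate(20, measureNstd(simulatePet(ph, acq))))
  expect_equal(m, 0.10, tolerance = 0.05)
  # target 0 short-circuits to the noise-free pipeline
  acq0 <- calibrateNoise(0)
  expect_true(acq0$noiseFree)
  expect_error(calibrateNoise(0.9), "0.5")
})

test_that("calibrated scales are monotone across the standard noise levels", {
  set.seed(43)
  s <- vapply(c(0.05, 0.10, 0.15), function(t)
    calibrateNoise(t, nReal = 8L)$countScale, numeric(1))
  expect_true(all(diff(s) < 0))  # higher noise = fewer counts
})

test_that("ground-truth lesion masks follow the 50% area-fraction rule", {
  acq <- acquisitionSettings()
  # no tumor -> empty mask
  g0 <- new("AgentGrid",
            states = matrix(agentStates[["NORMAL"]], 200, 200), pixelSize = 20)
  expect_equal(sum(lesionMaskFromTruth(g0, acq)), 0)
  # disc of diameter 10 mm: mask area within 10% of pi r^2
  n <- 600L
  st <- matrix(agentStates[["NORMAL"]], n, n)
  d2 <- (row(st) - 300.5)^2 + (col(st) - 300.5)^2
  st[d2 <= 250^2] <- agentStates[["TUMOR_NORMOXIC"]]  # radius 5 mm
  gDisc <- new("AgentGrid", states = st, pixelSize = 20)
  m <- lesionMaskFromTruth(gDisc, acq)
  maskArea <- sum(m) * acq$pixelMm^2
  expect_equal(maskArea, pi * 5^2, tolerance = 0.10)
  # fully tumor world -> fully masked field of view
  gT <- g0; gT@states[] <- agentStates[["TUMOR_NORMOXIC"]]
  gT2 <- new("AgentGrid", states = matrix(agentStates[["TUMOR_NORMOXIC"]],
                                          2000, 2000), pixelSize = 20)
  expect_true(all(lesionMaskFromTruth(gT2, acq)))
})
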