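## Height-frame rendering, tip convolution, scan artifacts, dataset assembly.

test_that("a frame with no events and zero roughness is flat zero", {
  z <- renderHeightFrame(NULL, flatConfig())
  expect_true(all(z == 0))
  expect_equal(dim(z), c(240L, 320L))
})

test_that("a rendered pit has the requested baseline-crossing diameter (profile oracle)", {
  cfg <- flatConfig()
  z <- renderPit(300, cx = 0, cy = 0, cfg = cfg)
  ctr <- which(z == min(z), arr.ind = TRUE)[1, ]
  expect_lt(abs(oracleRowDiameter(z, ctr) - 300), 18.75 + 1e-9)
  # grid minimum sits up to half a pixel off the continuous center
  expect_lt(abs(min(z) + 30), 0.7)
})

test_that("a capping swelling renders as a positive cap of the configured height", {
  cfg <- flatConfig()
  ev <- data.frame(x = 0, y = 0, aperture = NA_real_,
                   swellX = 150, swellY = -100, swellDia = 378, swellAmp = 38)
  z <- renderHeightFrame(ev, cfg)
  expect_equal(max(z) - median(z), 38, tolerance = 0.5)
})

test_that("tip convolution: identity cases and output >= input", {
  z <- renderPit(200)
  expect_identical(applyTipConvolution(z, 0, 18.75), z)
  flat <- matrix(2.5, 30, 30)
  expect_equal(applyTipConvolution(flat, 100, 18.75), flat)
  out <- applyTipConvolution(z, 60, 18.75)
  expect_true(all(out >= z - 1e-12))
  expect_error(applyTipConvolution(z, 1e7, 18.75), "half the grid")
})

test_that("tip convolution matches the brute-force spherical-cap oracle", {
  set.seed(8)
  z <- matrix(0, 15, 15)
  z[8, 8] <- 50          # single-pixel spike
  z[3, 12] <- 20
  z <- z + matrix(runif(225, 0, 2), 15, 15)
  for (R in c(25, 40)) {
    expect_equal(applyTipConvolution(z, R, 18.75),
                 oracleTipDilation(z, R, 18.75), tolerance = 1e-12)
  }
})

test_that("apparent aperture is non-increasing in tip radius", {
  cfg <- flatConfig()
  z <- renderPit(300, cfg = cfg)
  ctr <- which(z == min(z), arr.ind = TRUE)[1, ]
  dias <- sapply(c(0, 30, 60, 90), function(R)
    oracleRowDiameter(applyTipConvolution(z, R, 18.75), ctr))
  expect_true(all(diff(dias) <= 1e-9))
})

test_that("scan artifacts: zero rates are identity; forced skips touch only their rows", {
  set.seed(2)
  z <- matrix(rnorm(200 * 100), 200, 100)
  out <- injectScanArtifacts(z, list(pSkip = 0, pAmplitude = 0))
  expect_identical(out$frame, z)
  expect_equal(nrow(out$log), 0L)

  out <- injectScanArtifacts(z, list(pSkip = 0, pAmplitude = 0),
                             forceSkipRow = 50)
  w <- out$log$width[1]
  touched <- 50:(50 + w - 1)
  expect_true(all(out$frame[-touched, ] == z[-touched, ]))
  expect_false(all(out$frame[touched, ] == z[touched, ]))
  # skipped rows duplicate the previous row up to a constant offset
  for (r in touched)
    expect_lt(sd(out$frame[r, ] - z[49, ]), 1e-9)
})

test_that("tip-skip width corresponds to ~37 nm at the default pixel size", {
  # 1-2 scan lines at 18.75 nm/pixel: a 2-line skip spans 37.5 nm
  set.seed(3)
  widths <- replicate(50, {
    z <- matrix(rnorm(40 * 30), 40, 30)
    injectScanArtifacts(z, list(pSkip = 0, pAmplitude = 0),
                        forceSkipRow = 20)$log$width
  })
  expect_true(all(widths %in% 1:2))
  expect_equal(max(widths) * 18.75, 37.5)
})

test_that("generateDataset: empty movie, determinism, conservation", {
  cfg <- simulationConfig(nEvents = 0L, nFrames = 5L, seed = 2L,
                          artifactRates = list(pSkip = 0, pAmplitude = 0))
  b <- generateDataset(cfg)
  expect_equal(nrow(groundTruth(b)@events), 0L)
  expect_equal(nrow(groundTruth(b)@drift), 5L)
  # pure background: no frame has a pit-depth excursion
  expect_gt(min(b@height@frames), -15)

  cfg2 <- smallConfig(nEvents = 3L, nFrames = 25L, seed = 9L)
  b1 <- generateDataset(cfg2)
  b2 <- generateDataset(cfg2)
  expect_identical(b1@height@frames, b2@height@frames)
  expect_identical(b1@fluor@channels, b2@fluor@channels)
  expect_equal(nrow(groundTruth(b1)@events), 3L)
  expect_equal(nrow(groundTruth(b1)@drift), 25L)
})

test_that("motion labels drawn from the untreated mixture match their binomial expectation", {
  cfg <- simulationConfig(nEvents = 300L, nFrames = 90L, seed = 5L)
  set.seed(cfg@seed)
  ev <- sampleEvents(cfg)
  p <- 0.549
  expect_lt(abs(mean(ev$capping) - p), 3 * sqrt(p * (1 - p) / 300))
  # capping and re-opening are mutually exclusive
  expect_equal(sum(ev$capping & ev$reopen), 0L)
})

test_that("generated phase durations reproduce the configured kinetics", {
  cfg <- simulationConfig(nEvents = 300L, nFrames = 90L, seed = 6L)
  set.seed(cfg@seed)
  ev <- sampleEvents(cfg)
  expect_lt(abs(mean(ev$lifetime) - 81), 3 * 55 / sqrt(300))
  expect_true(all(ev$lifetime >= 40 & ev$lifetime <= 330))
  expect_true(all(ev$closing <= 50 + 1e-9))
  expect_true(all(ev$growing + ev$stable + ev$closing - ev$openDur < 1e-6))
})
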