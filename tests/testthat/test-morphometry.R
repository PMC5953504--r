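## Section profiles, diameters, heights, tip correction, area pipeline.

test_that("section profiles: flat grid, symmetry, and angle agreement", {
  cfg <- flatConfig()
  z <- matrix(3.2, 240, 320)
  pr <- sectionProfile(z, c(0, 0), 0, 400, pixelSize = 18.75)
  expect_true(all(abs(pr@heights - 3.2) < 1e-12))

  z <- renderPit(300, cfg = cfg)
  pr <- sectionProfile(z, c(0, 0), 0, 450, pixelSize = 18.75)
  imin <- which.min(pr@heights)
  expect_lt(abs(pr@positions[imin]), 18.75)
  # symmetric within discretization
  expect_equal(pr@heights, rev(pr@heights), tolerance = 0.02)

  d0 <- measureDiameter(sectionProfile(z, c(0, 0), 0, 450, pixelSize = 18.75))
  d90 <- measureDiameter(sectionProfile(z, c(0, 0), pi / 2, 450, pixelSize = 18.75))
  expect_lt(abs(d0 - d90), 18.75 + 1e-9)

  expect_error(sectionProfile(z, c(1e6, 0), 0, 450, pixelSize = 18.75),
               "outside")
})

test_that("edge-walk diameter: noiseless raised-cosine pit and error cases", {
  z <- renderPit(300, cfg = flatConfig())
  pr <- sectionProfile(z, c(0, 0), 0, 450, pixelSize = 18.75)
  expect_lt(abs(measureDiameter(pr) - 300), 18.75 + 1e-9)

  flat <- sectionProfile(matrix(0, 240, 320), c(0, 0), 0, 450, pixelSize = 18.75)
  expect_error(measureDiameter(flat), "no-pit")
})

test_that("rim-extrapolated diameter is unbiased within one pixel across apertures and angles", {
  cfg <- flatConfig()
  for (D in c(150, 200, 250, 300, 350, 400)) {
    z <- renderPit(D, cx = 4, cy = -6, cfg = cfg)
    for (ang in list(c(0, pi / 2), c(pi / 4, 3 * pi / 4))) {
      d <- sectionDiameter(z, c(4, -6), 18.75, angles = ang)
      expect_lt(abs(d - D), 18.75 + 1e-9)
    }
  }
})

test_that("height measurement: symmetric bump, flat error, tilted baseline", {
  cfg <- flatConfig()
  mkBump <- function(h, tilt = 0) {
    ev <- data.frame(x = 0, y = 0, aperture = NA_real_,
                     swellX = 0, swellY = 0, swellDia = 378, swellAmp = h)
    z <- renderHeightFrame(ev, cfg)
    if (tilt != 0) z <- z + outer(rep(1, 240), seq(-tilt, tilt, length.out = 320))
    z
  }
  pr <- sectionProfile(mkBump(38), c(0, 0), 0, 450, pixelSize = 18.75)
  expect_equal(measureHeight(pr), 38, tolerance = 0.5)

  flat <- sectionProfile(matrix(1, 240, 320), c(0, 0), 0, 450, pixelSize = 18.75)
  expect_error(measureHeight(flat), "no-peak")

  prT <- sectionProfile(mkBump(38, tilt = 5), c(0, 0), 0, 450, pixelSize = 18.75)
  expect_lt(abs(measureHeight(prT) - 38), 2)
})

test_that("tip correction follows the instrument arithmetic", {
  expect_identical(tipCorrect(150, 10), 130)
  expect_identical(tipCorrect(400, 10), 380)
  expect_identical(tipCorrect(237, 0), 237)
  expect_error(tipCorrect(15, 10), "domain")
})

test_that("area pipeline: flat ROI, disk depression, and top-hat size cutoff", {
  roi <- list(rows = c(1, 60), cols = c(1, 60))
  flat <- matrix(0, 60, 60)
  expect_equal(measureArea(flat, roi, 18.75), 0)

  # disk depression of diameter 10 px
  z <- matrix(0, 60, 60)
  rr <- row(z); cc <- col(z)
  z[(rr - 30)^2 + (cc - 30)^2 <= 5^2] <- -25
  a <- measureArea(z, roi, 18.75)
  expected <- sum((rr - 30)^2 + (cc - 30)^2 <= 5^2) * 18.75^2
  expect_lt(abs(a - expected) / expected, 0.15)

  # structure wider than the top-hat element is removed
  z2 <- matrix(0, 60, 60)
  z2[(rr - 30)^2 + (cc - 30)^2 <= 24^2] <- -25
  a2 <- measureArea(z2, roi, 18.75)
  expect_lt(a2, 0.1 * sum((rr - 30)^2 + (cc - 30)^2 <= 24^2) * 18.75^2)

  expect_error(measureArea(z, list(rows = c(2, 1), cols = c(1, 0)), 18.75),
               "roi")
})

test_that("area pipeline agrees with a brute-force morphology oracle on a small grid", {
  set.seed(12)
  z <- matrix(0, 40, 40)
  rr <- row(z); cc <- col(z)
  z[(rr - 20)^2 + (cc - 20)^2 <= 4^2] <- -20
  z <- z + matrix(rnorm(1600, 0, 0.3), 40, 40)

  # oracle: same cascade with brute-force operators
  x01 <- (z - min(z)) / diff(range(z))
  med <- as.matrix(EBImage::medianFilter(EBImage::Image(x01), 1))
  mk <- function(d) { m <- EBImage::makeBrush(d, "disc"); m }
  bth <- oracleErode(oracleDilate(med, mk(19)), mk(19)) - med   # closing - x
  # opening (erode-dilate) then closing (dilate-erode)
  op <- oracleDilate(oracleErode(bth, mk(5)), mk(5))
  ocl <- oracleErode(oracleDilate(op, mk(5)), mk(5))
  areaOracle <- sum(ocl >= max(ocl) / 2) * 18.75^2

  a <- measureArea(z, list(rows = c(1, 40), cols = c(1, 40)), 18.75)
  expect_lt(abs(a - areaOracle) / max(areaOracle, 1), 0.2)
})

test_that("opening-then-closing is idempotent at the mask level", {
  set.seed(4)
  z <- matrix(runif(900), 30, 30)
  k <- EBImage::makeBrush(5, "disc")
  oc1 <- as.matrix(EBImage::closing(EBImage::opening(EBImage::Image(z), k), k))
  oc2 <- as.matrix(EBImage::closing(EBImage::opening(EBImage::Image(oc1), k), k))
  m1 <- oc1 >= max(oc1) / 2
  m2 <- oc2 >= max(oc2) / 2
  expect_identical(m1, m2)
})

test_that("area tracks the aperture for disk-like depressions", {
  roi <- list(rows = c(1, 60), cols = c(1, 60))
  z <- matrix(0, 60, 60)
  rr <- row(z); cc <- col(z)
  for (rad in c(4, 6)) {
    zz <- z; zz[(rr - 30)^2 + (cc - 30)^2 <= rad^2] <- -25
    a <- measureArea(zz, roi, 18.75)
    d <- 2 * rad * 18.75
    expect_lt(abs(a - pi * (d / 2)^2) / (pi * (d / 2)^2), 0.2)
  }
})
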