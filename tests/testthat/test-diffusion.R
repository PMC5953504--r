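## Drift estimation, MSD computation, diffusion fits.

brownianTracks <- function(n, D, drift, nFrames, dt = 10) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    p <- sampleTrajectory(D, drift, nFrames, dt)
    data.frame(event_id = i, frame = seq_len(nFrames), x = p[, 1], y = p[, 2])
  }))
}

test_that("drift estimation: common translation and stationary cases", {
  # all tracks translated by (100, 0) over the movie
  tracks <- do.call(rbind, lapply(1:5, function(i)
    data.frame(event_id = i, frame = 1:11,
               x = i * 1000 + seq(0, 100, by = 10), y = 0)))
  de <- estimateDrift(tracks, 11, "ensemble")
  expect_equal(de@net, c(100, 0), tolerance = 1e-9)
  deFL <- estimateDrift(tracks, 11, "first-last")
  expect_equal(deFL@net, c(100, 0), tolerance = 1e-9)

  one <- data.frame(event_id = 1, frame = 1:10, x = 5, y = -3)
  expect_equal(estimateDrift(one, 10)@net, c(0, 0))

  expect_error(estimateDrift(one[1, ], 10), "insufficient-data")
})

test_that("MSD: two-point displacement, drift cancellation, ballistic signature", {
  tr <- data.frame(event_id = 1, frame = 1:2, x = c(0, 30), y = c(0, 40))
  m <- computeMSD(tr, NULL, 10)
  expect_equal(m@msd[m@lag == 10], 2500)
  expect_equal(m@msd[m@lag == 0], 0)

  # pure drift with a matching estimate: corrected MSD ~ 0
  v <- 20
  tracks <- do.call(rbind, lapply(1:10, function(i)
    data.frame(event_id = i, frame = 1:20, x = i * 500 + v * (0:19), y = 0)))
  de <- estimateDrift(tracks, 20)
  m <- computeMSD(tracks[tracks$event_id == 1, ], de, 10)
  expect_lt(max(m@msd), 1e-9)

  # uncorrected linear motion: MSD(t) = v^2 t^2 (per-frame speed v/dt)
  m2 <- computeMSD(tracks[tracks$event_id == 1, ], NULL, 10)
  lag <- m2@lag[m2@lag > 0]
  expect_equal(m2@msd[m2@lag > 0], (v / 10)^2 * lag^2, tolerance = 1e-9)

  expect_error(computeMSD(tr[1, ], NULL, 10), "insufficient-data")
})

test_that("fitDiffusion returns D exactly on an exact 4*D*t curve", {
  D <- 5e-10
  lag <- c(0, 10, 20, 30, 40)
  msd <- new("MSDCurve", lag = lag, msd = 4 * D * 1e14 * lag,
             n = c(0L, rep(100L, 4)))
  fit <- fitDiffusion(msd, 4)
  expect_equal(fit@D, D, tolerance = 1e-12)
  expect_false(fit@flagged)
  expect_error(fitDiffusion(msd, 4, minCount = 1000), "insufficient")
})

test_that("corrected D is invariant to an added common drift within 2%", {
  set.seed(21)
  D <- 7.3e-9; dt <- 10
  t0 <- brownianTracks(200, D, c(0, 0), 25, dt)
  t1 <- t0
  t1$x <- t1$x + 25 * (t1$frame - 1)   # add 25 nm/frame drift
  f0 <- fitDiffusion(ensembleMSD(t0, estimateDrift(t0, 25), dt, 4), 4)
  f1 <- fitDiffusion(ensembleMSD(t1, estimateDrift(t1, 25), dt, 4), 4)
  expect_lt(abs(f1@D - f0@D) / f0@D, 0.02)
})

test_that("a motionless ensemble yields D = 0", {
  lag <- c(0, 10, 20, 30, 40)
  msd <- new("MSDCurve", lag = lag, msd = rep(0, 5),
             n = c(0L, rep(50L, 4)))
  fit <- fitDiffusion(msd, 4)
  expect_equal(fit@D, 0)
  expect_false(fit@flagged)
})
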