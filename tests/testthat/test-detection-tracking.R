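## Pit detection, linking with gap closing, identity, lifetimes.

test_that("detection: flat frame yields nothing; single and double pits are found", {
  expect_equal(nrow(detectPits(matrix(0, 240, 320), 18.75)), 0L)

  cfg <- flatConfig()
  z <- renderPit(300, cx = 50, cy = -30, cfg = cfg)
  d <- detectPits(z, 18.75)
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$x - 50), 18.75)
  expect_lt(abs(d$y + 30), 18.75)
  expect_gt(d$depth, 25)

  ev <- data.frame(x = c(-250, 250), y = c(0, 0), aperture = c(300, 300))
  z2 <- renderHeightFrame(ev, cfg)
  d2 <- detectPits(z2, 18.75)
  expect_equal(nrow(d2), 2L)
})

test_that("artifact rows are excluded from detection", {
  cfg <- flatConfig()
  z <- renderPit(300, cx = 0, cy = 0, cfg = cfg)
  inj <- injectScanArtifacts(z, list(pSkip = 0, pAmplitude = 0),
                             forceSkipRow = 60)
  d <- detectPits(inj$frame, 18.75,
                  artifactLog = data.frame(frame = 1, inj$log))
  expect_equal(nrow(d), 1L)  # pit still found, skip rows not spurious
})

test_that("linking: stationary detections form one gapless track; long jumps split", {
  det <- data.frame(frame = 1:6, x = 0, y = 0, depth = 30, diameter = 300,
                    area_px = 20, score = 30)
  tr <- linkTracks(det)
  expect_equal(length(unique(tr$event_id)), 1L)
  expect_equal(nrow(attr(tr, "gaps")), 0L)

  det2 <- det
  det2$x <- c(0, 0, 0, 5000, 5000, 5000)
  tr2 <- linkTracks(det2)
  expect_equal(length(unique(tr2$event_id)), 2L)
})

test_that("a re-opening gap is bridged into a single track with one closed-gap interval", {
  det <- data.frame(frame = c(1:5, 9:12),
                    x = c(rep(0, 5), rep(50, 4)), y = 0,
                    depth = 30, diameter = 300, area_px = 20, score = 30)
  tr <- linkTracks(det)
  expect_equal(length(unique(tr$event_id)), 1L)
  g <- attr(tr, "gaps")
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$gapStart, g$gapEnd), c(6L, 8L))
  expect_equal(g$displacement, 50)
})

test_that("no detection is claimed by two tracks", {
  set.seed(20)
  b <- generateDataset(smallConfig(nEvents = 8L, nFrames = 50L, seed = 20L))
  det <- detectPitsMovie(b@height)
  tr <- linkTracks(det)
  key <- paste(tr$frame, tr$x, tr$y)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("tracking recall and precision >= 0.9 at default noise", {
  b <- generateDataset(smallConfig(nEvents = 8L, nFrames = 60L, seed = 33L))
  res <- runAnalyze(b)
  ev <- runEvaluate(res, b)
  expect_gte(ev$detectionRecall, 0.9)
  expect_gte(ev$detectionPrecision, 0.9)
})

test_that("lifetime and formation-rate arithmetic", {
  tr <- data.frame(event_id = 1L, frame = 5:13, x = 0, y = 0)
  lt <- lifetimeAndRate(tr, areaUm2 = 27, durationS = 900, dt = 10,
                        nFramesTotal = 90)
  expect_equal(lt$lifetimes$lifetime_s, 90)
  expect_false(lt$lifetimes$censored)

  # 12 new tracks in 27 um^2 over 15 min
  tr12 <- do.call(rbind, lapply(1:12, function(i)
    data.frame(event_id = i, frame = c(2 * i, 2 * i + 1), x = i, y = i)))
  lt12 <- lifetimeAndRate(tr12, 27, 900, 10, 900 / 10)
  expect_equal(lt12$formationFrequency, 12 / 27 / 15, tolerance = 1e-12)

  expect_error(lifetimeAndRate(tr, 27, 0, 10, 90), "zero-duration")

  # censored tracks never exceed the movie duration and are excluded
  trC <- data.frame(event_id = 1L, frame = 80:90, x = 0, y = 0)
  ltC <- lifetimeAndRate(trC, 27, 900, 10, 90)
  expect_true(ltC$lifetimes$censored)
  expect_true(is.na(ltC$meanLifetime) || ltC$meanLifetime <= 900)
})

test_that("identity assignment: markers win, size prior is the fallback", {
  cfg <- simulationConfig(nEvents = 6L, nFrames = 40L, seed = 15L,
                          mixture = list(ccp = 0.5))
  b <- generateDataset(cfg)
  res <- runAnalyze(b)
  truthIds <- groundTruth(b)@events
  ev <- runEvaluate(res, b)
  m <- merge(ev$matches, res$identities, by = "event_id")
  m <- merge(m, truthIds[, c("event", "identity")],
             by.x = "truth_event", by.y = "event")
  agree <- mean(m$identity.x == m$identity.y)
  expect_gte(agree, 0.8)

  # markerless: size prior
  trackSmall <- data.frame(frame = 1:5, x = 0, y = 0, diameter = 100)
  tf <- buildTransform(scanGeometry())
  expect_equal(assignIdentity(trackSmall, NULL, tf, tipRadius = 0),
               "caveola-like")
  trackBig <- data.frame(frame = 1:5, x = 0, y = 0, diameter = 300)
  expect_equal(assignIdentity(trackBig, NULL, tf, tipRadius = 10), "CCP-like")
  trackMid <- data.frame(frame = 1:5, x = 0, y = 0, diameter = 135)
  expect_equal(assignIdentity(trackMid, NULL, tf, tipRadius = 0),
               "unclassified")
})
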