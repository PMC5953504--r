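## Closing-motion classification and condition summaries.

test_that("capping events are recognized and plain closures are not", {
  b <- generateDataset(smallConfig(nEvents = 8L, nFrames = 60L, seed = 11L))
  res <- runAnalyze(b)
  ev <- runEvaluate(res, b)
  m <- merge(ev$matches, res$motions, by = "event_id")
  m <- merge(m, groundTruth(b)@events[, c("event", "capping", "two_step", "reopen")],
             by.x = "truth_event", by.y = "event", suffixes = c(".p", ".t"))
  expect_gte(nrow(m), 6)
  expect_gte(mean(m$capping.p == m$capping.t), 0.85)
  expect_gte(mean(m$two_step.p == m$two_step.t), 0.85)
  expect_gte(mean(m$reopen.p == m$reopen.t), 0.85)
})

test_that("a swelling that never covers the pit is not capping", {
  # plain pit next to an off-side bump that stays away from the pit center
  cfg <- flatConfig()
  frames <- array(0, c(240, 320, 12))
  for (k in 1:10) frames[, , k] <-
    renderHeightFrame(data.frame(x = 0, y = 0, aperture = 300), cfg)
  # bump far from the pit (never overlapping its centroid) in the window
  for (k in 9:12) {
    ev <- data.frame(x = NA, y = NA, aperture = NA,
                     swellX = 500, swellY = 0, swellDia = 250, swellAmp = 38)
    frames[, , k] <- frames[, , k] + renderHeightFrame(ev, cfg)
  }
  hm <- new("HeightMovie", frames = frames, frameInterval = 10,
            geometry = scanGeometry(), artifactLog = data.frame())
  track <- data.frame(event_id = 1L, frame = 1:10, x = 0, y = 0, diameter = 300)
  sw <- detectSwelling(hm, track)
  expect_true(is.null(sw) || !sw$covers)
  ann <- classifyClosing(track, NULL, sw, 10, 12)
  expect_false(ann$capping)
})

test_that("re-open annotation records gap duration, displacement and retention", {
  b <- generateDataset(simulationConfig(nEvents = 5L, nFrames = 70L, seed = 5L,
                                        mixture = list(capping = 0, two_step = 0,
                                                       reopen = 1)))
  res <- runAnalyze(b)
  mo <- res$motions[res$motions$reopen, ]
  expect_gte(nrow(mo), 3)
  expect_true(all(mo$reopenGap_s >= 10 & mo$reopenGap_s <= 70))
  expect_true(all(mo$reopenDisp_nm <= 120))
  ret <- mo$retention[!is.na(mo$retention)]
  expect_gte(length(ret), 2)
  expect_lt(abs(mean(ret) - 0.39), 0.3)
})

test_that("motion summary arithmetic and cross-tab consistency", {
  ann <- data.frame(event_id = 1:100,
                    capping = c(rep(TRUE, 55), rep(FALSE, 45)),
                    two_step = rep(c(TRUE, FALSE), 50),
                    reopen = c(rep(FALSE, 90), rep(TRUE, 10)),
                    plain = FALSE, plateauFrames = 0)
  s <- motionSummary(ann)
  expect_equal(unname(s$percentages["capping"]), 55)
  expect_equal(sum(s$crossTab), 100)
  expect_equal(sum(s$crossTab[2, ]), 55)
  expect_error(motionSummary(ann[0, ]), "empty")
})

test_that("the untreated mixture suppresses capping/re-open co-occurrence (odds ratio < 1)", {
  cfg <- simulationConfig(nEvents = 400L, nFrames = 90L, seed = 17L)
  set.seed(cfg@seed)
  ev <- sampleEvents(cfg)
  ann <- data.frame(event_id = ev$event, capping = ev$capping,
                    two_step = ev$two_step, reopen = ev$reopen,
                    plain = !(ev$capping | ev$two_step | ev$reopen),
                    plateauFrames = 0)
  s <- motionSummary(ann)
  expect_lt(s$cappingReopenOddsRatio, 1)
})

test_that("the cytochalasin-B preset collapses capping and inflates re-opening", {
  b <- generateDataset(simulationConfig(nEvents = 25L, nFrames = 90L,
                                        seed = 19L, preset = "cytoB"))
  res <- runAnalyze(b)
  s <- res$motionSummary
  expect_lt(s$percentages[["capping"]], 5)
  expect_gt(s$percentages[["reopen"]], 40)
})
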