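## Slope-rule phase segmentation and protein-timing statistics.

test_that("trapezoid trace: the stable run covers the flat interior", {
  tr <- c(seq(0, 1, by = 0.2), rep(1, 6), seq(1, 0, by = -0.2))
  seg <- segmentPhases(tr, 10)
  expect_false(is.na(seg@stableStart))
  # interior flat frames (smoothing blurs the boundary frames)
  expect_lte(seg@stableStart, 8)
  expect_gte(seg@stableEnd, 11)
})

test_that("a ramp of +0.08/frame is entirely stable (slope inside the band)", {
  tr <- seq(0.2, 1, by = 0.08)
  seg <- segmentPhases(c(tr, 1, 1), 10)
  expect_false(is.na(seg@stableStart))
  expect_lte(seg@stableStart, 3)
})

test_that("a sharp triangle has no stable run and splits at the peak", {
  tr <- c(seq(0, 1, by = 0.25), seq(0.75, 0, by = -0.25))
  seg <- segmentPhases(tr, 10)
  expect_true(is.na(seg@stableStart))
  expect_equal(seg@stable, 0)
  expect_gt(seg@growing, 0)
  expect_gt(seg@closing, 0)
})

test_that("segmentation is invariant to positive rescaling of the raw trace", {
  set.seed(7)
  base <- c(seq(0, 1, 0.15), rep(1, 8), seq(1, 0.05, -0.12))
  tr <- abs(base + rnorm(length(base), 0, 0.01))
  s1 <- segmentPhases(tr, 10)
  s2 <- segmentPhases(tr * 731.8, 10)
  expect_identical(s1@stableStart, s2@stableStart)
  expect_identical(s1@stableEnd, s2@stableEnd)
  expect_identical(s1@growing, s2@growing)
})

test_that("phase durations exactly tile the signal interval", {
  set.seed(8)
  for (i in 1:20) {
    tr <- c(seq(0, 1, length.out = sample(4:10, 1)),
            rep(1, sample(5:9, 1)),
            seq(1, 0, length.out = sample(4:8, 1)))
    seg <- segmentPhases(tr, 10)
    span <- (seg@signalEnd - seg@signalStart + 1L) * 10
    expect_equal(seg@growing + seg@stable + seg@closing, span)
  }
})

test_that("widening the slope band never shortens the stable phase", {
  set.seed(9)
  for (i in 1:15) {
    base <- c(seq(0, 0.8, 0.16), rep(0.8, 7), 1, seq(1, 0, -0.2))
    tr <- pmax(base + rnorm(length(base), 0, 0.02), 0)
    s1 <- segmentPhases(tr, 10, slopeBounds = c(-0.05, 0.1))
    s2 <- segmentPhases(tr, 10, slopeBounds = c(-0.10, 0.2))
    expect_gte(s2@stable, s1@stable)
  }
})

test_that("all-zero traces raise a no-signal error", {
  expect_error(segmentPhases(rep(0, 10), 10), "no-signal")
})

test_that("phase boundaries are recovered within 1 frame (clean) and 2 frames (noisy) for >= 90% of events", {
  set.seed(3)
  n <- 60; ok0 <- 0; okN <- 0
  for (i in 1:n) {
    G <- runif(1, 30, 50); S <- runif(1, 60, 160)
    tInv <- 100 + runif(1, 0, 20)
    ev <- data.frame(tInv = tInv, tCls = tInv + G + S + 30, tR1 = NA,
                     growing = G, stable = S, closing = 30, reopen = FALSE,
                     gapFrames = 0L, retention = NA, offApp = -10,
                     offPeak = rnorm(1, 3, 3), offDis = 39)
    tr <- synthesizeTrace(ev, "clathrin", nFrames = 45, dt = 10)
    pf <- attr(tr, "phaseFrames")
    s0 <- segmentPhases(tr, 10)
    sN <- segmentPhases(pmax(as.numeric(tr) + rnorm(45, 0, 0.02), 0), 10)
    e0 <- max(abs(s0@stableStart - pf$stableStart),
              abs(s0@stableEnd - pf$stableEnd))
    eN <- max(abs(sN@stableStart - pf$stableStart),
              abs(sN@stableEnd - pf$stableEnd))
    ok0 <- ok0 + (!is.na(e0) && e0 <= 1)
    okN <- okN + (!is.na(eN) && eN <= 2)
  }
  expect_gte(ok0 / n, 0.9)
  expect_gte(okN / n, 0.9)
})

test_that("event-time arithmetic: confirmation run and closure frame", {
  tr <- data.frame(frame = 3:10)
  t <- detectEventTimes(tr, 10, 90)
  expect_equal(t$t0Invagination, 30)
  expect_equal(t$t0Closure, 110)
  expect_false(t$censored)

  trC <- data.frame(frame = 85:90)
  tC <- detectEventTimes(trC, 10, 90)
  expect_true(tC$censored)
  expect_true(is.na(tC$t0Closure))
})

test_that("re-open tracks take closure at the final closure, not the gap", {
  b <- generateDataset(simulationConfig(nEvents = 4L, nFrames = 70L, seed = 5L,
                                        mixture = list(capping = 0, two_step = 0,
                                                       reopen = 1)))
  res <- runAnalyze(b)
  ev <- runEvaluate(res, b)
  m <- merge(ev$matches, res$events, by = "event_id")
  m <- merge(m, groundTruth(b)@events[, c("event", "tCls")],
             by.x = "truth_event", by.y = "event")
  m <- m[!m$censored, ]
  expect_gt(nrow(m), 1)
  expect_true(all(abs(m$t0_closure - m$tCls) <= 15))
})

test_that("clathrin cohort timing: appearance ~34 s before invagination", {
  offs <- c()
  for (sd in c(41, 42)) {
    b <- generateDataset(simulationConfig(nEvents = 18L, nFrames = 90L, seed = sd))
    res <- runAnalyze(b)
    if (!is.null(res$timing)) offs <- c(offs, res$timing$app_vs_invagination)
  }
  expect_gte(length(offs), 25)
  tol <- max(2 * 13 / sqrt(length(offs)), 10)  # 2 SE, floored at one frame
  expect_lt(abs(mean(offs) - (-34)), tol)
})

test_that("a trace indistinguishable from background is reported absent", {
  tt <- data.frame(frame = 1:20, raw = 10, bgMean = 10, bgSd = 1,
                   net = 0)
  expect_null(relativeTiming(tt, list(t0Invagination = 50, t0Closure = 100), 10))
})

test_that("actin-style synthetic cohort peaks just after closure", {
  set.seed(6)
  pk <- c()
  for (i in 1:30) {
    ev <- data.frame(tInv = 200, tCls = 350, tR1 = NA, growing = 50,
                     stable = 70, closing = 30, reopen = FALSE, gapFrames = 0L,
                     retention = NA, offApp = NA, offPeak = NA, offDis = NA)
    tr <- as.numeric(synthesizeTrace(ev, "actin", nFrames = 60, dt = 10))
    # manufacture a measured-trace table from the synthetic amplitude
    tb <- data.frame(frame = 1:60, raw = 100 * tr + 20, bgMean = 20,
                     bgSd = 1.5, net = 100 * tr)
    tm <- relativeTiming(tb, list(t0Invagination = 200, t0Closure = 350), 10)
    pk <- c(pk, tm$peak_vs_closure)
  }
  tol <- max(2 * 7 / sqrt(length(pk)), 10)
  expect_lt(abs(mean(pk) - 2.5), tol)
})
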