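## Trace synthesis: channel timing structure and normalization.

mkEvent <- function(tInv = 200, L = 150, G = 50, S = 70, C = 30,
                    offApp = -34, offPeak = 3, offDis = 39) {
  data.frame(tInv = tInv, tCls = tInv + L, tR1 = NA_real_, growing = G,
             stable = S, closing = C, reopen = FALSE, gapFrames = 0L,
             retention = NA_real_, offApp = offApp, offPeak = offPeak,
             offDis = offDis)
}

test_that("clathrin trace appears ~34 s before invagination and persists ~39 s after closure", {
  ev <- mkEvent()
  tr <- synthesizeTrace(ev, "clathrin", nFrames = 60, dt = 10)
  k <- attr(tr, "knots")
  expect_equal(k$tApp, ev$tInv - 34)
  expect_equal(k$tDis, ev$tCls + 39)
  tt <- seq_len(60) * 10
  expect_true(all(tr[tt < k$tApp] == 0))
  expect_true(all(tr[tt > k$tDis] == 0))
  expect_gt(tr[which(tt > ev$tCls + 20)[1]], 0)  # still present after closure
  expect_equal(max(tr), 1)
})

test_that("closure at the movie edge truncates the trace without error", {
  ev <- mkEvent(tInv = 400, L = 190)  # closure at t = 590, movie ends 600
  tr <- synthesizeTrace(ev, "clathrin", nFrames = 60, dt = 10)
  expect_length(as.numeric(tr), 60)
  expect_true(all(tr >= 0 & tr <= 1))
})

test_that("zero-duration stable phase gives a monotone rise then fall with a unique peak", {
  ev <- mkEvent(L = 80, G = 50, S = 0, C = 30, offPeak = 0)
  tr <- as.numeric(synthesizeTrace(ev, "clathrin", nFrames = 60, dt = 10))
  pk <- which.max(tr)
  expect_equal(sum(tr == max(tr)), 1L)
  sig <- which(tr > 0)
  expect_true(all(diff(tr[sig[1]:pk]) >= -1e-12))
  expect_true(all(diff(tr[pk:sig[length(sig)]]) <= 1e-12))
})

test_that("actin is a closure-anchored burst peaking just after closure", {
  ev <- mkEvent()
  set.seed(5)
  means <- replicate(200, {
    tr <- synthesizeTrace(ev, "actin", nFrames = 60, dt = 10)
    attr(tr, "knots")$tPeak - ev$tCls
  })
  expect_lt(abs(mean(means) - 2.5), 2 * 7 / sqrt(200) + 1)
})

test_that("re-opening traces dip to the retention fraction during the gap", {
  ev <- mkEvent(tInv = 150, L = 200)
  ev$reopen <- TRUE; ev$gapFrames <- 3L
  ev$tR1 <- ev$tInv + 100; ev$retention <- 0.39
  tr <- as.numeric(synthesizeTrace(ev, "clathrin", nFrames = 60, dt = 10))
  gapFrames <- (ev$tR1 / 10 + 1):(ev$tR1 / 10 + 3)
  expect_lt(min(tr[gapFrames]), 0.45)
  expect_gt(min(tr[gapFrames]), 0.3)
})

test_that("unknown channels raise a configuration error", {
  expect_error(synthesizeTrace(mkEvent(), "arp2/3", nFrames = 30, dt = 10),
               "timing parameters")
})

test_that("caveolin traces are constant presence", {
  ev <- mkEvent(); ev$tInv <- 10
  tr <- as.numeric(synthesizeTrace(ev, "caveolin", nFrames = 30, dt = 10))
  expect_true(all(tr[1:30] == 1))
})
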