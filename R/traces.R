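## Fluorescence trace synthesis.

PLATEAU_LEVEL <- 0.75   # stable-phase level of the max-normalized trace
ONSET_JUMP <- 0.10      # one-frame nucleation jump at appearance (x plateau)

## Piecewise-linear evaluation with flat extrapolation; knots sanitized to
## strictly increasing times.
evalKnots <- function(kt, kv, tout) {
  ord <- order(kt)
  kt <- kt[ord]; kv <- kv[ord]
  keep <- c(TRUE, diff(kt) > 1e-9)
  kt <- kt[keep]; kv <- kv[keep]
  if (length(kt) == 1L) return(rep(kv, length(tout)))
  stats::approx(kt, kv, xout = tout, rule = 2)$y
}

#' Synthesize a per-frame fluorescence amplitude trace for one event
#'
#' Builds the normalized (max = 1) intensity time course of a protein channel
#' at one endocytic event. Coat proteins (clathrin, epsin, dynamin) appear
#' before the membrane invaginates, rise through the growing phase with a
#' small one-frame nucleation jump, hold a stable plateau, rise to their peak
#' near pit closure, and decay to zero by their disappearance offset. The
#' actin channel is a closure-anchored burst. Re-opening events dip to the
#' event's retention fraction during the closed gap. Caveolin is constant
#' while the caveola is present.
#'
#' Timing offsets are taken from the event record when present (columns
#' offApp/offPeak/offDis, as drawn by [sampleEvents()] for the clathrin
#' channel) and are otherwise drawn from `timingParams` using the current
#' RNG stream.
#'
#' @param event one-row data.frame as returned by [sampleEvents()].
#' @param channel channel name with an entry in `timingParams`.
#' @param timingParams per-channel timing list; see [defaultTimingParams()].
#' @param nFrames number of frames.
#' @param dt frame interval (s); frame k is timestamped t = k*dt.
#' @return numeric vector of length `nFrames` in [0, 1], with attributes
#'   `knots` (construction times) and `phaseFrames` (growing/stable/closing
#'   frame boundaries implied by the construction).
#' @export
synthesizeTrace <- function(event, channel, timingParams = defaultTimingParams(),
                            nFrames, dt) {
  tp <- timingParams[[channel]]
  if (is.null(tp))
    stop("configuration error: no timing parameters for channel '", channel,
         "'", call. = FALSE)
  tt <- seq_len(nFrames) * dt
  ev <- as.list(event)

  if (identical(tp$anchor, "none")) {
    tr <- as.numeric(tt >= ev$tInv)
    attr(tr, "knots") <- list(tApp = ev$tInv)
    return(tr)
  }

  useOwn <- channel == "clathrin" && !is.null(ev$offApp) && is.finite(ev$offApp)
  offApp <- if (useOwn) ev$offApp else rnormTrunc(1, tp$app[1], tp$app[2], -120, -1)
  offPeak <- if (useOwn) ev$offPeak else stats::rnorm(1, tp$peak[1], tp$peak[2])
  offDis <- if (useOwn) ev$offDis else
    pmax(rnormTrunc(1, tp$dis[1], tp$dis[2], 2, 120), offPeak + dt)

  tCls <- ev$tCls
  if (is.null(tCls) || !is.finite(tCls)) tCls <- (nFrames + 2) * dt

  if (identical(tp$anchor, "closure")) {
    tApp <- tCls + offApp
    tPeak <- tCls + offPeak
    tDis <- tCls + offDis
    tSS <- tPeak; tR0 <- tPeak
    kt <- c(tApp, tPeak, tDis)
    kv <- c(0, 1, 0)
  } else {
    tApp <- ev$tInv + offApp
    tSS <- ev$tInv + ev$growing            # trace stable start
    tPeak <- tCls + offPeak
    tDis <- tCls + offDis
    tR0 <- max(tPeak - 2 * dt, tSS)        # start of the final rise
    p <- PLATEAU_LEVEL
    kt <- c(tApp, tApp + dt, tSS, tR0, tPeak, tDis)
    kv <- c(0, ONSET_JUMP * p, p, p, 1, 0)
    if (isTRUE(ev$reopen) && !is.null(ev$tR1) && is.finite(ev$tR1)) {
      gapEnd <- ev$tR1 + ev$gapFrames * dt
      ret <- if (!is.null(ev$retention) && is.finite(ev$retention)) ev$retention else 0.39
      selLo <- kt < ev$tR1 - 1e-9
      selHi <- kt > gapEnd + dt + 1e-9
      # the clathrin signal drops to the retention fraction of its maximum
      # and stays there for the whole closed state
      ins <- c(ev$tR1, ev$tR1 + dt / 2, gapEnd + dt / 2, gapEnd + dt)
      insv <- c(p, ret, ret, p)
      kt <- c(kt[selLo], ins, kt[selHi])
      kv <- c(kv[selLo], insv, kv[selHi])
    }
  }
  # zero before appearance and after disappearance
  kt <- c(tApp - dt, kt, tDis + dt)
  kv <- c(0, kv, 0)
  tr <- evalKnots(kt, kv, tt)
  tr[tt < tApp] <- 0
  tr[tt > tDis] <- 0
  m <- max(tr)
  if (m <= 0) stop("no-signal: trace is all zero within the movie", call. = FALSE)
  tr <- tr / m
  attr(tr, "knots") <- list(tApp = tApp, tStableStart = tSS, tRise = tR0,
                            tPeak = tPeak, tDis = tDis)
  attr(tr, "phaseFrames") <- tracePhaseFrames(tApp, tSS, tPeak, tDis, dt, nFrames)
  tr
}

## Frame-index phase boundaries implied by the trace construction: growing =
## signal start .. stable start; the stable phase ends at the peak frame
## (the 3-frame-smoothed slope first leaves the band there); closing = peak
## .. signal end. Frame k covers time k*dt.
tracePhaseFrames <- function(tApp, tSS, tPeak, tDis, dt, nFrames) {
  f <- function(t) max(1L, min(nFrames, as.integer(ceiling(t / dt - 1e-9))))
  fr <- function(t) max(1L, min(nFrames, as.integer(round(t / dt))))
  list(signalStart = f(tApp), stableStart = f(tSS),
       stableEnd = fr(tPeak), signalEnd = f(tDis))
}
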