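## Event sampling: lifecycle kinetics, motion labels and geometry draws.

## Lifetime model: 40 + Gamma(shape, scale) truncated at 330 s. The shape and
## scale were solved numerically so that the truncated distribution has mean
## 81 s and SD 55 s on [40, 330] s (no truncated normal can reach that SD at
## that mean on this support).
LIFETIME_SHAPE <- 0.43447870
LIFETIME_SCALE <- 106.92831895
LIFETIME_MIN <- 40
LIFETIME_MAX <- 330

sampleLifetimes <- function(n, scaleFactor = 1) {
  LIFETIME_MIN + rgammaTrunc(n, LIFETIME_SHAPE,
                             LIFETIME_SCALE * scaleFactor,
                             (LIFETIME_MAX - LIFETIME_MIN) * scaleFactor)
}

#' Draw the per-event specifications for a simulated acquisition
#'
#' Samples, for each event: identity (CCP vs caveola), lifetime and the
#' growing/stable/closing split of the AFM aperture series, closing-motion
#' labels from the configured mixture (capping and re-opening are mutually
#' exclusive; two-step may co-occur), geometry draws (max aperture, plateau
#' diameter, swelling diameter/height, re-open gap and displacement), the
#' fluorescence timing offsets, anchor positions (minimum-separation
#' rejection sampling) and the invagination time. Uses the current RNG
#' stream; [generateDataset()] seeds it from the config.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame with one row per event.
#' @export
sampleEvents <- function(config) {
  n <- config@nEvents
  if (n == 0L) return(emptyEventTable())
  dt <- config@frameInterval
  nf <- config@nFrames
  geo <- config@geometryParams
  mix <- config@mixture
  pre <- motionPreset(config@preset)

  identity <- ifelse(stats::runif(n) < mix$ccp, "CCP", "caveola")
  isCCP <- identity == "CCP"

  lifetime <- sampleLifetimes(n, pre$lifetimeScale)
  lifetime[!isCCP] <- nf * dt + 2 * dt  # caveolae open past the movie end

  capping <- isCCP & stats::runif(n) < mix$capping
  # suppressed co-occurrence: re-opening drawn only among non-capping events,
  # rescaled so the overall re-open fraction matches the configured one
  pReGivenNotCap <- if (mix$capping < 1) min(1, mix$reopen / (1 - mix$capping)) else 0
  reopen <- isCCP & !capping & stats::runif(n) < pReGivenNotCap
  twoStep <- isCCP & stats::runif(n) < mix$two_step

  # re-open gap carved out of the total span so the tracked lifetime (first
  # detection -> final closure, gap included) keeps the configured mean
  gapS <- stats::runif(n, geo$reopenGapRange[1], geo$reopenGapRange[2])
  gapS <- pmin(gapS, pmax(lifetime - 4 * dt, geo$reopenGapRange[1]))
  gapFrames <- pmax(1L, as.integer(round(gapS / dt)))
  reopenDisp <- stats::runif(n, geo$reopenDisplacementRange[1],
                             geo$reopenDisplacementRange[2])
  retention <- rnormTrunc(n, geo$retentionMeanSd[1], geo$retentionMeanSd[2],
                          0.14, 0.70)

  # growing / stable / closing split of the open (aperture > 0) duration
  openDur <- ifelse(reopen, pmax(lifetime - gapFrames * dt, 4 * dt), lifetime)
  closing <- pmin(stats::runif(n, 20, 50), pmax(openDur - 40, 10))
  rem <- openDur - closing
  u <- stats::rbeta(n, 2, 2)
  growing <- ifelse(rem <= 40, rem, 40 + (pmin(rem - 40, 280 - 40)) * u)
  stable <- pmax(rem - growing, 0)
  over <- stable > 260
  growing[over] <- rem[over] - 260
  stable[over] <- 260

  apertureMax <- ifelse(isCCP,
                        stats::runif(n, geo$apertureRange[1], geo$apertureRange[2]),
                        stats::runif(n, geo$caveolaRange[1], geo$caveolaRange[2]))
  plateauDur <- if (!is.null(geo$plateauDurationRange))
    stats::runif(n, geo$plateauDurationRange[1], geo$plateauDurationRange[2])
  else stats::runif(n, 10, 40)
  plateauDia <- rnormTrunc(n, geo$plateauDiameter, geo$plateauDiameterSd,
                           100, 140)
  swellDia <- rnormTrunc(n, geo$swellingDiameter, geo$swellingDiameterSd,
                         200, 560)
  swellH <- rnormTrunc(n, geo$swellingHeight, geo$swellingHeightSd, 22, 70)
  swellAngle <- stats::runif(n, 0, 2 * pi)
  swellOffset <- 0.55 * swellDia / 2

  # clathrin timing offsets (rendered lifecycle channel)
  tp <- config@timingParams$clathrin
  offApp <- rnormTrunc(n, tp$app[1], tp$app[2], -90, -5)
  offPeak <- stats::rnorm(n, tp$peak[1], tp$peak[2])
  offDis <- pmax(rnormTrunc(n, tp$dis[1], tp$dis[2], 5, 90), offPeak + dt)

  span <- openDur + gapFrames * dt * reopen
  tR1 <- rep(NA_real_, n)
  firstOpen <- pmax(pmin(0.6 * openDur, openDur - 2 * dt), 2 * dt)

  # placement: events fully inside the movie (margin for the capping window)
  margin <- 4 * dt
  tInv <- numeric(n)
  for (i in seq_len(n)) {
    if (!isCCP[i]) { tInv[i] <- dt; next }
    lo <- margin + max(0, -offApp[i])
    hi <- nf * dt - span[i] - margin
    tInv[i] <- if (hi <= lo) lo else stats::runif(1, lo, hi)
  }
  tR1[reopen] <- tInv[reopen] + firstOpen[reopen]
  tCls <- tInv + span
  tCls[!isCCP] <- NA_real_

  # anchor positions with minimum separation
  px <- config@pixelSize
  xr <- c(-(config@gridShape[2] / 2) * px + 500, (config@gridShape[2] / 2) * px - 500)
  yr <- c(-(config@gridShape[1] / 2) * px + 500, (config@gridShape[1] / 2) * px - 500)
  ax <- numeric(n); ay <- numeric(n)
  minSep <- 900
  for (i in seq_len(n)) {
    cx <- stats::runif(1, xr[1], xr[2]); cy <- stats::runif(1, yr[1], yr[2])
    if (i > 1L) {
      for (tryi in seq_len(300)) {
        d2 <- (ax[seq_len(i - 1)] - cx)^2 + (ay[seq_len(i - 1)] - cy)^2
        if (min(d2) > minSep^2) break
        cx <- stats::runif(1, xr[1], xr[2]); cy <- stats::runif(1, yr[1], yr[2])
      }
    }
    ax[i] <- cx; ay[i] <- cy
  }

  data.frame(
    event = seq_len(n), identity = identity, lifetime = lifetime,
    tInv = tInv, tCls = tCls, tR1 = tR1, openDur = openDur,
    growing = growing, stable = stable, closing = closing,
    capping = capping, two_step = twoStep, reopen = reopen,
    gapFrames = ifelse(reopen, gapFrames, 0L),
    reopenDisp = ifelse(reopen, reopenDisp, NA_real_),
    retention = ifelse(reopen, retention, NA_real_),
    apertureMax = apertureMax,
    plateauDur = ifelse(twoStep, plateauDur, NA_real_),
    plateauDia = ifelse(twoStep, plateauDia, NA_real_),
    swellDia = ifelse(capping, swellDia, NA_real_),
    swellH = ifelse(capping, swellH, NA_real_),
    swellAngle = ifelse(capping, swellAngle, NA_real_),
    swellOffset = ifelse(capping, swellOffset, NA_real_),
    offApp = offApp, offPeak = offPeak, offDis = offDis,
    anchorX = ax, anchorY = ay,
    stringsAsFactors = FALSE
  )
}

emptyEventTable <- function() {
  data.frame(event = integer(), identity = character(), lifetime = numeric(),
             tInv = numeric(), tCls = numeric(), tR1 = numeric(),
             openDur = numeric(),
             growing = numeric(), stable = numeric(), closing = numeric(),
             capping = logical(), two_step = logical(), reopen = logical(),
             gapFrames = integer(), reopenDisp = numeric(),
             retention = numeric(), apertureMax = numeric(),
             plateauDur = numeric(), plateauDia = numeric(),
             swellDia = numeric(), swellH = numeric(), swellAngle = numeric(),
             swellOffset = numeric(), offApp = numeric(), offPeak = numeric(),
             offDis = numeric(), anchorX = numeric(), anchorY = numeric(),
             stringsAsFactors = FALSE)
}

## Aperture profile of one open interval. u = time since interval start,
## dur = interval duration; decline target for sudden (non-two-step) closure
## stays above the CCP class boundary so plain closures never mimic the
## small-aperture plateau.
aperturePhase <- function(u, dur, grow, stab, clos, amax, twoStep,
                          plateauDia, plateauDur, a0 = 150) {
  aa <- numeric(length(u))
  gEnd <- min(grow, dur)
  sEnd <- min(grow + stab, dur)
  ix <- u < gEnd
  aa[ix] <- a0 + (amax - a0) * (u[ix] / max(gEnd, 1e-9))
  ix <- u >= gEnd & u < sEnd
  aa[ix] <- amax
  ix <- u >= sEnd
  if (any(ix)) {
    uu <- u[ix]
    if (isTRUE(twoStep)) {
      pd <- min(plateauDur, dur - sEnd)
      declEnd <- max(dur - pd, sEnd)
      dec <- uu < declEnd
      aa[ix][dec] <- amax + (plateauDia - amax) *
        ((uu[dec] - sEnd) / max(declEnd - sEnd, 1e-9))
      aa[ix][!dec] <- plateauDia
    } else {
      # sudden (non-two-step) closure: the aperture narrows but never enters
      # the small-aperture band before vanishing
      endA <- max(200, 0.5 * amax)
      endA <- min(endA, amax)
      aa[ix] <- amax + (endA - amax) * ((uu - sEnd) / max(dur - sEnd, 1e-9))
    }
  }
  aa
}

## Aperture (nm) of one event (a one-row data.frame) at times t (seconds);
## NA when closed or not yet formed.
apertureAt <- function(ev, t, dt) {
  a <- rep(NA_real_, length(t))
  if (ev$identity == "caveola") {
    a[t >= ev$tInv] <- ev$apertureMax
    return(a)
  }
  if (isTRUE(ev$reopen) && ev$gapFrames > 0) {
    firstOpen <- ev$tR1 - ev$tInv
    t0b <- ev$tR1 + ev$gapFrames * dt
    durB <- ev$tCls - t0b
    open1 <- t >= ev$tInv & t < ev$tR1
    open2 <- t >= t0b & t < ev$tCls
    if (any(open1))
      a[open1] <- aperturePhase(t[open1] - ev$tInv, firstOpen, ev$growing,
                                ev$stable, ev$closing, ev$apertureMax,
                                FALSE, NA, NA)
    if (any(open2)) {
      amax2 <- min(ev$apertureMax, 250)
      g2 <- min(dt, durB / 3)
      s2 <- max(durB - g2 - 2 * dt, 0)
      a[open2] <- aperturePhase(t[open2] - t0b, durB, g2, s2, durB - g2 - s2,
                                amax2, isTRUE(ev$two_step), ev$plateauDia,
                                ev$plateauDur, a0 = 150)
    }
  } else {
    open <- t >= ev$tInv & t < ev$tCls
    if (any(open))
      a[open] <- aperturePhase(t[open] - ev$tInv, ev$tCls - ev$tInv,
                               ev$growing, ev$stable, ev$closing,
                               ev$apertureMax, isTRUE(ev$two_step),
                               ev$plateauDia, ev$plateauDur)
  }
  a
}
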