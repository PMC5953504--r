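## End-to-end synthetic acquisition.

## Swelling amplitude fraction over time for a capping event: the adjacent
## membrane swells starting ~2 frames before closure, peaks one frame after
## closure (covering the former pit), and subsides by +3 frames.
swellingAmpFrac <- function(t, tCls, dt) {
  evalKnots(c(tCls - dt, tCls, tCls + dt, tCls + 2 * dt, tCls + 3 * dt),
            c(0, 0.12, 1, 1, 0.2), t) *
    as.numeric(t > tCls - dt - 1e-9 & t < tCls + 3 * dt + 1e-9)
}

#' Generate a complete synthetic hybrid acquisition
#'
#' Draws events from the configured mixture and kinetics, renders the AFM
#' height stack (background roughness field, raised-cosine pits and capping
#' swellings, confined Brownian wander plus stage drift, spherical-cap tip
#' dilation, per-frame sensor noise, tip-skip/amplitude artifacts, z-DAC
#' quantization) and the fluorescence stacks (Gaussian-PSF spots following
#' the per-event traces, with the AFM-vs-confocal scan-time lag, Poisson
#' photon noise and Gaussian read noise), and returns everything together
#' with the per-event / per-frame ground truth. Fully deterministic given
#' `config@seed`.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{MovieBundle}.
#' @examples
#' cfg <- simulationConfig(nEvents = 2L, nFrames = 30L, seed = 7L)
#' b <- generateDataset(cfg)
#' @export
generateDataset <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  dt <- config@frameInterval
  nf <- config@nFrames
  gs <- config@gridShape
  geo <- config@geometryParams

  events <- sampleEvents(config)
  n <- nrow(events)
  background <- makeRoughnessField(config)

  # cumulative stage drift (nm), frame 1 = 0
  drift <- cbind((seq_len(nf) - 1) * config@driftVelocity[1],
                 (seq_len(nf) - 1) * config@driftVelocity[2])
  colnames(drift) <- c("x", "y")

  # per-event confined wander and traces
  wander <- vector("list", n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    D <- if (events$identity[i] == "CCP") config@mobility$ccp else
      config@mobility$caveola
    wander[[i]] <- sampleTrajectory(D, c(0, 0), nf, dt,
                                    confinementRadius = config@mobility$confinementRadius)
    ch <- if (events$identity[i] == "CCP") "clathrin" else "caveolin"
    traces[[i]] <- synthesizeTrace(events[i, ], ch, config@timingParams, nf, dt)
  }
  lag <- stats::runif(1, 0, dt)   # AFM-vs-confocal scan start offset

  # ground-truth per-frame table
  tt <- seq_len(nf) * dt
  pf <- vector("list", n)
  peakSwellFrame <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ev <- events[i, ]
    ap <- apertureAt(ev, tt, dt)
    tr <- as.numeric(traces[[i]])
    alive <- which(!is.na(ap) | tr > 1e-6)
    if (!length(alive)) next
    x <- ev$anchorX + wander[[i]][alive, 1] + drift[alive, 1]
    y <- ev$anchorY + wander[[i]][alive, 2] + drift[alive, 2]
    sw <- rep(NA_real_, length(alive)); swx <- swy <- swd <- sw
    if (isTRUE(ev$capping)) {
      frac <- swellingAmpFrac(tt[alive], ev$tCls, dt)
      act <- frac > 1e-6
      sw[act] <- frac[act] * ev$swellH
      swx[act] <- x[act] + cos(ev$swellAngle) * ev$swellOffset
      swy[act] <- y[act] + sin(ev$swellAngle) * ev$swellOffset
      swd[act] <- ev$swellDia
      peakSwellFrame[i] <- alive[which.max(frac)]
    }
    pf[[i]] <- data.frame(event = ev$event, frame = alive, t = tt[alive],
                          x = x, y = y, aperture = ap[alive],
                          open = !is.na(ap[alive]),
                          swellX = swx, swellY = swy, swellDia = swd,
                          swellAmp = sw, trace = tr[alive],
                          stringsAsFactors = FALSE)
  }
  perFrame <- if (length(pf)) do.call(rbind, pf) else
    data.frame(event = integer(), frame = integer(), t = numeric(),
               x = numeric(), y = numeric(), aperture = numeric(),
               open = logical(), swellX = numeric(), swellY = numeric(),
               swellDia = numeric(), swellAmp = numeric(), trace = numeric())
  events$peakSwellFrame <- peakSwellFrame
  events$timeLag <- if (n) rep(lag, n) else numeric(0)

  # AFM stack
  frames <- array(0, c(gs[1], gs[2], nf))
  alog <- data.frame(frame = integer(), row = integer(), width = integer(),
                     type = character(), stringsAsFactors = FALSE)
  for (k in seq_len(nf)) {
    rows <- perFrame[perFrame$frame == k, , drop = FALSE]
    feat <- if (nrow(rows)) data.frame(
      x = rows$x, y = rows$y, aperture = rows$aperture,
      swellX = rows$swellX, swellY = rows$swellY,
      swellDia = rows$swellDia, swellAmp = rows$swellAmp) else NULL
    z <- renderHeightFrame(feat, config, background)
    if (config@noise$sigmaFrame > 0)
      z <- z + matrix(stats::rnorm(length(z), 0, config@noise$sigmaFrame),
                      gs[1], gs[2])
    z <- applyTipConvolution(z, config@tipRadius, config@pixelSize)
    inj <- injectScanArtifacts(z, config@artifactRates)
    z <- inj$frame
    if (nrow(inj$log))
      alog <- rbind(alog, cbind(frame = k, inj$log))
    frames[, , k] <- quantizeHeights(z)
  }

  # fluorescence stacks (positions sampled at t + lag, linear interpolation
  # between frame positions, plus any configured misregistration)
  grid <- opticalGrid(config)
  mis <- geo$misregistration
  channels <- stats::setNames(
    lapply(config@channels, function(ch) array(0, c(grid$rows, grid$cols, nf))),
    config@channels)
  for (k in seq_len(nf)) {
    frac <- lag / dt
    for (ch in config@channels) {
      spots <- NULL
      for (i in seq_len(n)) {
        want <- (ch == "clathrin" && events$identity[i] == "CCP") ||
                (ch == "caveolin" && events$identity[i] == "caveola")
        if (!want) next
        tr <- as.numeric(traces[[i]])
        a1 <- tr[k]; a2 <- if (k < nf) tr[k + 1] else a1
        amp <- a1 + (a2 - a1) * frac
        if (amp <= 1e-6) next
        w1 <- wander[[i]][k, ]; w2 <- if (k < nf) wander[[i]][k + 1, ] else w1
        d1 <- drift[k, ]; d2 <- if (k < nf) drift[k + 1, ] else d1
        pos <- (1 - frac) * (w1 + d1) + frac * (w2 + d2)
        spots <- rbind(spots, data.frame(
          x = events$anchorX[i] + pos[1] + mis[1],
          y = events$anchorY[i] + pos[2] + mis[2], amp = amp))
      }
      channels[[ch]][, , k] <- renderFluorFrame(spots, config, grid)
    }
  }

  ex <- gs[2] * config@pixelSize; ey <- gs[1] * config@pixelSize
  corners <- rbind(c(-ex / 2, ey / 2), c(ex / 2, ey / 2),
                   c(ex / 2, -ey / 2), c(-ex / 2, -ey / 2))
  height <- new("HeightMovie", frames = frames, frameInterval = dt,
                geometry = scanGeometry(corners = corners,
                                        afmPixelSize = config@pixelSize,
                                        opticalPixelSize = grid$pixelSize,
                                        probeOrigin = c((grid$cols + 1) / 2,
                                                        (grid$rows + 1) / 2)),
                artifactLog = alog)
  fluor <- new("FluorMovie", channels = channels, frameInterval = dt,
               pixelSize = grid$pixelSize)
  truth <- new("GroundTruth", events = events, perFrame = perFrame,
               drift = drift, artifactLog = alog)
  new("MovieBundle", height = height, fluor = fluor, truth = truth,
      config = config)
}
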