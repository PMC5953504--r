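## Phase segmentation of fluorescence traces and relative protein timing.

#' PhaseSegmentation result container
#'
#' @slot stableStart,stableEnd frame indices of the stable phase (NA when no
#'   qualifying run exists).
#' @slot growing,stable,closing durations in seconds.
#' @slot smoothed smoothed trace.
#' @slot slope per-frame slope series.
#' @slot signalStart,signalEnd first/last frame with signal.
#' @export
setClass("PhaseSegmentation", representation(
  stableStart = "integer", stableEnd = "integer",
  growing = "numeric", stable = "numeric", closing = "numeric",
  smoothed = "numeric", slope = "numeric",
  signalStart = "integer", signalEnd = "integer"
))

setMethod("show", "PhaseSegmentation", function(object) {
  cat(sprintf("PhaseSegmentation: growing %.0f s | stable %.0f s | closing %.0f s%s\n",
              object@growing, object@stable, object@closing,
              if (is.na(object@stableStart)) " (no stable run; split at peak)" else ""))
})

#' Segment a normalized intensity trace into growing / stable / closing
#'
#' The trace (max-normalized) is smoothed with a 3-frame centered moving
#' average (window shrinking at the edges); the slope is the central
#' difference of the smoothed trace (one-sided at the edges). The stable
#' phase is the earliest run of at least 5 consecutive frames with slope in
#' [-0.05, +0.1] per frame; growing runs from signal start to stable start
#' and closing from stable end to signal end. When no run qualifies the
#' stable phase is empty and growing/closing split at the smoothed argmax.
#'
#' @param trace numeric intensity trace (any positive scale; normalized
#'   internally).
#' @param dt frame interval, seconds.
#' @param slopeBounds slope window in normalized units per frame.
#' @param minRun minimum qualifying run length in frames.
#' @param signalThreshold fraction of the maximum below which frames are
#'   treated as signal-free (guards the run search against noise floors).
#' @return a \linkS4class{PhaseSegmentation}.
#' @export
segmentPhases <- function(trace, dt, slopeBounds = c(-0.05, 0.1),
                          minRun = 5L, signalThreshold = 0.05) {
  trace <- as.numeric(trace)
  if (length(trace) < 6L)
    stop("trace too short to segment (need >= 6 frames)", call. = FALSE)
  m <- max(trace)
  if (m <= 0) stop("no-signal: all-zero trace", call. = FALSE)
  x <- trace / m
  sig <- which(x > signalThreshold)
  i0 <- sig[1]; i1 <- sig[length(sig)]
  sm <- movingAverage(x, 1L)
  sl <- centralSlope(sm)
  inBand <- sl >= slopeBounds[1] & sl <= slopeBounds[2]
  # restrict to the signal interval
  inBand[seq_len(length(x)) < i0 | seq_len(length(x)) > i1] <- FALSE
  r <- rle(inBand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  q <- which(r$values & r$lengths >= minRun)
  if (length(q)) {
    ss <- starts[q[1]]; se <- ends[q[1]]
    growing <- (ss - i0) * dt
    stable <- (se - ss + 1L) * dt
    closing <- (i1 - se) * dt
  } else {
    pk <- which.max(sm)
    ss <- NA_integer_; se <- NA_integer_
    growing <- (pk - i0) * dt
    stable <- 0
    closing <- (i1 - pk + 1L) * dt   # peak frame counted into closing
  }
  new("PhaseSegmentation", stableStart = as.integer(ss),
      stableEnd = as.integer(se), growing = growing, stable = stable,
      closing = closing, smoothed = sm, slope = sl,
      signalStart = as.integer(i0), signalEnd = as.integer(i1))
}

#' AFM anchor times of a track: invagination start and complete closure
#'
#' t0_invagination is the time of the first frame of the first run of at
#' least `confirmFrames` consecutive detections; t0_closure is the time of
#' the first frame with no detection after the final detection (censored
#' when the track reaches the last movie frame). Frame k is timestamped
#' t = k * dt.
#'
#' @param track one track's points (column frame).
#' @param dt frame interval, s.
#' @param nFramesTotal movie length in frames.
#' @param confirmFrames detector confirmation run length.
#' @return list(t0Invagination, t0Closure, censored).
#' @export
detectEventTimes <- function(track, dt, nFramesTotal, confirmFrames = 2L) {
  fr <- sort(unique(track$frame))
  if (length(fr) < 2L)
    stop("track must have >= 2 detections", call. = FALSE)
  consec <- c(diff(fr) == 1L, FALSE)
  r <- rle(consec)
  # first run of >= confirmFrames consecutive frames
  t0 <- NA_real_
  run <- 1L
  i <- 1L
  while (i <= length(fr)) {
    j <- i
    while (j < length(fr) && fr[j + 1] == fr[j] + 1L) j <- j + 1L
    if (j - i + 1L >= confirmFrames) { t0 <- fr[i] * dt; break }
    i <- j + 1L
  }
  last <- fr[length(fr)]
  censored <- last >= nFramesTotal
  t0c <- if (censored) NA_real_ else (last + 1L) * dt
  list(t0Invagination = t0, t0Closure = t0c, censored = censored)
}

#' Extract a background-subtracted spot intensity trace from a movie
#'
#' Per frame, the spot intensity is the mean count in a disc of
#' `spotRadius` optical pixels around the event position and the background
#' is estimated (median and SD) in an annulus between `spotRadius + 1` and
#' `bgRadius`.
#'
#' @param fluor a \linkS4class{FluorMovie}.
#' @param channel channel name.
#' @param positions n_frames x 2 matrix of (x, y) nm positions (the tracked
#'   or anchor position per frame).
#' @param transform a \linkS4class{RegistrationTransform}.
#' @param spotRadius,bgRadius radii in optical pixels.
#' @return data.frame: frame, raw, bgMean, bgSd, net.
#' @export
extractTrace <- function(fluor, channel, positions, transform,
                         spotRadius = 2, bgRadius = 6) {
  arr <- fluor@channels[[channel]]
  if (is.null(arr)) stop("unknown channel '", channel, "'", call. = FALSE)
  nf <- dim(arr)[3]
  out <- data.frame(frame = seq_len(nf), raw = NA_real_, bgMean = NA_real_,
                    bgSd = NA_real_, net = NA_real_)
  for (k in seq_len(nf)) {
    p <- positions[min(k, nrow(positions)), ]
    if (any(is.na(p))) next
    px <- fromCommon(transform, p, "optical")
    cc <- px[1]; rr <- px[2]
    nr <- nrow(arr[, , k]); ncol_ <- ncol(arr[, , k])
    cs <- max(1, floor(cc - bgRadius)):min(ncol_, ceiling(cc + bgRadius))
    rs <- max(1, floor(rr - bgRadius)):min(nr, ceiling(rr + bgRadius))
    if (length(cs) < 3 || length(rs) < 3) next
    d2 <- outer((rs - rr)^2, (cs - cc)^2, "+")
    win <- arr[rs, cs, k]
    spot <- d2 <= spotRadius^2
    annul <- d2 > (spotRadius + 1)^2 & d2 <= bgRadius^2
    if (!any(spot) || sum(annul) < 5) next
    out$raw[k] <- mean(win[spot])
    out$bgMean[k] <- stats::median(win[annul])
    out$bgSd[k] <- stats::sd(win[annul])
    out$net[k] <- out$raw[k] - out$bgMean[k]
  }
  out
}

#' Appearance, peak and disappearance times of a channel at one event
#'
#' Appearance is the first of at least 2 consecutive frames with raw spot
#' intensity above background mean + `kSigma` * background SD;
#' disappearance is the symmetric time after the last such run; the peak is
#' the argmax of the 3-frame-smoothed net trace. Offsets are reported
#' against both anchors.
#'
#' @param traceTable data.frame from [extractTrace()].
#' @param times list from [detectEventTimes()] (or truth equivalents with
#'   elements t0Invagination, t0Closure).
#' @param dt frame interval, s.
#' @param kSigma detection threshold in background SDs.
#' @return data.frame with appearance_s, peak_s, disappearance_s and offsets
#'   vs both anchors, or NULL when the channel never exceeds threshold.
#' @export
relativeTiming <- function(traceTable, times, dt, kSigma = 3) {
  ok <- !is.na(traceTable$raw)
  above <- ok & traceTable$raw > traceTable$bgMean + kSigma * traceTable$bgSd
  r <- rle(as.vector(above))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 2L)
  if (!length(runs)) return(NULL)   # channel absent
  appF <- starts[runs[1]]
  disF <- ends[runs[length(runs)]] + 1L
  net <- ifelse(is.na(traceTable$net), 0, traceTable$net)
  pkF <- which.max(movingAverage(net, 1L))
  app <- appF * dt; dis <- disF * dt; pk <- pkF * dt
  data.frame(appearance_s = app, peak_s = pk, disappearance_s = dis,
             app_vs_invagination = app - times$t0Invagination,
             peak_vs_closure = pk - times$t0Closure,
             dis_vs_closure = dis - times$t0Closure)
}
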