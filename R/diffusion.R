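## Specimen-drift estimation and MSD-based diffusion coefficients.

#' DriftEstimate: cumulative specimen drift over the movie
#'
#' @slot perFrame n_frames x 2 matrix of cumulative drift (nm), first row 0.
#' @slot method "ensemble" (per-frame-pair mean displacement) or
#'   "first-last" (the initial-vs-final average displacement of all pits,
#'   spread linearly).
#' @slot nTracks contributing tracks.
#' @slot net terminal drift vector (nm).
#' @export
setClass("DriftEstimate", representation(
  perFrame = "matrix", method = "character", nTracks = "integer",
  net = "numeric"
))

setMethod("show", "DriftEstimate", function(object) {
  cat(sprintf("DriftEstimate (%s, %d tracks): net (%.1f, %.1f) nm, |d| = %.1f nm\n",
              object@method, object@nTracks, object@net[1], object@net[2],
              sqrt(sum(object@net^2))))
})

#' MSDCurve: time-averaged mean squared displacement vs lag
#'
#' @slot lag lag times (s), starting at 0.
#' @slot msd nm^2.
#' @slot n pair counts per lag.
#' @export
setClass("MSDCurve", representation(
  lag = "numeric", msd = "numeric", n = "integer"
))

setValidity("MSDCurve", function(object) {
  if (any(diff(object@lag) <= 0)) return("lags must be strictly increasing")
  if (any(object@msd < 0)) return("MSD must be >= 0")
  if (object@lag[1] == 0 && object@msd[1] != 0) return("MSD(0) must be 0")
  TRUE
})

#' DiffusionEstimate: fitted diffusion coefficient
#'
#' @slot D cm^2/s (truncated at 0; negative-slope fits are flagged).
#' @slot se standard error (cm^2/s).
#' @slot lagsUsed number of lags fitted.
#' @slot identityClass identity class label.
#' @slot flagged TRUE when the raw slope was negative.
#' @export
setClass("DiffusionEstimate", representation(
  D = "numeric", se = "numeric", lagsUsed = "integer", identityClass = "character",
  flagged = "logical"
))

setMethod("show", "DiffusionEstimate", function(object) {
  cat(sprintf("DiffusionEstimate [%s]: D = %.3g cm^2/s (SE %.2g, %d lags)%s\n",
              object@identityClass, object@D, object@se, object@lagsUsed,
              if (object@flagged) " [negative slope truncated]" else ""))
})

#' Estimate specimen drift from the track ensemble
#'
#' `method = "ensemble"`: for every consecutive frame pair, the mean
#' displacement of all tracks present in both frames, accumulated into a
#' cumulative per-frame series (frames with no spanning track inherit the
#' previous increment of zero). `method = "first-last"`: the average
#' displacement of all tracks between their initial and final frames,
#' normalized per frame and spread linearly — the randomly diffusing pits
#' average to zero, so what remains is the stage drift.
#'
#' @param tracks data.frame (event_id, frame, x, y).
#' @param nFramesTotal movie length in frames.
#' @param method "ensemble" or "first-last".
#' @return a \linkS4class{DriftEstimate}.
#' @export
estimateDrift <- function(tracks, nFramesTotal,
                          method = c("ensemble", "first-last")) {
  method <- match.arg(method)
  sp <- split(tracks, tracks$event_id)
  sp <- sp[vapply(sp, nrow, 1L) >= 2L]
  if (!length(sp))
    stop("insufficient-data: no track spans two frames", call. = FALSE)
  per <- matrix(0, nFramesTotal, 2)
  if (method == "ensemble") {
    sumd <- matrix(0, nFramesTotal - 1L, 2)
    cnt <- integer(nFramesTotal - 1L)
    for (d in sp) {
      d <- d[order(d$frame), ]
      i <- which(diff(d$frame) == 1L)
      if (!length(i)) next
      k <- d$frame[i]
      sumd[k, 1] <- sumd[k, 1] + (d$x[i + 1] - d$x[i])
      sumd[k, 2] <- sumd[k, 2] + (d$y[i + 1] - d$y[i])
      cnt[k] <- cnt[k] + 1L
    }
    inc <- sumd
    inc[cnt > 0, 1] <- sumd[cnt > 0, 1] / cnt[cnt > 0]
    inc[cnt > 0, 2] <- sumd[cnt > 0, 2] / cnt[cnt > 0]
    inc[cnt == 0, ] <- 0
    per[2:nFramesTotal, 1] <- cumsum(inc[, 1])
    per[2:nFramesTotal, 2] <- cumsum(inc[, 2])
  } else {
    disp <- t(vapply(sp, function(d) {
      d <- d[order(d$frame), ]
      n <- nrow(d)
      span <- d$frame[n] - d$frame[1]
      c(d$x[n] - d$x[1], d$y[n] - d$y[1], span)
    }, numeric(3)))
    disp <- disp[disp[, 3] > 0, , drop = FALSE]
    rate <- colMeans(disp[, 1:2, drop = FALSE] / disp[, 3])
    per[, 1] <- (seq_len(nFramesTotal) - 1L) * rate[1]
    per[, 2] <- (seq_len(nFramesTotal) - 1L) * rate[2]
  }
  new("DriftEstimate", perFrame = per, method = method,
      nTracks = length(sp), net = per[nFramesTotal, ] - per[1, ])
}

#' Time-averaged MSD of one drift-corrected track
#'
#' Drift is subtracted per frame; the MSD at each lag averages over all
#' ordered detection pairs separated by that lag (pairs with a missing
#' endpoint — gaps — are excluded).
#'
#' @param track data.frame (frame, x, y).
#' @param drift a \linkS4class{DriftEstimate} or NULL.
#' @param dt frame interval, s.
#' @param maxLag maximum lag in frames (default all).
#' @return an \linkS4class{MSDCurve}.
#' @export
computeMSD <- function(track, drift = NULL, dt, maxLag = NULL) {
  if (nrow(track) < 2L)
    stop("insufficient-data: need >= 2 detections", call. = FALSE)
  d <- track[order(track$frame), ]
  x <- d$x; y <- d$y
  if (!is.null(drift)) {
    x <- x - drift@perFrame[d$frame, 1]
    y <- y - drift@perFrame[d$frame, 2]
  }
  fr <- d$frame
  span <- max(fr) - min(fr)
  if (is.null(maxLag)) maxLag <- span
  lags <- seq_len(min(maxLag, span))
  msd <- numeric(length(lags)); n <- integer(length(lags))
  pos <- rep(NA_real_, max(fr) - min(fr) + 1L)
  ix <- fr - min(fr) + 1L
  px <- pos; px[ix] <- x
  py <- pos; py[ix] <- y
  for (li in seq_along(lags)) {
    l <- lags[li]
    dx <- px[-(seq_len(l))] - px[seq_len(length(px) - l)]
    dy <- py[-(seq_len(l))] - py[seq_len(length(py) - l)]
    ok <- !is.na(dx)
    n[li] <- sum(ok)
    msd[li] <- if (n[li]) mean(dx[ok]^2 + dy[ok]^2) else NA_real_
  }
  keep <- n > 0
  new("MSDCurve", lag = c(0, lags[keep] * dt), msd = c(0, msd[keep]),
      n = c(0L, n[keep]))
}

#' Pool per-track MSDs into an ensemble curve
#'
#' @param tracks track table (event_id, frame, x, y).
#' @param drift a \linkS4class{DriftEstimate} or NULL.
#' @param dt frame interval, s.
#' @param maxLag maximum lag in frames.
#' @param minFrames tracks with fewer detections are excluded.
#' @return an \linkS4class{MSDCurve} (pair-count weighted).
#' @export
ensembleMSD <- function(tracks, drift = NULL, dt, maxLag = 4L, minFrames = 5L) {
  sp <- split(tracks, tracks$event_id)
  sp <- sp[vapply(sp, nrow, 1L) >= minFrames]
  if (!length(sp)) stop("insufficient-data: no usable tracks", call. = FALSE)
  acc <- matrix(0, maxLag, 2)  # sum, count
  for (d in sp) {
    m <- tryCatch(computeMSD(d, drift, dt, maxLag), error = function(e) NULL)
    if (is.null(m)) next
    for (li in seq_along(m@lag)) {
      if (m@lag[li] == 0) next
      l <- as.integer(round(m@lag[li] / dt))
      if (l >= 1 && l <= maxLag) {
        acc[l, 1] <- acc[l, 1] + m@msd[li] * m@n[li]
        acc[l, 2] <- acc[l, 2] + m@n[li]
      }
    }
  }
  keep <- acc[, 2] > 0
  new("MSDCurve", lag = c(0, (seq_len(maxLag) * dt)[keep]),
      msd = c(0, (acc[keep, 1] / acc[keep, 2])),
      n = c(0L, as.integer(acc[keep, 2])))
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Unweighted zero-intercept least squares through the first `nLags`
#' nonzero-lag points: MSD = 4 D t, so D = slope / 4, converted to cm^2/s.
#' A negative slope is truncated to D = 0 and flagged.
#'
#' @param msd an \linkS4class{MSDCurve}.
#' @param nLags number of lags to fit.
#' @param minCount minimum pair count per fitted lag.
#' @param class identity label carried into the estimate.
#' @return a \linkS4class{DiffusionEstimate}.
#' @export
fitDiffusion <- function(msd, nLags = 4L, minCount = 10L, class = "CCP") {
  ix <- which(msd@lag > 0)
  if (length(ix) < nLags)
    stop("insufficient counts: fewer than nLags usable lags", call. = FALSE)
  ix <- ix[seq_len(nLags)]
  if (any(msd@n[ix] < minCount))
    stop("insufficient counts: lag with fewer than ", minCount, " pairs",
         call. = FALSE)
  t <- msd@lag[ix]; y <- msd@msd[ix]
  slope <- sum(t * y) / sum(t^2)
  resid <- y - slope * t
  seSlope <- if (nLags > 1)
    sqrt(sum(resid^2) / (nLags - 1) / sum(t^2)) else NA_real_
  flagged <- slope < 0
  D <- max(slope, 0) / 4 * CM2_PER_NM2
  new("DiffusionEstimate", D = D, se = seSlope / 4 * CM2_PER_NM2,
      lagsUsed = as.integer(nLags), identityClass = class, flagged = flagged)
}
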