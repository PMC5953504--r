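## Terminal closing-motion classification: capping, two-step, re-opening.

## Classification threshold separating the small-aperture (two-step plateau)
## band from the large-aperture CCP band. The nominal boundary is 150 nm
## (the CCP minimum); because the edge walk reports the first sample at or
## beyond the baseline crossing, a plateau touching 140 nm legitimately
## reads one sample pitch wider, so the implemented boundary carries half a
## pixel of guard band above 150.
twoStepThreshold <- function(pixelSize = 18.75) 150 + pixelSize / 2

#' Detect a covering membrane swelling around a closing pit
#'
#' Searches the frames around closure (default +/- 3) within 1.5 x the last
#' pit diameter of the final pit position for a positive membrane feature at
#' least `minHeight` high and `minDiameter` wide (section-profile
#' measurements). The swelling qualifies as "covering" when its footprint
#' overlaps the former pit centroid in any frame at or after closure.
#'
#' @param movie a \linkS4class{HeightMovie}.
#' @param track one track's points (frame, x, y, diameter).
#' @param windowFrames frames around closure to search.
#' @param minHeight,minDiameter qualification thresholds (nm).
#' @param staticBg optional static background subtracted before measurement.
#' @return data.frame(frame, x, y, diameter, height, covers) for the
#'   highest qualifying frame, or NULL when none qualifies.
#' @export
detectSwelling <- function(movie, track, windowFrames = 3L,
                           minHeight = 20, minDiameter = 150,
                           staticBg = NULL) {
  px <- movie@geometry@afmPixelSize
  nf <- nFrames(movie)
  lastF <- max(track$frame)
  closure <- lastF + 1L
  i <- which.max(track$frame)
  cx <- track$x[i]; cy <- track$y[i]
  lastDia <- track$diameter[i]
  if (is.na(lastDia)) lastDia <- 200
  searchR <- 1.5 * lastDia
  frames <- max(1L, closure - windowFrames):min(nf, closure + windowFrames)
  best <- NULL
  for (k in frames) {
    z <- measurementFrame(movie@frames[, , k], staticBg, cx, cy, px)
    ctr <- afmPixelCenters(dim(z), px)
    ci <- which(abs(ctr$x - cx) <= searchR + 200)
    ri <- which(abs(ctr$y - cy) <= searchR + 200)
    if (length(ci) < 5 || length(ri) < 5) next
    sub <- z[ri, ci, drop = FALSE]
    base <- stats::median(sub)
    inR <- sqrt(outer((ctr$y[ri] - cy)^2, (ctr$x[ci] - cx)^2, "+")) <= searchR
    vals <- sub; vals[!inR] <- -Inf
    m <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    if (sub[m[1], m[2]] - base < minHeight * 0.75) next
    sx <- ctr$x[ci[m[2]]]; sy <- ctr$y[ri[m[1]]]
    hl <- max(450, 1.5 * minDiameter)
    h <- sectionHeight(z, c(sx, sy), px, halfLength = hl)
    d <- sectionDiameter(z, c(sx, sy), px, halfLength = hl,
                         depthMin = minHeight * 0.75, feature = "peak")
    if (is.na(h) || is.na(d)) next
    rec <- data.frame(frame = k, x = sx, y = sy, diameter = d, height = h,
                      covers = sqrt((sx - cx)^2 + (sy - cy)^2) <= d / 2 &&
                        k >= closure)
    if (rec$height < minHeight || rec$diameter < minDiameter) next
    covers <- rec$covers
    if (is.null(best)) best <- rec else {
      if (rec$height > best$height) { c0 <- best$covers; best <- rec
                                      best$covers <- best$covers || c0 }
      else best$covers <- best$covers || covers
    }
  }
  best
}

#' Classify the terminal closing motion of one closed track
#'
#' Labels: `capping` when a covering swelling was found; `two_step` when at
#' least one frame immediately before final closure has a small-aperture
#' diameter (below the two-step threshold, >= 60 nm) preceded by at least 2
#' frames in the large-aperture band; `reopen` when the track contains a
#' closed-gap interval of 1-7 frames (gap closing already bounds the re-open
#' displacement); `plain` otherwise.
#'
#' @param track one track's points with per-frame `diameter`.
#' @param gaps closed-gap intervals for this track (from [linkTracks()]).
#' @param swelling swelling record from [detectSwelling()] (or NULL).
#' @param dt frame interval, s.
#' @param nFramesTotal movie length (frames).
#' @param trace optional net intensity trace (for the re-open retention
#'   fraction).
#' @param pixelSize AFM pixel size (sets the class boundary).
#' @return one-row data.frame annotation.
#' @export
classifyClosing <- function(track, gaps = NULL, swelling = NULL, dt,
                            nFramesTotal, trace = NULL, pixelSize = 18.75) {
  lastF <- max(track$frame)
  if (lastF >= nFramesTotal)
    stop("not-classifiable: track does not close within the movie", call. = FALSE)
  thr <- twoStepThreshold(pixelSize)
  ord <- order(track$frame)
  fr <- track$frame[ord]; dia <- track$diameter[ord]

  capping <- !is.null(swelling) && isTRUE(swelling$covers)

  # plateau: terminal run of small-aperture frames before final closure,
  # tolerating one isolated large-reading frame inside the run (one-pixel
  # measurement noise at the class boundary)
  small <- !is.na(dia) & dia < thr & dia >= 60
  idx <- integer(); i <- length(dia); tol <- 0L
  while (i >= 1L) {
    if (small[i]) { idx <- c(i, idx); i <- i - 1L }
    else if (tol == 0L && i > 1L && small[i - 1L] && length(idx)) {
      tol <- 1L; i <- i - 1L
    } else break
  }
  nLargeBefore <- 0L
  while (i >= 1L && !is.na(dia[i]) && dia[i] >= thr) {
    nLargeBefore <- nLargeBefore + 1L; i <- i - 1L
  }
  twoStep <- length(idx) >= 1L && nLargeBefore >= 2L
  plateauFrames <- if (twoStep) fr[idx] else integer()
  nrun <- length(plateauFrames)
  plateauMedian <- if (twoStep) stats::median(dia[idx]) else NA_real_

  reopen <- !is.null(gaps) && nrow(gaps) > 0 &&
    any(gaps$gapEnd - gaps$gapStart + 1L <= 7L)
  gapDur <- if (reopen) (gaps$gapEnd[1] - gaps$gapStart[1] + 1L) * dt else NA_real_
  gapDisp <- if (reopen) gaps$displacement[1] else NA_real_
  retention <- NA_real_
  if (reopen && !is.null(trace)) {
    gapIdx <- gaps$gapStart[1]:gaps$gapEnd[1]
    gapIdx <- gapIdx[gapIdx >= 1 & gapIdx <= length(trace)]
    if (length(gapIdx) && max(trace, na.rm = TRUE) > 0)
      retention <- min(trace[gapIdx], na.rm = TRUE) / max(trace, na.rm = TRUE)
  }

  # closing duration: diameter decline onset -> final closure
  maxDia <- max(dia, na.rm = TRUE)
  big <- which(!is.na(dia) & dia >= 0.9 * maxDia)
  onset <- if (length(big)) fr[max(big)] else fr[1]
  closingDur <- ((lastF + 1L) - onset) * dt

  labels <- c(if (capping) "capping", if (twoStep) "two_step",
              if (reopen) "reopen")
  if (!length(labels)) labels <- "plain"
  data.frame(
    event_id = track$event_id[1], labels = paste(labels, collapse = "+"),
    capping = capping, two_step = twoStep, reopen = reopen,
    plain = identical(labels, "plain"),
    swellDiameter = if (capping) swelling$diameter else NA_real_,
    swellHeight = if (capping) swelling$height else NA_real_,
    plateauMedianDia = plateauMedian, plateauFrames = nrun,
    reopenGap_s = gapDur, reopenDisp_nm = gapDisp, retention = retention,
    closing_s = closingDur, stringsAsFactors = FALSE
  )
}

#' Summarize closing-motion annotations
#'
#' @param annotations data.frame of [classifyClosing()] rows.
#' @param lifetimes optional data.frame (event_id, lifetime_s) to attach
#'   per-label lifetime distributions.
#' @param condition optional condition label carried into the output.
#' @return list with counts, percentages, the capping x re-open cross-tab
#'   (with odds ratio), per-label lifetimes and the two-step
#'   large/small-aperture duration table.
#' @export
motionSummary <- function(annotations, lifetimes = NULL, condition = NA) {
  if (is.null(annotations) || !nrow(annotations))
    stop("empty input: no annotations to summarize", call. = FALSE)
  n <- nrow(annotations)
  counts <- c(capping = sum(annotations$capping),
              two_step = sum(annotations$two_step),
              reopen = sum(annotations$reopen),
              plain = sum(annotations$plain))
  pct <- 100 * counts / n
  ct <- table(factor(annotations$capping, c(FALSE, TRUE)),
              factor(annotations$reopen, c(FALSE, TRUE)),
              dnn = c("capping", "reopen"))
  orNum <- (ct[2, 2] + 0.5) * (ct[1, 1] + 0.5) /
    ((ct[2, 1] + 0.5) * (ct[1, 2] + 0.5))
  lifeByLabel <- NULL
  if (!is.null(lifetimes)) {
    m <- merge(annotations, lifetimes, by = "event_id")
    lifeByLabel <- lapply(c("capping", "two_step", "reopen", "plain"),
                          function(l) m$lifetime_s[m[[l]]])
    names(lifeByLabel) <- c("capping", "two_step", "reopen", "plain")
  }
  ts <- annotations[annotations$two_step, , drop = FALSE]
  apertureDurations <- data.frame(
    event_id = ts$event_id,
    small_s = ts$plateauFrames * NA_real_,
    stringsAsFactors = FALSE)
  if (nrow(ts)) apertureDurations$small_s <- ts$plateauFrames
  list(condition = condition, n = n, counts = counts, percentages = pct,
       crossTab = ct, cappingReopenOddsRatio = unname(orNum),
       lifetimesByLabel = lifeByLabel, twoStepPlateauFrames = apertureDurations)
}
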