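## Frame-to-frame linking of pit detections into event tracks.

#' Link per-frame detections into pit tracks with gap closing
#'
#' Greedy nearest-neighbour linking: for each consecutive frame pair the
#' closest (track head, detection) pairs within `rLink` are joined, closest
#' first; unmatched detections seed new tracks. A second pass re-links track
#' ends to track starts across gaps of 1..`gMax` missing frames within
#' `rReopen` (the re-opening geometry), recording the closed-gap interval.
#' Tracks with fewer than `minFrames` detections are discarded as
#' single-frame blips.
#'
#' @param detections data.frame from [detectPitsMovie()] (columns frame, x,
#'   y, depth, diameter).
#' @param rLink per-frame linking radius, nm.
#' @param gMax maximum gap length, frames.
#' @param rReopen gap-closing radius, nm.
#' @param minFrames minimum detections per confirmed track.
#' @return data.frame of track points: event_id, frame, x, y, depth,
#'   diameter, with attribute `gaps` (data.frame event_id, gapStart, gapEnd,
#'   displacement).
#' @export
linkTracks <- function(detections, rLink = 250, gMax = 7L, rReopen = 120,
                       minFrames = 2L) {
  if (!nrow(detections)) {
    out <- cbind(event_id = integer(), detections)
    attr(out, "gaps") <- emptyGaps()
    return(out)
  }
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track <- NA_integer_
  frames <- sort(unique(det$frame))
  nextId <- 1L
  heads <- data.frame(track = integer(), x = numeric(), y = numeric(),
                      frame = integer())
  for (f in frames) {
    idx <- which(det$frame == f)
    act <- heads[heads$frame == f - 1L, , drop = FALSE]
    unmatched <- idx
    if (nrow(act) && length(idx)) {
      dmat <- outer(act$x, det$x[idx], "-")^2 + outer(act$y, det$y[idx], "-")^2
      repeat {
        m <- which.min(dmat)
        if (!length(m) || dmat[m] > rLink^2) break
        ti <- (m - 1) %% nrow(dmat) + 1
        di <- (m - 1) %/% nrow(dmat) + 1
        det$track[idx[di]] <- act$track[ti]
        dmat[ti, ] <- Inf; dmat[, di] <- Inf
        unmatched <- setdiff(unmatched, idx[di])
      }
    }
    for (i in unmatched) {
      det$track[i] <- nextId
      nextId <- nextId + 1L
    }
    # refresh heads
    new <- det[idx, c("track", "x", "y", "frame")]
    names(new)[1] <- "track"
    heads <- rbind(heads[!(heads$track %in% new$track), , drop = FALSE],
                   data.frame(track = new$track, x = new$x, y = new$y,
                              frame = new$frame))
  }

  # gap closing: join a track that ends at frame e to one starting at s with
  # 1 <= s - e - 1 <= gMax and displacement <= rReopen
  info <- do.call(rbind, lapply(split(det, det$track), function(d) {
    data.frame(track = d$track[1], first = min(d$frame), last = max(d$frame),
               fx = d$x[which.min(d$frame)], fy = d$y[which.min(d$frame)],
               lx = d$x[which.max(d$frame)], ly = d$y[which.max(d$frame)])
  }))
  gaps <- emptyGaps()
  repeat {
    cand <- NULL
    for (i in seq_len(nrow(info))) {
      g <- info$first - info$last[i] - 1L
      ok <- which(g >= 1L & g <= gMax & info$track != info$track[i])
      if (!length(ok)) next
      dd <- sqrt((info$fx[ok] - info$lx[i])^2 + (info$fy[ok] - info$ly[i])^2)
      ok2 <- ok[dd <= rReopen]
      if (!length(ok2)) next
      dd <- dd[dd <= rReopen]
      j <- ok2[which.min(dd)]
      cand <- rbind(cand, data.frame(from = info$track[i], to = info$track[j],
                                     d = min(dd), i = i, j = j))
    }
    if (is.null(cand)) break
    best <- cand[which.min(cand$d), ]
    i <- best$i; j <- best$j
    gaps <- rbind(gaps, data.frame(event_id = best$from,
                                   gapStart = info$last[i] + 1L,
                                   gapEnd = info$first[j] - 1L,
                                   displacement = best$d))
    det$track[det$track == best$to] <- best$from
    gaps$event_id[gaps$event_id == best$to] <- best$from
    info$last[i] <- info$last[j]; info$lx[i] <- info$lx[j]; info$ly[i] <- info$ly[j]
    info <- info[-j, , drop = FALSE]
  }

  keep <- names(which(table(det$track) >= minFrames))
  det <- det[det$track %in% as.integer(keep), , drop = FALSE]
  gaps <- gaps[gaps$event_id %in% as.integer(keep), , drop = FALSE]
  # renumber
  ids <- sort(unique(det$track))
  det$event_id <- match(det$track, ids)
  gaps$event_id <- match(gaps$event_id, ids)
  out <- det[, c("event_id", setdiff(names(detections), "track"))]
  out <- out[order(out$event_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gaps") <- gaps
  out
}

emptyGaps <- function() {
  data.frame(event_id = integer(), gapStart = integer(), gapEnd = integer(),
             displacement = numeric())
}

#' Assign CCP / caveola identity to a track by marker colocalization
#'
#' A track takes the identity of the marker channel whose spot (local
#' background-subtracted centroid) lies within `rColoc` of the track
#' position in at least half of the track's frames; ties are broken by mean
#' spot intensity. Without any marker, a size prior is used: mean corrected
#' diameter <= 120 nm is "caveola-like", >= 150 nm "CCP-like", otherwise
#' "unclassified".
#'
#' @param track data.frame of one track's points (frame, x, y, diameter).
#' @param fluor a \linkS4class{FluorMovie}, or NULL for the size prior.
#' @param transform a \linkS4class{RegistrationTransform}.
#' @param markerMap named channel -> identity map.
#' @param rColoc colocalization radius, nm.
#' @param tipRadius tip radius used for the size prior's corrected diameter.
#' @return identity label (character).
#' @export
assignIdentity <- function(track, fluor, transform,
                           markerMap = c(clathrin = "CCP", caveolin = "caveola"),
                           rColoc = 150, tipRadius = 10) {
  if (!is.null(fluor) && length(fluor@channels)) {
    hits <- numeric(0); meanI <- numeric(0)
    for (ch in intersect(names(markerMap), names(fluor@channels))) {
      arr <- fluor@channels[[ch]]
      nHit <- 0L; tot <- 0L; isum <- 0
      for (i in seq_len(nrow(track))) {
        k <- track$frame[i]
        if (k > dim(arr)[3]) next
        tot <- tot + 1L
        px <- fromCommon(transform, c(track$x[i], track$y[i]), "optical")
        ctd <- spotCentroid(arr[, , k], px)
        if (any(is.na(ctd))) next
        nm <- toCommon(transform, ctd, "optical")
        d <- sqrt((nm[1] - track$x[i])^2 + (nm[2] - track$y[i])^2)
        win <- arr[, , k]
        if (d <= rColoc) {
          nHit <- nHit + 1L
          isum <- isum + win[round(ctd[2]), round(ctd[1])]
        }
      }
      if (tot > 0 && nHit / tot >= 0.5) {
        hits[ch] <- nHit / tot
        meanI[ch] <- isum / max(nHit, 1L)
      }
    }
    if (length(hits)) {
      best <- names(hits)[hits == max(hits)]
      if (length(best) > 1L) best <- best[which.max(meanI[best])]
      return(unname(markerMap[best]))
    }
  }
  d <- mean(track$diameter, na.rm = TRUE)
  dCorr <- if (d > 2 * tipRadius) d - 2 * tipRadius else d
  if (is.na(dCorr)) return("unclassified")
  if (dCorr <= 120) "caveola-like" else if (dCorr >= 150) "CCP-like" else "unclassified"
}

#' Per-track lifetimes and the pit formation frequency
#'
#' Lifetime = first detection to final closure (one frame past the last
#' detection), gaps included. Tracks still present in the last frame are
#' censored and excluded from the mean. Formation frequency = new tracks per
#' scanned area per minute.
#'
#' @param tracks track table from [linkTracks()].
#' @param areaUm2 scanned area in um^2.
#' @param durationS movie duration in seconds.
#' @param dt frame interval in seconds.
#' @param nFramesTotal number of frames in the movie.
#' @return list(lifetimes = data.frame(event_id, lifetime_s, censored),
#'   formationFrequency = events/um^2/min, meanLifetime = s).
#' @export
lifetimeAndRate <- function(tracks, areaUm2, durationS, dt, nFramesTotal) {
  if (durationS <= 0) stop("invalid parameter: zero-duration movie", call. = FALSE)
  if (!nrow(tracks))
    return(list(lifetimes = data.frame(event_id = integer(),
                                       lifetime_s = numeric(),
                                       censored = logical()),
                formationFrequency = 0, meanLifetime = NA_real_))
  sp <- split(tracks, tracks$event_id)
  lt <- do.call(rbind, lapply(sp, function(d) {
    first <- min(d$frame); last <- max(d$frame)
    censored <- last >= nFramesTotal || first <= 1L
    data.frame(event_id = d$event_id[1],
               lifetime_s = ((last + 1L) - first) * dt,
               censored = censored)
  }))
  rownames(lt) <- NULL
  list(lifetimes = lt,
       formationFrequency = nrow(lt) / areaUm2 / (durationS / 60),
       meanLifetime = mean(lt$lifetime_s[!lt$censored]))
}
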