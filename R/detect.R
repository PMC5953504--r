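## Per-frame pit detection on AFM height frames.

#' Flag scan rows affected by tip-skip artifacts
#'
#' A skipped row duplicates its predecessor up to a constant offset; rows
#' whose residual after removing the best constant offset is essentially
#' zero are flagged (plus any rows named in an artifact log).
#'
#' @param z height matrix.
#' @param artifactLog optional data.frame with columns row, width for this
#'   frame.
#' @param tol residual tolerance (nm).
#' @return integer vector of affected row indices.
#' @export
flagArtifactRows <- function(z, artifactLog = NULL, tol = 0.05) {
  rows <- integer()
  if (!is.null(artifactLog) && nrow(artifactLog)) {
    for (i in seq_len(nrow(artifactLog))) {
      if (!is.na(artifactLog$row[i]))
        rows <- c(rows, artifactLog$row[i] + seq_len(artifactLog$width[i]) - 1L)
    }
  }
  d <- z[-1, , drop = FALSE] - z[-nrow(z), , drop = FALSE]
  resid <- apply(d, 1, function(v) stats::sd(v))
  dup <- which(resid < tol) + 1L
  sort(unique(c(rows, dup[dup <= nrow(z)])))
}

#' Static background of a height movie (per-pixel temporal median)
#'
#' Membrane texture persists between frames while endocytic pits are
#' transient, so the per-pixel median over time recovers the static relief.
#' Subtracting it before section-profile measurements removes the texture
#' that otherwise biases the tangential edge search. Structures present in
#' most frames (e.g. caveolae) survive into the background; measurement
#' code falls back to the raw frame where the background is itself deep.
#'
#' @param movie a \linkS4class{HeightMovie} or 3-D array.
#' @return rows x cols matrix (nm).
#' @export
staticBackground <- function(movie) {
  fr <- if (methods::is(movie, "HeightMovie")) movie@frames else movie
  apply(fr, c(1, 2), stats::median)
}

#' Detect membrane pits in one height frame
#'
#' Baseline-removal detection: the local baseline is a running median over a
#' ~750 nm window; connected regions deeper than `depthMin` below it are
#' candidate pits, split at merged minima by a tolerance-limited watershed.
#' Each candidate's centroid is the depth-weighted center and its
#' preliminary diameter is a section-profile measurement through the
#' centroid; candidates narrower than `minDiameter` are dropped. Flagged
#' artifact rows are replaced by their predecessor before filtering.
#'
#' @param z height matrix (nm).
#' @param pixelSize nm/pixel.
#' @param depthMin detection depth threshold below the local baseline (nm).
#' @param minDiameter minimum preliminary diameter (nm).
#' @param baselineWindow running-median window (nm).
#' @param artifactLog optional artifact log rows for this frame.
#' @param staticBg optional static background (see [staticBackground()])
#'   subtracted before the preliminary diameter measurement.
#' @return data.frame: x, y (nm), depth (nm), diameter (nm), area_px, score.
#' @export
detectPits <- function(z, pixelSize, depthMin = 10, minDiameter = 60,
                       baselineWindow = 750, artifactLog = NULL,
                       staticBg = NULL) {
  bad <- flagArtifactRows(z, artifactLog)
  if (length(bad)) {
    for (r in bad) if (r > 1) z[r, ] <- z[r - 1, ]
  }
  rng <- range(z)
  span <- max(diff(rng), 1e-6)
  x01 <- (z - rng[1]) / span
  radPx <- max(1L, as.integer(round(baselineWindow / pixelSize / 2)))
  base01 <- as.matrix(EBImage::medianFilter(EBImage::Image(x01), radPx))
  depthMap <- (base01 - x01) * span     # positive inside depressions
  mask <- depthMap > depthMin
  if (!any(mask)) return(emptyDetections())
  # watershed split of merged regions, tolerance half the depth threshold
  ws <- EBImage::watershed(EBImage::Image(depthMap * mask / span),
                           tolerance = (depthMin / 2) / span, ext = 1)
  lab <- as.matrix(EBImage::imageData(ws))
  lab[!mask] <- 0
  ids <- setdiff(unique(as.vector(lab)), 0)
  if (!length(ids)) return(emptyDetections())
  ctr <- afmPixelCenters(dim(z), pixelSize)
  out <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    sel <- lab == ids[j]
    npx <- sum(sel)
    if (npx < 3L) next
    rc <- which(sel, arr.ind = TRUE)
    w <- depthMap[sel]
    cx <- sum(ctr$x[rc[, 2]] * w) / sum(w)
    cy <- sum(ctr$y[rc[, 1]] * w) / sum(w)
    depth <- max(w)
    zm <- measurementFrame(z, staticBg, cx, cy, pixelSize)
    dia <- sectionDiameter(zm, c(cx, cy), pixelSize, depthMin = depthMin)
    if (is.na(dia) || dia < minDiameter) next
    out[[j]] <- data.frame(x = cx, y = cy, depth = depth, diameter = dia,
                           area_px = npx, score = depth,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(emptyDetections())
  do.call(rbind, out)
}

emptyDetections <- function() {
  data.frame(x = numeric(), y = numeric(), depth = numeric(),
             diameter = numeric(), area_px = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect pits across all frames of a height movie
#'
#' @param movie a \linkS4class{HeightMovie} (or MovieBundle).
#' @param ... passed to [detectPits()].
#' @return data.frame with a `frame` column prepended.
#' @export
detectPitsMovie <- function(movie, ...) {
  if (methods::is(movie, "MovieBundle")) movie <- movie@height
  px <- movie@geometry@afmPixelSize
  nf <- nFrames(movie)
  bg <- staticBackground(movie)
  res <- vector("list", nf)
  for (k in seq_len(nf)) {
    alog <- movie@artifactLog[movie@artifactLog$frame == k, , drop = FALSE]
    d <- detectPits(movie@frames[, , k], px, artifactLog = alog,
                    staticBg = bg, ...)
    if (nrow(d)) res[[k]] <- cbind(frame = k, d)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(cbind(frame = integer(), emptyDetections()))
  do.call(rbind, res)
}

## Frame used for section measurements: static background removed unless the
## background is itself deep near the feature (a persistent structure such as
## a caveola would be cancelled by its own background).
measurementFrame <- function(z, staticBg, cx, cy, pixelSize) {
  if (is.null(staticBg)) return(z)
  ctr <- afmPixelCenters(dim(z), pixelSize)
  ci <- which.min(abs(ctr$x - cx)); ri <- which.min(abs(ctr$y - cy))
  rs <- max(1, ri - 3):min(nrow(z), ri + 3)
  cs <- max(1, ci - 3):min(ncol(z), ci + 3)
  if (min(staticBg[rs, cs]) < -8) return(z)   # contaminated background
  z - staticBg
}
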