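## Rendering of AFM height frames and confocal fluorescence frames.

## Pixel-center coordinate vectors of the AFM grid in the common frame (nm),
## scan area centered on the probe origin, +y up (row 1 = top).
afmPixelCenters <- function(gridShape, pixelSize) {
  rows <- gridShape[1]; cols <- gridShape[2]
  list(x = (seq_len(cols) - 0.5 - cols / 2) * pixelSize,
       y = (rows / 2 - (seq_len(rows) - 0.5)) * pixelSize)
}

#' Static membrane-roughness background field
#'
#' White Gaussian noise smoothed to the configured correlation length and
#' rescaled to the configured RMS roughness. The field is static over the
#' movie (membrane texture persists between frames); per-frame sensor noise
#' is added separately at render time.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return rows x cols matrix (nm).
#' @export
makeRoughnessField <- function(config) {
  rows <- config@gridShape[1]; cols <- config@gridShape[2]
  sz <- config@noise$sigmaZ
  if (sz <= 0) return(matrix(0, rows, cols))
  w <- matrix(stats::rnorm(rows * cols), rows, cols)
  sigmaPx <- config@noise$corrLength / config@pixelSize / 2
  sm <- EBImage::gblur(w, sigma = sigmaPx)
  sm <- sm - mean(sm)
  sm * (sz / stats::sd(as.vector(sm)))
}

## Add one radially symmetric raised-cosine feature (pit if amp < 0,
## swelling if amp > 0) at common-frame position (cx, cy) to height grid z.
addFeature <- function(z, cx, cy, radius, amp, gridShape, pixelSize) {
  if (radius <= 0 || amp == 0) return(z)
  ctr <- afmPixelCenters(gridShape, pixelSize)
  ci <- which(abs(ctr$x - cx) < radius + pixelSize)
  ri <- which(abs(ctr$y - cy) < radius + pixelSize)
  if (!length(ci) || !length(ri)) return(z)
  dx <- ctr$x[ci] - cx
  dy <- ctr$y[ri] - cy
  r <- sqrt(outer(dy^2, dx^2, "+"))
  z[ri, ci] <- z[ri, ci] + raisedCosine(r, radius, amp)
  z
}

#' Render one AFM height frame
#'
#' Draws every open pit as a radially smooth raised-cosine depression whose
#' baseline-crossing diameter equals its aperture and whose depth is the
#' configured pit depth, and every active capping swelling as a positive
#' raised-cosine cap, on top of a background field. Event positions are taken
#' as given (drift, if any, is already folded into them).
#'
#' @param events data.frame with one row per feature to draw: columns x, y
#'   (nm), aperture (nm, NA if closed), plus optional swelling columns
#'   swellX, swellY, swellDia, swellAmp for events with an active swelling.
#' @param config a \linkS4class{SimulationConfig}.
#' @param background rows x cols matrix (nm) or NULL for a flat zero field.
#' @return rows x cols height matrix (nm).
#' @export
renderHeightFrame <- function(events, config, background = NULL) {
  gs <- config@gridShape; px <- config@pixelSize
  z <- if (is.null(background)) matrix(0, gs[1], gs[2]) else background
  depth <- config@geometryParams$depth
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ap <- events$aperture[i]
      if (!is.na(ap) && ap > 0)
        z <- addFeature(z, events$x[i], events$y[i], ap / 2, -depth, gs, px)
      if (!is.null(events$swellAmp) && !is.na(events$swellAmp[i]) &&
          events$swellAmp[i] > 0)
        z <- addFeature(z, events$swellX[i], events$swellY[i],
                        events$swellDia[i] / 2, events$swellAmp[i], gs, px)
    }
  }
  z
}

#' Image a surface with a finite spherical-cap tip (grayscale dilation)
#'
#' The imaged height at a pixel is the maximum over the tip footprint of the
#' surface height plus the tip profile t(d) = sqrt(R^2 - d^2) - R (<= 0).
#' The output is everywhere >= the input and the operator is the identity
#' for a zero tip radius; note that dilation *narrows* depressions, whereas
#' the downstream diameter correction follows the instrument convention of
#' subtracting the tip diameter (see [tipCorrect()]).
#'
#' @param z height matrix (nm).
#' @param tipRadius tip radius (nm).
#' @param pixelSize nm per pixel.
#' @return imaged height matrix.
#' @export
applyTipConvolution <- function(z, tipRadius, pixelSize) {
  if (tipRadius < 0) stop("invalid parameter: tipRadius must be >= 0", call. = FALSE)
  halfExtent <- min(nrow(z), ncol(z)) * pixelSize / 2
  if (tipRadius > halfExtent)
    stop("invalid parameter: tip radius exceeds half the grid extent", call. = FALSE)
  if (tipRadius == 0) return(z)
  kpx <- floor(tipRadius / pixelSize)
  if (kpx < 1) return(z)  # footprint smaller than one pixel
  off <- expand.grid(dr = -kpx:kpx, dc = -kpx:kpx)
  off$d <- sqrt(off$dr^2 + off$dc^2) * pixelSize
  off <- off[off$d <= tipRadius, ]
  nr <- nrow(z); nc <- ncol(z)
  out <- z
  for (i in seq_len(nrow(off))) {
    dr <- off$dr[i]; dc <- off$dc[i]
    if (dr == 0 && dc == 0) next
    tprof <- sqrt(tipRadius^2 - off$d[i]^2) - tipRadius
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    out[rs, cs] <- pmax(out[rs, cs], z[rs + dr, cs + dc] + tprof)
  }
  out
}

#' Inject scan-line artifacts into a height frame
#'
#' With probability `pSkip` a tip skip replaces 1-2 consecutive scan rows
#' with the previous row's values plus a constant offset; with probability
#' `pAmplitude` an amplitude step rescales the frame's relief about its
#' median (a global contrast change). All injections are logged.
#'
#' @param z height matrix.
#' @param artifactRates list with pSkip and pAmplitude in [0, 1].
#' @param forceSkipRow optionally force a skip starting at this row (tests).
#' @return list(frame = modified matrix, log = data.frame(row, width, type)).
#' @export
injectScanArtifacts <- function(z, artifactRates, forceSkipRow = NULL) {
  stopIfNot(all(unlist(artifactRates) >= 0 & unlist(artifactRates) <= 1),
            "artifact rates must be in [0, 1]")
  log <- data.frame(row = integer(), width = integer(), type = character(),
                    stringsAsFactors = FALSE)
  doSkip <- !is.null(forceSkipRow) || stats::runif(1) < artifactRates$pSkip
  if (doSkip) {
    r <- if (!is.null(forceSkipRow)) as.integer(forceSkipRow) else
      sample(2:(nrow(z) - 1), 1)
    w <- sample(1:2, 1)
    offset <- stats::runif(1, -6, 6)
    rows <- r:min(r + w - 1, nrow(z))
    for (rr in rows) z[rr, ] <- z[r - 1, ] + offset
    log <- rbind(log, data.frame(row = r, width = length(rows),
                                 type = "tip_skip", stringsAsFactors = FALSE))
  }
  if (stats::runif(1) < artifactRates$pAmplitude) {
    fac <- stats::runif(1, 1.02, 1.08)
    med <- stats::median(z)
    z <- med + (z - med) * fac
    log <- rbind(log, data.frame(row = NA_integer_, width = NA_integer_,
                                 type = "amplitude_step",
                                 stringsAsFactors = FALSE))
  }
  list(frame = z, log = log)
}

## Optical-grid dimensions and pixel centers for the fluorescence channels.
opticalGrid <- function(config) {
  extentX <- config@gridShape[2] * config@pixelSize
  extentY <- config@gridShape[1] * config@pixelSize
  pxo <- 83
  cols <- as.integer(floor(extentX / pxo))
  rows <- as.integer(floor(extentY / pxo))
  list(rows = rows, cols = cols, pixelSize = pxo,
       x = (seq_len(cols) - 0.5 - cols / 2) * pxo,
       y = (rows / 2 - (seq_len(rows) - 0.5)) * pxo)
}

PSF_SIGMA_NM <- 106  # ~250 nm FWHM confocal PSF

## Render one fluorescence frame: Gaussian PSF spots + Poisson photon noise
## + Gaussian read noise, integer counts.
renderFluorFrame <- function(spots, config, grid = opticalGrid(config),
                             noiseless = FALSE) {
  img <- matrix(config@noise$background, grid$rows, grid$cols)
  if (!is.null(spots) && nrow(spots)) {
    for (i in seq_len(nrow(spots))) {
      amp <- spots$amp[i] * config@noise$photonScale
      if (is.na(amp) || amp <= 0) next
      cx <- spots$x[i]; cy <- spots$y[i]
      win <- 4 * PSF_SIGMA_NM
      ci <- which(abs(grid$x - cx) < win)
      ri <- which(abs(grid$y - cy) < win)
      if (!length(ci) || !length(ri)) next
      gx <- exp(-(grid$x[ci] - cx)^2 / (2 * PSF_SIGMA_NM^2))
      gy <- exp(-(grid$y[ri] - cy)^2 / (2 * PSF_SIGMA_NM^2))
      img[ri, ci] <- img[ri, ci] + amp * outer(gy, gx)
    }
  }
  if (noiseless) return(img)
  counts <- matrix(stats::rpois(length(img), as.vector(img)),
                   nrow(img), ncol(img))
  counts <- counts + round(stats::rnorm(length(counts), 0, config@noise$readSigma))
  counts[counts < 0] <- 0
  counts
}
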