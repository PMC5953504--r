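## Shared fixtures and independent brute-force oracles.

# quiet config for single-frame rendering tests: no events, no noise
flatConfig <- function(...) {
  simulationConfig(nEvents = 0L, nFrames = 1L, seed = 1L, tipRadius = 0,
                   noise = list(sigmaZ = 0, sigmaFrame = 0), ...)
}

# small movie config used by pipeline tests
smallConfig <- function(nEvents = 6L, nFrames = 50L, seed = 11L, ...) {
  simulationConfig(nEvents = nEvents, nFrames = nFrames, seed = seed, ...)
}

# independent 1-D profile oracle: diameter of a pit rendered in matrix z,
# measured on the raw grid row through the center (no package measurement
# code): first grid column at/beyond the baseline crossing on each side.
oracleRowDiameter <- function(z, centerRowCol, eps = 1) {
  r <- centerRowCol[1]
  prof <- z[r, ]
  imin <- which.min(prof)
  left <- imin
  while (left > 1 && prof[left] < -eps) left <- left - 1
  right <- imin
  while (right < length(prof) && prof[right] < -eps) right <- right + 1
  (right - left) * 18.75
}

# brute-force grayscale dilation with a spherical-cap tip (independent of
# applyTipConvolution's implementation)
oracleTipDilation <- function(z, tipRadius, pixelSize) {
  nr <- nrow(z); nc <- ncol(z)
  out <- z
  kpx <- floor(tipRadius / pixelSize)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    best <- z[r, c]
    for (dr in -kpx:kpx) for (dc in -kpx:kpx) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      d <- sqrt(dr^2 + dc^2) * pixelSize
      if (d > tipRadius) next
      v <- z[rr, cc] + sqrt(tipRadius^2 - d^2) - tipRadius
      if (v > best) best <- v
    }
    out[r, c] <- best
  }
  out
}

# brute-force flat morphology on binary/graylevel matrices with a disc mask
oracleErode <- function(x, mask) {
  # minimum over mask-shifted copies; out-of-range neighbours ignored
  nr <- nrow(x); nc <- ncol(x)
  kr <- (nrow(mask) - 1) / 2; kc <- (ncol(mask) - 1) / 2
  out <- matrix(Inf, nr, nc)
  for (dr in -kr:kr) for (dc in -kc:kc) {
    if (mask[dr + kr + 1, dc + kc + 1] == 0) next
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    out[rs, cs] <- pmin(out[rs, cs], x[rs + dr, cs + dc])
  }
  out
}

oracleDilate <- function(x, mask) -oracleErode(-x, mask)

# render one raised-cosine pit (plus optional bump) on a flat grid
renderPit <- function(aperture, depth = 30, cx = 0, cy = 0, cfg = flatConfig()) {
  renderHeightFrame(data.frame(x = cx, y = cy, aperture = aperture), cfg)
}
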