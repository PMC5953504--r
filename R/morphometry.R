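## Section-profile morphometry: the measurement operators applied to every
## detected pit and swelling.

#' SectionProfile: heights sampled along a line through a feature
#'
#' @slot positions nm along the line (strictly increasing, 0 at the center).
#' @slot heights nm.
#' @slot angle radians from the +x (fast scan) axis.
#' @slot spacing sample spacing in nm (one AFM pixel).
#' @slot truncated TRUE if the requested line left the grid.
#' @export
setClass("SectionProfile", representation(
  positions = "numeric", heights = "numeric", angle = "numeric",
  spacing = "numeric", truncated = "logical"
))

setValidity("SectionProfile", function(object) {
  if (length(object@positions) != length(object@heights))
    return("positions and heights must have equal length")
  if (any(diff(object@positions) <= 0))
    return("positions must be strictly increasing")
  TRUE
})

setMethod("show", "SectionProfile", function(object) {
  cat(sprintf("SectionProfile: %d samples @ %.4g nm, angle %.1f deg%s\n",
              length(object@positions), object@spacing,
              object@angle * 180 / pi,
              if (object@truncated) " (truncated)" else ""))
})

#' Extract a cross-section profile through a point of a height grid
#'
#' Samples the grid by bilinear interpolation along a line through `center`
#' at one-pixel spacing, out to `halfLength` on each side.
#'
#' @param z height matrix (nm).
#' @param center c(x, y) in the common nm frame.
#' @param angle line direction, radians from the +x axis.
#' @param halfLength nm on each side of the center.
#' @param config a \linkS4class{SimulationConfig}, or NULL with explicit
#'   `pixelSize`/`gridShape`.
#' @param pixelSize,gridShape grid geometry when `config` is NULL.
#' @return a \linkS4class{SectionProfile}.
#' @export
sectionProfile <- function(z, center, angle = 0, halfLength, config = NULL,
                           pixelSize = NULL, gridShape = NULL) {
  if (!is.null(config)) { pixelSize <- config@pixelSize; gridShape <- config@gridShape }
  if (is.null(gridShape)) gridShape <- dim(z)
  ctr <- afmPixelCenters(gridShape, pixelSize)
  if (center[1] < min(ctr$x) || center[1] > max(ctr$x) ||
      center[2] < min(ctr$y) || center[2] > max(ctr$y))
    stop("center outside grid", call. = FALSE)
  s <- seq(-halfLength, halfLength, by = pixelSize)
  xs <- center[1] + s * cos(angle)
  ys <- center[2] + s * sin(angle)
  # nm -> fractional (row, col)
  col <- (xs - ctr$x[1]) / pixelSize + 1
  row <- (ctr$y[1] - ys) / pixelSize + 1
  h <- bilinear(z, row, col)
  ok <- !is.na(h)
  new("SectionProfile", positions = s[ok], heights = h[ok], angle = angle,
      spacing = pixelSize, truncated = any(!ok))
}

profileBaseline <- function(profile, flankFrac = 0.25) {
  n <- length(profile@positions)
  k <- max(2L, floor(n * flankFrac))
  left <- stats::median(profile@heights[seq_len(k)])
  right <- stats::median(profile@heights[(n - k + 1):n])
  c(left = left, right = right, mid = (left + right) / 2)
}

#' Measure a pit (or swelling) diameter on a section profile
#'
#' The baseline is the mean of the two flank medians (outer 25% of samples
#' per side). Starting from the extremum and walking outward, the edge on
#' each side is the first sample whose height returns to within `eps` of the
#' baseline; the diameter is the distance between the two edges.
#'
#' @param profile a \linkS4class{SectionProfile}.
#' @param depthMin minimum extremum excursion below (pit) or above (peak)
#'   the baseline, nm.
#' @param eps edge tolerance, nm.
#' @param feature "pit" for depressions, "peak" for swellings.
#' @return diameter in nm.
#' @export
measureDiameter <- function(profile, depthMin = 10, eps = 1,
                            feature = c("pit", "peak")) {
  feature <- match.arg(feature)
  h <- if (feature == "peak") -profile@heights else profile@heights
  bl <- profileBaseline(profile)
  base <- if (feature == "peak") -bl[["mid"]] else bl[["mid"]]
  if (min(h) >= base - depthMin)
    stop("no-pit: profile has no qualifying minimum", call. = FALSE)
  r <- profileRadii(profile, depthMin, eps, feature)
  if (any(is.na(r)))
    stop("truncation: edge not found within profile", call. = FALSE)
  sum(r)
}

#' Measure a swelling height on a section profile
#'
#' Height of the maximum above the mean of the two basal levels, each basal
#' level being the median of the outer 25% of samples on that side.
#'
#' @param profile a \linkS4class{SectionProfile}.
#' @return height in nm.
#' @export
measureHeight <- function(profile) {
  h <- profile@heights
  bl <- profileBaseline(profile)
  imax <- which.max(h)
  n <- length(h)
  k <- max(2L, floor(n * 0.25))
  if (imax <= k || imax > n - k || h[imax] <= max(bl[["left"]], bl[["right"]]))
    stop("no-peak: profile has no interior maximum above both flanks",
         call. = FALSE)
  h[imax] - (bl[["left"]] + bl[["right"]]) / 2
}

## Per-side edge radii of one profile (distance from the extremum's position
## to the edge sample on each side), NA when a side has no edge.
profileRadii <- function(profile, depthMin = 10, eps = 1,
                         feature = c("pit", "peak")) {
  feature <- match.arg(feature)
  h <- profile@heights
  if (feature == "peak") h <- -h
  pos <- profile@positions
  bl <- profileBaseline(profile)
  base <- if (feature == "peak") -bl[["mid"]] else bl[["mid"]]
  imin <- which.min(h)
  if (h[imin] >= base - depthMin) return(c(NA_real_, NA_real_))
  leftSide <- rev(seq_len(imin))
  iL <- leftSide[which(h[leftSide] >= base - eps)[1]]
  rightSide <- imin:length(h)
  iR <- rightSide[which(h[rightSide] >= base - eps)[1]]
  c(if (is.na(iL)) NA_real_ else pos[imin] - pos[iL],
    if (is.na(iR)) NA_real_ else pos[iR] - pos[imin])
}

## Per-side rim radii by two-level extrapolation. A smooth pit meets the
## baseline tangentially, so near the rim the profile is ~quadratic in
## (a - r); the baseline-crossing radius a then follows from the continuous
## (interpolated) crossings r1, r2 at two depths e1 < e2 below baseline:
## with e2 = 4*e1, a = 2*r1 - r2. Sub-pixel, insensitive to the sampling
## phase and to the bilinear resampling of the grid.
rimRadii <- function(profile, depthMin = 10, feature = c("pit", "peak")) {
  feature <- match.arg(feature)
  h <- if (feature == "peak") -profile@heights else profile@heights
  pos <- profile@positions
  bl <- profileBaseline(profile)
  base <- if (feature == "peak") -bl[["mid"]] else bl[["mid"]]
  imin <- which.min(h)
  depth <- base - h[imin]
  if (depth < depthMin) return(c(NA_real_, NA_real_))
  e2 <- min(8, depth / 3)
  e1 <- e2 / 4
  crossOut <- function(idx) {
    # first outward crossing of base - e, linearly interpolated
    cross <- function(e) {
      lev <- base - e
      prev <- imin
      for (i in idx) {
        if (h[i] >= lev) {
          if (i == imin) return(abs(pos[i] - pos[imin]))
          f <- (lev - h[prev]) / (h[i] - h[prev])
          return(abs(pos[prev] + f * (pos[i] - pos[prev]) - pos[imin]))
        }
        prev <- i
      }
      NA_real_
    }
    r1 <- cross(e1); r2 <- cross(e2)
    if (is.na(r1) || is.na(r2)) return(NA_real_)
    max(2 * r1 - r2, r1)
  }
  c(crossOut(rev(seq_len(imin))), crossOut(imin:length(h)))
}

#' Robust multi-angle section diameter
#'
#' Extracts section profiles through `center` at several angles and, on each
#' side of each profile, locates the rim by extrapolating the interpolated
#' crossings at two depths below baseline to the tangential baseline
#' crossing (sub-pixel). The diameter is twice the median of the per-side
#' radii; the median suppresses the directional outliers that arise when one
#' section runs into a texture dip or a neighbouring structure.
#'
#' @param z height matrix (nm).
#' @param center c(x, y) nm.
#' @param pixelSize nm/pixel.
#' @param angles section angles in radians.
#' @param halfLength profile half length (nm).
#' @param depthMin,eps,feature as in [measureDiameter()].
#' @return diameter in nm (NA when no angle yields a measurement).
#' @export
sectionDiameter <- function(z, center, pixelSize,
                            angles = c(0, pi / 4, pi / 2, 3 * pi / 4),
                            halfLength = 600, depthMin = 10, eps = 1,
                            feature = c("pit", "peak")) {
  feature <- match.arg(feature)
  radii <- c()
  for (a in angles) {
    prof <- tryCatch(sectionProfile(z, center, a, halfLength,
                                    pixelSize = pixelSize, gridShape = dim(z)),
                     error = function(e) NULL)
    if (is.null(prof)) next
    radii <- c(radii, rimRadii(prof, depthMin, feature))
  }
  radii <- radii[!is.na(radii)]
  if (length(radii) < 2) return(NA_real_)
  # half a pixel compensates the support widening introduced by pixel-grid
  # rendering plus bilinear resampling of a tangential rim
  max(2 * stats::median(radii) - pixelSize / 2, pixelSize)
}

#' Robust multi-angle swelling height
#'
#' Median over section angles of [measureHeight()] at `center`.
#'
#' @inheritParams sectionDiameter
#' @return height in nm (NA when no angle yields a measurement).
#' @export
sectionHeight <- function(z, center, pixelSize,
                          angles = c(0, pi / 4, pi / 2, 3 * pi / 4),
                          halfLength = 450) {
  hs <- c()
  for (a in angles) {
    h <- tryCatch({
      prof <- sectionProfile(z, center, a, halfLength,
                             pixelSize = pixelSize, gridShape = dim(z))
      measureHeight(prof)
    }, error = function(e) NA_real_)
    hs <- c(hs, h)
  }
  hs <- hs[!is.na(hs)]
  if (!length(hs)) return(NA_real_)
  stats::median(hs)
}

#' Tip-curvature correction of a measured diameter
#'
#' The instrument convention: the apparent (outer) diameter measured on the
#' AFM image overestimates the aperture by the tip diameter, so the
#' corrected value is `diameter - 2 * tipRadius` (150 -> 130 and 400 -> 380
#' at the default 10 nm tip radius).
#'
#' @param diameterRaw measured diameter, nm.
#' @param tipRadius tip radius, nm (default 10).
#' @return corrected diameter, nm.
#' @examples
#' tipCorrect(150, 10)  # 130
#' @export
tipCorrect <- function(diameterRaw, tipRadius = 10) {
  if (any(diameterRaw <= 2 * tipRadius))
    stop("domain error: diameter must exceed the tip diameter", call. = FALSE)
  diameterRaw - 2 * tipRadius
}

#' Morphological-filter pit area
#'
#' The filter cascade applied to one frame: 3x3 median filter, black top-hat
#' with a circular structuring element (~20 px diameter; extracts
#' depressions narrower than the element), opening-then-closing with a ~6 px
#' circular element (removes speckle), threshold at half the maximum
#' response within the ROI, and area = suprathreshold pixel count times the
#' pixel area.
#'
#' @param z height matrix (nm).
#' @param roi list(rows = c(r0, r1), cols = c(c0, c1)) region of interest.
#' @param pixelSize nm per pixel.
#' @param topHatDiameter,openCloseDiameter structuring-element diameters, px.
#' @return area in nm^2 (0 for a flat ROI).
#' @export
measureArea <- function(z, roi, pixelSize,
                        topHatDiameter = 20, openCloseDiameter = 6) {
  if (roi$rows[2] < roi$rows[1] || roi$cols[2] < roi$cols[1])
    stop("empty roi", call. = FALSE)
  rs <- roi$rows[1]:roi$rows[2]; cs <- roi$cols[1]:roi$cols[2]
  sub <- z[rs, cs, drop = FALSE]
  rng <- range(sub)
  if (diff(rng) < 1e-9) return(0)
  x01 <- (sub - rng[1]) / diff(rng)
  med <- as.matrix(EBImage::medianFilter(EBImage::Image(x01), 1))
  kTH <- discBrush(topHatDiameter)
  resp <- as.matrix(EBImage::closing(EBImage::Image(med), kTH)) - med  # black top-hat
  kOC <- discBrush(openCloseDiameter)
  resp <- EBImage::closing(EBImage::opening(EBImage::Image(resp), kOC), kOC)
  resp <- as.matrix(resp)
  m <- max(resp)
  if (m <= 1e-6) return(0)
  sum(resp >= m / 2) * pixelSize^2
}
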