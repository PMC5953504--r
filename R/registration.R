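## Probe-origin registration of the AFM scan area with the optical frame.

#' Locate the probe-origin spot in a fluorescence image
#'
#' The parked cantilever tip's autofluorescence spot defines the origin of
#' the common coordinate frame. The image is thresholded at median + 3*MAD,
#' the connected bright region with the highest peak intensity is selected,
#' and its intensity-weighted centroid (above-background weights) is
#' returned with sub-pixel precision.
#'
#' @param img intensity matrix (rows x cols).
#' @return c(col, row) centroid in optical pixels.
#' @export
locateProbeOrigin <- function(img) {
  # remove any smooth illumination slope before thresholding
  rr <- row(img); cc <- col(img)
  fit <- stats::lm.fit(cbind(1, as.vector(rr), as.vector(cc)),
                       as.vector(img))
  img <- img - matrix(fit$fitted.values, nrow(img), ncol(img))
  if (diff(range(img)) < 1e-9)
    stop("no-spot: image is constant", call. = FALSE)
  bg <- stats::median(img)
  thr <- bg + 3 * stats::mad(img)
  mask <- img > thr
  if (!any(mask)) stop("no-spot: no pixel above background threshold", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  peaks <- tapply(img[mask], lab[mask], max)
  best <- max(peaks)
  ties <- names(peaks)[peaks > best - 1e-3 * max(abs(best), 1)]
  if (length(ties) > 1L)
    stop("ambiguity: multiple regions share the maximal intensity", call. = FALSE)
  sel <- lab == as.integer(ties[1])
  w <- img[sel] - bg
  rc <- which(sel, arr.ind = TRUE)
  c(col = sum(rc[, 2] * w) / sum(w), row = sum(rc[, 1] * w) / sum(w))
}

#' Build the registration transform from a scan geometry
#'
#' Produces the affine maps taking AFM pixel coordinates and optical pixel
#' coordinates (pixel centers at integer (col, row), row 1 = top) into the
#' common nm frame whose origin is the probe spot and whose +y axis points
#' up. AFM pixel (1, 1) maps to the top-left scan corner inset by half a
#' pixel; the probe origin maps to (0, 0) nm.
#'
#' @param geometry a \linkS4class{ScanGeometry}.
#' @return a \linkS4class{RegistrationTransform}.
#' @export
buildTransform <- function(geometry) {
  methods::validObject(geometry)
  px <- geometry@afmPixelSize
  tl <- geometry@corners[1, ]
  afm <- rbind(c(px, 0, tl[1] - 0.5 * px),
               c(0, -px, tl[2] + 0.5 * px),
               c(0, 0, 1))
  pxo <- geometry@opticalPixelSize
  x0 <- geometry@probeOrigin[1]; y0 <- geometry@probeOrigin[2]
  opt <- rbind(c(pxo, 0, -x0 * pxo),
               c(0, -pxo, y0 * pxo),
               c(0, 0, 1))
  new("RegistrationTransform", afmToCommon = afm, opticalToCommon = opt,
      timeOffset = 0)
}

#' Map pixel coordinates to the common nm frame (and back)
#'
#' @param transform a \linkS4class{RegistrationTransform}.
#' @param xy n x 2 matrix of (col, row) pixels (`toCommon`) or (x, y) nm
#'   (`fromCommon`).
#' @param from which grid: "afm" or "optical".
#' @return n x 2 matrix.
#' @export
toCommon <- function(transform, xy, from = c("afm", "optical")) {
  from <- match.arg(from)
  M <- if (from == "afm") transform@afmToCommon else transform@opticalToCommon
  xy <- matrix(xy, ncol = 2)
  out <- cbind(xy, 1) %*% t(M)
  out[, 1:2, drop = FALSE]
}

#' @rdname toCommon
#' @export
fromCommon <- function(transform, xy, from = c("afm", "optical")) {
  from <- match.arg(from)
  M <- if (from == "afm") transform@afmToCommon else transform@opticalToCommon
  xy <- matrix(xy, ncol = 2)
  out <- cbind(xy, 1) %*% t(solve(M))
  out[, 1:2, drop = FALSE]
}

#' Centroid offset between an AFM pit and its fluorescence spot
#'
#' @param afmCentroid c(x, y) nm in the common frame.
#' @param fluorCentroid c(x, y) nm in the common frame.
#' @param event,frame optional identifiers carried into the record.
#' @return data.frame with dx_nm, dy_nm and the Euclidean d_nm.
#' @export
measureOffset <- function(afmCentroid, fluorCentroid, event = NA, frame = NA) {
  dx <- fluorCentroid[1] - afmCentroid[1]
  dy <- fluorCentroid[2] - afmCentroid[2]
  data.frame(event_id = event, frame = frame, dx_nm = dx, dy_nm = dy,
             d_nm = sqrt(dx^2 + dy^2))
}

#' Sub-pixel fluorescence spot centroid near a position
#'
#' Intensity-weighted centroid in a fixed-radius window around an expected
#' position, after subtracting the local median background.
#'
#' @param img intensity matrix.
#' @param center c(col, row) expected position, optical pixels.
#' @param radius window radius in pixels (default 5).
#' @return c(col, row) centroid, or NA if no positive mass.
#' @export
spotCentroid <- function(img, center, radius = 5) {
  nr <- nrow(img); nc <- ncol(img)
  cs <- max(1, round(center[1] - radius)):min(nc, round(center[1] + radius))
  rs <- max(1, round(center[2] - radius)):min(nr, round(center[2] + radius))
  win <- img[rs, cs, drop = FALSE]
  w <- win - stats::median(win)
  w[w < 0] <- 0
  if (sum(w) <= 0) return(c(col = NA_real_, row = NA_real_))
  c(col = sum(rep(cs, each = length(rs)) * w) / sum(w),
    row = sum(rep(rs, times = length(cs)) * w) / sum(w))
}
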