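#' @import methods
#' @importFrom stats median mad rnorm runif rpois sd setNames quantile
NULL

#' ScanGeometry: placement of the AFM scan area in the optical frame
#'
#' Holds the corner coordinates of the AFM scan area expressed in the optical
#' (confocal) coordinate frame, the two pixel sizes, and the probe origin.
#' The probe origin is the autofluorescence spot of the parked cantilever tip,
#' which defines the origin (0, 0) of the common coordinate frame; the default
#' corners place a 6.0 x 4.5 um^2 scan area symmetrically about it.
#'
#' @slot corners numeric 4x2 matrix (nm), rows = top-left, top-right,
#'   bottom-right, bottom-left in the common frame (+y up).
#' @slot afmPixelSize nm per AFM pixel.
#' @slot opticalPixelSize nm per optical pixel.
#' @slot probeOrigin numeric length-2, probe-spot position in optical pixels
#'   (col, row).
#' @export
setClass("ScanGeometry", representation(
  corners = "matrix",
  afmPixelSize = "numeric",
  opticalPixelSize = "numeric",
  probeOrigin = "numeric"
))

setValidity("ScanGeometry", function(object) {
  msg <- NULL
  co <- object@corners
  if (!is.matrix(co) || !identical(dim(co), c(4L, 2L)))
    msg <- c(msg, "corners must be a 4x2 matrix")
  else {
    # axis-aligned rectangle: TL/TR share y, TR/BR share x, etc.
    if (!(isTRUE(all.equal(co[1, 2], co[2, 2])) &&
          isTRUE(all.equal(co[3, 2], co[4, 2])) &&
          isTRUE(all.equal(co[1, 1], co[4, 1])) &&
          isTRUE(all.equal(co[2, 1], co[3, 1]))))
      msg <- c(msg, "corners must form an axis-aligned rectangle")
    if (co[2, 1] <= co[1, 1] || co[1, 2] <= co[4, 2])
      msg <- c(msg, "degenerate corners")
  }
  if (object@afmPixelSize <= 0) msg <- c(msg, "afmPixelSize must be > 0")
  if (object@opticalPixelSize <= 0) msg <- c(msg, "opticalPixelSize must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ScanGeometry
#'
#' @param corners 4x2 matrix of scan-area corners in nm (common frame, +y up);
#'   default is the 6.0 x 4.5 um^2 area spanning (-3000, 2250) .. (3000, -2250).
#' @param afmPixelSize AFM pixel size in nm (default 18.75).
#' @param opticalPixelSize optical pixel size in nm (default 83).
#' @param probeOrigin probe-spot position in optical pixels (col, row).
#' @return a \linkS4class{ScanGeometry}.
#' @export
scanGeometry <- function(corners = NULL, afmPixelSize = 18.75,
                         opticalPixelSize = 83,
                         probeOrigin = c(36.5, 27.5)) {
  if (is.null(corners))
    corners <- rbind(c(-3000, 2250), c(3000, 2250),
                     c(3000, -2250), c(-3000, -2250))
  new("ScanGeometry", corners = corners, afmPixelSize = afmPixelSize,
      opticalPixelSize = opticalPixelSize, probeOrigin = probeOrigin)
}

#' HeightMovie: a time-ordered stack of AFM height maps
#'
#' @slot frames numeric array rows x cols x frames, heights in nm.
#' @slot frameInterval seconds per frame.
#' @slot geometry a \linkS4class{ScanGeometry}.
#' @slot artifactLog data.frame logging injected/flagged scan artifacts
#'   (columns frame, row, width, type).
#' @export
setClass("HeightMovie", representation(
  frames = "array",
  frameInterval = "numeric",
  geometry = "ScanGeometry",
  artifactLog = "data.frame"
))

setValidity("HeightMovie", function(object) {
  msg <- NULL
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3-D array (rows x cols x frames)")
  if (any(!is.finite(object@frames))) msg <- c(msg, "heights must be finite")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' FluorMovie: per-channel fluorescence intensity stacks
#'
#' @slot channels named list of numeric arrays (rows x cols x frames), counts.
#' @slot frameInterval seconds per frame.
#' @slot pixelSize optical pixel size in nm.
#' @export
setClass("FluorMovie", representation(
  channels = "list",
  frameInterval = "numeric",
  pixelSize = "numeric"
))

setValidity("FluorMovie", function(object) {
  msg <- NULL
  ch <- object@channels
  if (length(ch)) {
    if (is.null(names(ch)) || any(names(ch) == ""))
      msg <- c(msg, "channels must be named")
    dims <- lapply(ch, dim)
    if (any(vapply(dims, length, 1L) != 3L))
      msg <- c(msg, "each channel must be rows x cols x frames")
    else if (length(unique(lapply(dims, identity))) != 1L)
      msg <- c(msg, "channels must share dimensions")
    if (any(vapply(ch, function(x) any(x < 0), logical(1))))
      msg <- c(msg, "intensities must be >= 0")
  }
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' RegistrationTransform: affine maps between pixel grids and the common frame
#'
#' Both maps are 3x3 homogeneous matrices taking (col, row, 1) pixel
#' coordinates (pixel centers at integer coordinates) to (x, y, 1) in nm.
#'
#' @slot afmToCommon 3x3 matrix, AFM pixels -> nm.
#' @slot opticalToCommon 3x3 matrix, optical pixels -> nm.
#' @slot timeOffset AFM-vs-optical scan start lag in seconds.
#' @export
setClass("RegistrationTransform", representation(
  afmToCommon = "matrix",
  opticalToCommon = "matrix",
  timeOffset = "numeric"
))

setValidity("RegistrationTransform", function(object) {
  msg <- NULL
  for (m in list(object@afmToCommon, object@opticalToCommon)) {
    if (!identical(dim(m), c(3L, 3L)) || abs(det(m)) < 1e-12)
      msg <- c(msg, "transform matrices must be invertible 3x3")
  }
  if (is.null(msg)) TRUE else msg
})

#' GroundTruth: generative record emitted with every simulated bundle
#'
#' @slot events data.frame, one row per event (identity, frames, geometry,
#'   motion labels, timing offsets).
#' @slot perFrame data.frame, one row per event per frame while the event is
#'   alive (position, aperture, open flag, swelling state, trace values).
#' @slot drift numeric n_frames x 2 matrix of cumulative stage drift (nm).
#' @slot artifactLog data.frame of injected artifacts.
#' @export
setClass("GroundTruth", representation(
  events = "data.frame",
  perFrame = "data.frame",
  drift = "matrix",
  artifactLog = "data.frame"
))

#' MovieBundle: one simulated acquisition
#'
#' @slot height a \linkS4class{HeightMovie}.
#' @slot fluor a \linkS4class{FluorMovie}.
#' @slot truth a \linkS4class{GroundTruth}.
#' @slot config the \linkS4class{SimulationConfig} echo.
#' @export
setClass("MovieBundle", representation(
  height = "HeightMovie",
  fluor = "FluorMovie",
  truth = "GroundTruth",
  config = "ANY"
))

setValidity("MovieBundle", function(object) {
  msg <- NULL
  nh <- dim(object@height@frames)[3]
  if (length(object@fluor@channels) &&
      dim(object@fluor@channels[[1]])[3] != nh)
    msg <- c(msg, "height and fluorescence stacks must share n_frames")
  if (nrow(object@truth@drift) != nh)
    msg <- c(msg, "drift series length must equal n_frames")
  if (is.null(msg)) TRUE else msg
})

## ------------------------------------------------------------------ accessors

#' @describeIn HeightMovie number of frames
#' @param x a movie object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setMethod("nFrames", "HeightMovie", function(x) dim(x@frames)[3])

#' @export
setMethod("nFrames", "FluorMovie", function(x)
  if (length(x@channels)) dim(x@channels[[1]])[3] else 0L)

#' @export
setMethod("nFrames", "MovieBundle", function(x) nFrames(x@height))

#' Extract one height frame (matrix, nm)
#' @param x a HeightMovie (or MovieBundle).
#' @param i frame index.
#' @export
setGeneric("heightFrame", function(x, i) standardGeneric("heightFrame"))

#' @export
setMethod("heightFrame", "HeightMovie", function(x, i) x@frames[, , i])

#' @export
setMethod("heightFrame", "MovieBundle", function(x, i) x@height@frames[, , i])

#' Frame interval accessor (seconds)
#' @param x a movie or bundle.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @export
setMethod("frameInterval", "HeightMovie", function(x) x@frameInterval)
#' @export
setMethod("frameInterval", "FluorMovie", function(x) x@frameInterval)
#' @export
setMethod("frameInterval", "MovieBundle", function(x) x@height@frameInterval)

#' Ground-truth accessor
#' @param x a MovieBundle.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @export
setMethod("groundTruth", "MovieBundle", function(x) x@truth)

setMethod("show", "HeightMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("HeightMovie: %d x %d px, %d frames @ %.3g s, pixel %.4g nm\n",
              d[1], d[2], d[3], object@frameInterval,
              object@geometry@afmPixelSize))
  cat(sprintf("  height range: [%.2f, %.2f] nm; %d logged artifacts\n",
              min(object@frames), max(object@frames),
              nrow(object@artifactLog)))
})

setMethod("show", "FluorMovie", function(object) {
  cat(sprintf("FluorMovie: channels [%s], %d frames @ %.3g s, pixel %.4g nm\n",
              paste(names(object@channels), collapse = ", "),
              nFrames(object), object@frameInterval, object@pixelSize))
})

setMethod("show", "MovieBundle", function(object) {
  cat("MovieBundle\n")
  show(object@height)
  show(object@fluor)
  cat(sprintf("  ground truth: %d events\n", nrow(object@truth@events)))
})
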