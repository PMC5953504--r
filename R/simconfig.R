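#' SimulationConfig: all knobs of the synthetic acquisition
#'
#' Bundles scan geometry, event kinetics, motion-class mixture, mobility,
#' noise, artifact rates, per-channel timing offsets and pit geometry. The
#' defaults are the study conditions of the hybrid imaging experiment this
#' package quantifies (see the methods vignette): a 6.0 x 4.5 um^2 scan at
#' 18.75 nm/pixel and 10 s/frame, CCP apertures 150-400 nm, lifetimes with
#' mean 81 s and SD 55 s on [40, 330] s, a closing-motion mixture of 54.9%
#' capping / 20% two-step / 10% re-opening, and mobilities of 7.3e-9 (CCP)
#' and 2.1e-9 (caveola) cm^2/s.
#'
#' @slot gridShape integer c(rows, cols) of the AFM grid.
#' @slot pixelSize AFM nm/pixel.
#' @slot frameInterval seconds per frame.
#' @slot nFrames number of frames.
#' @slot nEvents number of endocytic events to draw.
#' @slot mixture named list: motion-class probabilities (capping, two_step,
#'   reopen) and identity fraction ccp (caveola = 1 - ccp).
#' @slot mobility named list of diffusion coefficients in cm^2/s (ccp,
#'   caveola) plus the in-movie confinement radius (nm).
#' @slot driftVelocity nm/frame drift vector c(x, y).
#' @slot tipRadius nm.
#' @slot noise named list: sigmaZ (static membrane roughness RMS, nm),
#'   corrLength (nm), sigmaFrame (per-frame white height noise, nm),
#'   photonScale (peak photons of a unit-amplitude spot), background
#'   (photons/pixel), readSigma (camera read noise, counts).
#' @slot artifactRates named list: pSkip, pAmplitude per frame.
#' @slot timingParams named list per channel; see [defaultTimingParams()].
#' @slot geometryParams named list: apertureRange, caveolaRange, depth,
#'   swellingDiameter/Sd, swellingHeight/Sd, plateauDiameter/Sd,
#'   reopenGapRange (s), reopenDisplacementRange (nm), retentionMeanSd.
#' @slot channels character, fluorescence channels to render.
#' @slot seed integer RNG seed.
#' @slot preset condition preset name.
#' @export
setClass("SimulationConfig", representation(
  gridShape = "integer", pixelSize = "numeric", frameInterval = "numeric",
  nFrames = "integer", nEvents = "integer", mixture = "list",
  mobility = "list", driftVelocity = "numeric", tipRadius = "numeric",
  noise = "list", artifactRates = "list", timingParams = "list",
  geometryParams = "list", channels = "character", seed = "integer",
  preset = "character"
))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  mx <- object@mixture
  fr <- unlist(mx[c("capping", "two_step", "reopen")])
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "mixture fractions must be in [0,1]")
  if (mx$ccp < 0 || mx$ccp > 1) msg <- c(msg, "identity fraction ccp must be in [0,1]")
  if (object@tipRadius < 0) msg <- c(msg, "tipRadius must be >= 0")
  if (any(unlist(object@noise[c("sigmaZ", "sigmaFrame", "readSigma")]) < 0))
    msg <- c(msg, "noise sigmas must be >= 0")
  ar <- unlist(object@artifactRates)
  if (any(ar < 0 | ar > 1)) msg <- c(msg, "artifact rates must be in [0,1]")
  if (is.null(msg)) TRUE else msg
})

#' Default per-channel timing parameters
#'
#' Mean +/- SD offsets (seconds) of fluorescence appearance, peak and
#' disappearance for each protein channel, relative to the two AFM anchors:
#' appearance is anchored to invagination start for coat proteins (clathrin,
#' epsin, dynamin) and to closure for the actin burst; peak and disappearance
#' are anchored to closure. Signs follow the convention "negative = before
#' the anchor". Caveolin has no lifecycle timing (caveolae stay open).
#'
#' @return named list of per-channel parameter lists.
#' @export
defaultTimingParams <- function() {
  list(
    clathrin = list(anchor = "invagination",
                    app = c(-34, 13), peak = c(3, 7), dis = c(39, 13)),
    epsin    = list(anchor = "invagination",
                    app = c(-47, 9), peak = c(-14, 5), dis = c(13, 5)),
    dynamin  = list(anchor = "invagination",
                    app = c(-25, 12), peak = c(0, 5), dis = c(38, 9)),
    actin    = list(anchor = "closure",
                    app = c(-59, 18), peak = c(2.5, 7), dis = c(20, 7)),
    caveolin = list(anchor = "none",
                    app = c(NA, NA), peak = c(NA, NA), dis = c(NA, NA))
  )
}

#' Build a simulation configuration
#'
#' All arguments have study-condition defaults; pass a `preset` to re-weight
#' the closing-motion mixture and kinetics the way the cytoskeleton/dynamin
#' perturbations did (see [motionPreset()]).
#'
#' @param gridShape c(rows, cols) (default 240 x 320 = 4.5 x 6.0 um).
#' @param pixelSize AFM nm/pixel.
#' @param frameInterval s/frame (10 s default; use 1-2 s for closing studies).
#' @param nFrames frames in the movie.
#' @param nEvents endocytic events to generate.
#' @param mixture motion/identity mixture overrides (named list).
#' @param mobility mobility overrides (named list, cm^2/s).
#' @param driftVelocity stage drift, nm/frame.
#' @param tipRadius AFM tip radius, nm.
#' @param noise noise overrides (named list).
#' @param artifactRates artifact-rate overrides (named list).
#' @param timingParams channel timing overrides.
#' @param geometryParams geometry overrides.
#' @param channels fluorescence channels to render.
#' @param seed integer seed.
#' @param preset one of "untreated", "cytoB", "CK666", "jasp", "siDNM2".
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(gridShape = c(240L, 320L), pixelSize = 18.75,
                             frameInterval = 10, nFrames = 90L, nEvents = 20L,
                             mixture = list(), mobility = list(),
                             driftVelocity = c(0, 0), tipRadius = 10,
                             noise = list(), artifactRates = list(),
                             timingParams = list(), geometryParams = list(),
                             channels = c("clathrin", "caveolin"),
                             seed = 1L, preset = "untreated") {
  pre <- motionPreset(preset)
  mix <- utils::modifyList(pre$mixture, mixture)
  if (any(unlist(mix) < 0 | unlist(mix) > 1) || mix$capping + mix$reopen > 1)
    stop("unsatisfiable mixture: fractions exceed 1", call. = FALSE)
  mob <- utils::modifyList(
    list(ccp = 7.3e-9, caveola = 2.1e-9, confinementRadius = 75), mobility)
  noi <- utils::modifyList(
    list(sigmaZ = 2, corrLength = 100, sigmaFrame = 1,
         photonScale = 200, background = 20, readSigma = 2), noise)
  art <- utils::modifyList(list(pSkip = 0.01, pAmplitude = 0.005),
                           artifactRates)
  tim <- utils::modifyList(defaultTimingParams(), timingParams)
  geo <- utils::modifyList(utils::modifyList(list(
    apertureRange = c(150, 400), caveolaRange = c(80, 120), depth = 30,
    swellingDiameter = 378, swellingDiameterSd = 62,
    swellingHeight = 38, swellingHeightSd = 10,
    plateauDiameter = 120, plateauDiameterSd = 10,
    reopenGapRange = c(10, 70), reopenDisplacementRange = c(13, 113),
    retentionMeanSd = c(0.39, 0.18),
    closeEndFactor = 0.5, closeEndFloor = 170,
    misregistration = c(0, 0)
  ), pre$geometry), geometryParams)
  new("SimulationConfig",
      gridShape = as.integer(gridShape), pixelSize = pixelSize,
      frameInterval = frameInterval, nFrames = as.integer(nFrames),
      nEvents = as.integer(nEvents), mixture = mix, mobility = mob,
      driftVelocity = driftVelocity, tipRadius = tipRadius, noise = noi,
      artifactRates = art, timingParams = tim, geometryParams = geo,
      channels = channels, seed = as.integer(seed), preset = preset)
}

#' Condition presets for the closing-motion mixture
#'
#' Re-weightings of the motion mixture (and, for the dynamin knockdown, of
#' the small-aperture duration) representing the pharmacological and RNAi
#' perturbations as generator parameter sets: untreated 54.9% capping / 20%
#' two-step / 10% re-open; cytochalasin B collapses capping (~0.4%) and
#' raises re-opening to 67%; CK666 similarly (3% / 47%); jasplakinolide
#' prolongs lifetimes; dynamin knockdown halves capping (59% -> 35%) and
#' raises two-step with a prolonged small-aperture plateau.
#'
#' @param preset preset name.
#' @return list with elements `mixture`, `geometry`, `lifetimeScale`.
#' @export
motionPreset <- function(preset = c("untreated", "cytoB", "CK666",
                                    "jasp", "siDNM2")) {
  preset <- match.arg(preset)
  switch(preset,
    untreated = list(mixture = list(capping = 0.549, two_step = 0.20,
                                    reopen = 0.10, ccp = 1.0),
                     geometry = list(), lifetimeScale = 1),
    cytoB = list(mixture = list(capping = 0.004, two_step = 0.40,
                                reopen = 0.67, ccp = 1.0),
                 geometry = list(), lifetimeScale = 0.7),
    CK666 = list(mixture = list(capping = 0.03, two_step = 0.35,
                                reopen = 0.47, ccp = 1.0),
                 geometry = list(), lifetimeScale = 0.8),
    jasp = list(mixture = list(capping = 0.45, two_step = 0.20,
                               reopen = 0.12, ccp = 1.0),
                geometry = list(), lifetimeScale = 1.5),
    siDNM2 = list(mixture = list(capping = 0.35, two_step = 0.45,
                                 reopen = 0.12, ccp = 1.0),
                  geometry = list(plateauDurationRange = c(30, 90)),
                  lifetimeScale = 1.4)
  )
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig ('%s'): %d x %d px @ %.4g nm, %d frames @ %.3g s\n",
              object@preset, object@gridShape[1], object@gridShape[2],
              object@pixelSize, object@nFrames, object@frameInterval))
  cat(sprintf("  %d events; mixture capping %.1f%% two-step %.1f%% re-open %.1f%%; seed %d\n",
              object@nEvents, 100 * object@mixture$capping,
              100 * object@mixture$two_step, 100 * object@mixture$reopen,
              object@seed))
})

#' Serialize a configuration to a plain list (for the JSON config echo)
#' @param config a SimulationConfig.
#' @return a named list mirroring every slot.
#' @export
configAsList <- function(config) {
  sl <- methods::slotNames(config)
  stats::setNames(lapply(sl, function(s) methods::slot(config, s)), sl)
}
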