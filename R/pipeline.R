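## Orchestration: simulate -> analyze -> evaluate.

#' Simulate a bundle and write it to disk
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outdir output directory, or NULL to keep the bundle in memory.
#' @return the \linkS4class{MovieBundle} (invisibly when written).
#' @export
runSimulate <- function(config, outdir = NULL) {
  bundle <- generateDataset(config)
  if (!is.null(outdir)) {
    writeBundle(bundle, outdir)
    return(invisible(bundle))
  }
  bundle
}

#' Analyze a movie bundle (or bare movies) end to end
#'
#' Runs detection, tracking, identity assignment, per-detection section
#' morphometry with tip correction, AFM event times, fluorescence traces /
#' phase segmentation / relative timing for the lifecycle channel, swelling
#' detection and closing-motion classification, drift estimation, and
#' ensemble MSD/diffusion fits per identity class.
#'
#' @param height a \linkS4class{HeightMovie} or \linkS4class{MovieBundle}.
#' @param fluor a \linkS4class{FluorMovie} or NULL (AFM-only analysis).
#' @param params named list of overrides: tipRadius, rLink, gMax, rReopen,
#'   depthMin, minDiameter, driftMethod, nLags.
#' @return list of result tables (tracks, gaps, morphometry, identities,
#'   lifetimes, events, phases, timing, motions, motionSummary, drift,
#'   diffusion).
#' @export
runAnalyze <- function(height, fluor = NULL, params = list()) {
  if (methods::is(height, "MovieBundle")) {
    if (is.null(fluor)) fluor <- height@fluor
    height <- height@height
  }
  if (!is.null(fluor) && nFrames(fluor) &&
      nFrames(fluor) != nFrames(height))
    stop("geometry error: height and fluorescence stacks disagree in n_frames",
         call. = FALSE)
  p <- utils::modifyList(list(
    tipRadius = 10, rLink = 250, gMax = 7L, rReopen = 120,
    depthMin = 10, minDiameter = 60, driftMethod = "ensemble",
    nLags = 4L, minTrackFrames = 5L), params)
  dt <- height@frameInterval
  nf <- nFrames(height)
  px <- height@geometry@afmPixelSize
  transform <- buildTransform(height@geometry)

  staticBg <- staticBackground(height)
  det <- detectPitsMovie(height, depthMin = p$depthMin,
                         minDiameter = p$minDiameter)
  tracks <- linkTracks(det, rLink = p$rLink, gMax = p$gMax,
                       rReopen = p$rReopen)
  gaps <- attr(tracks, "gaps")

  ids <- unique(tracks$event_id)
  spl <- split(tracks, tracks$event_id)

  identities <- data.frame(event_id = ids, identity = NA_character_)
  for (i in seq_along(ids))
    identities$identity[i] <- assignIdentity(spl[[as.character(ids[i])]],
                                             fluor, transform,
                                             tipRadius = p$tipRadius)

  # morphometry: per-detection corrected diameters
  morph <- tracks[, c("event_id", "frame", "x", "y", "depth", "diameter")]
  morph$diameter_corrected <- ifelse(morph$diameter > 2 * p$tipRadius,
                                     morph$diameter - 2 * p$tipRadius,
                                     NA_real_)

  areaUm2 <- prod(dim(height@frames)[1:2]) * px^2 / 1e6
  lt <- lifetimeAndRate(tracks, areaUm2, nf * dt, dt, nf)

  # event times, traces, phases, timing
  evrows <- list(); phrows <- list(); tmrows <- list(); motrows <- list()
  for (i in seq_along(ids)) {
    tr <- spl[[as.character(ids[i])]]
    times <- tryCatch(detectEventTimes(tr, dt, nf), error = function(e) NULL)
    if (is.null(times)) next
    evrows[[i]] <- data.frame(event_id = ids[i],
                              t0_invagination = times$t0Invagination,
                              t0_closure = times$t0Closure,
                              censored = times$censored)
    traceNet <- NULL
    if (!is.null(fluor) && "clathrin" %in% names(fluor@channels) &&
        identities$identity[i] %in% c("CCP", "CCP-like")) {
      posm <- matrix(NA_real_, nf, 2)
      posm[tr$frame, 1] <- tr$x; posm[tr$frame, 2] <- tr$y
      # carry last known position through gaps and past closure
      for (k in seq_len(nf)) if (is.na(posm[k, 1]) && k > 1) posm[k, ] <- posm[k - 1, ]
      for (k in rev(seq_len(nf - 1))) if (is.na(posm[k, 1])) posm[k, ] <- posm[k + 1, ]
      tt <- extractTrace(fluor, "clathrin", posm, transform)
      traceNet <- ifelse(is.na(tt$net), 0, pmax(tt$net, 0))
      seg <- tryCatch(segmentPhases(traceNet, dt), error = function(e) NULL)
      if (!is.null(seg))
        phrows[[i]] <- data.frame(event_id = ids[i], growing_s = seg@growing,
                                  stable_s = seg@stable, closing_s = seg@closing)
      tm <- relativeTiming(tt, times, dt)
      if (!is.null(tm) && !times$censored)
        tmrows[[i]] <- cbind(event_id = ids[i], channel = "clathrin", tm)
    }
    if (!times$censored) {
      g <- gaps[gaps$event_id == ids[i], , drop = FALSE]
      sw <- detectSwelling(height, tr, staticBg = staticBg)
      ann <- tryCatch(classifyClosing(tr, g, sw, dt, nf, trace = traceNet,
                                      pixelSize = px),
                      error = function(e) NULL)
      if (!is.null(ann)) motrows[[i]] <- ann
    }
  }
  events <- do.call(rbind, evrows[!vapply(evrows, is.null, TRUE)])
  phases <- do.call(rbind, phrows[!vapply(phrows, is.null, TRUE)])
  timing <- do.call(rbind, tmrows[!vapply(tmrows, is.null, TRUE)])
  motions <- do.call(rbind, motrows[!vapply(motrows, is.null, TRUE)])

  # restrict the motion summary to CCP-class tracks
  motSum <- NULL
  if (!is.null(motions) && nrow(motions)) {
    ccpIds <- identities$event_id[identities$identity %in% c("CCP", "CCP-like")]
    mot <- motions[motions$event_id %in% ccpIds, , drop = FALSE]
    if (nrow(mot))
      motSum <- motionSummary(mot, lt$lifetimes)
  }

  drift <- tryCatch(estimateDrift(tracks, nf, p$driftMethod),
                    error = function(e) NULL)
  diffusion <- list()
  for (cls in c("CCP", "caveola")) {
    sel <- identities$event_id[identities$identity %in%
                                 c(cls, paste0(cls, "-like"))]
    sub <- tracks[tracks$event_id %in% sel, , drop = FALSE]
    est <- tryCatch({
      m <- ensembleMSD(sub, drift, dt, maxLag = p$nLags,
                       minFrames = p$minTrackFrames)
      fitDiffusion(m, p$nLags, class = cls)
    }, error = function(e) NULL)
    if (!is.null(est)) diffusion[[cls]] <- est
  }

  list(tracks = tracks, gaps = gaps, morphometry = morph,
       identities = identities, lifetimes = lt$lifetimes,
       formationFrequency = lt$formationFrequency,
       meanLifetime = lt$meanLifetime, events = events, phases = phases,
       timing = timing, motions = motions, motionSummary = motSum,
       drift = drift, diffusion = diffusion)
}

#' Score analysis results against the generator's ground truth
#'
#' Recovered tracks are matched to truth events greedily by mean centroid
#' distance (<= `matchRadius`); detection precision/recall are computed per
#' frame; the closing-motion labels form a per-label confusion table;
#' diameter RMSE and timing errors are reported for matched pairs.
#'
#' @param results list from [runAnalyze()].
#' @param truth a \linkS4class{GroundTruth} (or MovieBundle).
#' @param matchRadius nm.
#' @param dt frame interval, s.
#' @return list of metrics.
#' @export
runEvaluate <- function(results, truth, matchRadius = 150, dt = 10) {
  if (methods::is(truth, "MovieBundle")) {
    dt <- frameInterval(truth)
    truth <- truth@truth
  }
  pf <- truth@perFrame
  pfOpen <- pf[pf$open, , drop = FALSE]
  tracks <- results$tracks

  # per-frame detection matching
  tp <- 0L; fp <- 0L; fn <- 0L
  for (k in unique(c(tracks$frame, pfOpen$frame))) {
    dk <- tracks[tracks$frame == k, , drop = FALSE]
    tk <- pfOpen[pfOpen$frame == k, , drop = FALSE]
    if (!nrow(dk)) { fn <- fn + nrow(tk); next }
    if (!nrow(tk)) { fp <- fp + nrow(dk); next }
    dmat <- outer(dk$x, tk$x, "-")^2 + outer(dk$y, tk$y, "-")^2
    used <- logical(nrow(tk))
    for (i in seq_len(nrow(dk))) {
      j <- which.min(ifelse(used, Inf, dmat[i, ]))
      if (length(j) && dmat[i, j] <= matchRadius^2 && !used[j]) {
        tp <- tp + 1L; used[j] <- TRUE
      } else fp <- fp + 1L
    }
    fn <- fn + sum(!used)
  }
  precision <- if (tp + fp) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn) tp / (tp + fn) else NA_real_

  # track-to-event matching by mean centroid distance
  match <- data.frame(event_id = integer(), truth_event = integer(),
                      dist = numeric())
  spl <- split(tracks, tracks$event_id)
  for (id in names(spl)) {
    d <- spl[[id]]
    cand <- vapply(split(pfOpen, pfOpen$event), function(t0) {
      common <- intersect(d$frame, t0$frame)
      if (length(common) < 2) return(Inf)
      di <- d[match(common, d$frame), ]
      ti <- t0[match(common, t0$frame), ]
      mean(sqrt((di$x - ti$x)^2 + (di$y - ti$y)^2))
    }, numeric(1))
    if (!length(cand) || min(cand) > matchRadius) next
    match <- rbind(match, data.frame(
      event_id = as.integer(id),
      truth_event = as.integer(names(cand)[which.min(cand)]),
      dist = min(cand)))
  }
  # keep best recovered track per truth event
  match <- match[order(match$dist), ]
  match <- match[!duplicated(match$truth_event), , drop = FALSE]

  # diameter RMSE over matched open frames
  rmse <- NA_real_
  if (nrow(match)) {
    errs <- c()
    for (i in seq_len(nrow(match))) {
      d <- spl[[as.character(match$event_id[i])]]
      t0 <- pfOpen[pfOpen$event == match$truth_event[i], ]
      common <- intersect(d$frame, t0$frame)
      if (!length(common)) next
      errs <- c(errs, d$diameter[match(common, d$frame)] -
                  t0$aperture[match(common, t0$frame)])
    }
    errs <- errs[!is.na(errs)]
    if (length(errs)) rmse <- sqrt(mean(errs^2))
  }

  # closing-motion confusion per label
  conf <- NULL
  if (!is.null(results$motions) && nrow(match)) {
    ev <- truth@events
    mm <- merge(match, results$motions, by = "event_id")
    mm <- merge(mm, ev, by.x = "truth_event", by.y = "event")
    conf <- lapply(c("capping", "two_step", "reopen"), function(l) {
      pred <- mm[[paste0(l, ".x")]]
      tru <- mm[[paste0(l, ".y")]]
      if (is.null(pred)) { pred <- mm[[l]]; tru <- NULL }
      tab <- table(truth = factor(tru, c(FALSE, TRUE)),
                   predicted = factor(pred, c(FALSE, TRUE)))
      prec <- tab[2, 2] / max(sum(tab[, 2]), 1)
      rec <- tab[2, 2] / max(sum(tab[2, ]), 1)
      list(table = tab, precision = prec, recall = rec)
    })
    names(conf) <- c("capping", "two_step", "reopen")
  }

  list(detectionPrecision = precision, detectionRecall = recall,
       matches = match, nTruthEvents = nrow(truth@events),
       diameterRmse = rmse, motionConfusion = conf)
}
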