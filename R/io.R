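## Movie I/O: multi-page TIFF stacks with JSON metadata sidecars.
##
## AFM heights are stored as 32-bit float pages scaled to [0, 1] on a fixed
## 0.01 nm quantization grid (offset -100 nm), with the grid constants in
## the sidecar, so a write -> read round trip reproduces generator output
## exactly. Fluorescence channels are stored as 16-bit unsigned counts.

sidecarPath <- function(path) paste0(path, ".json")

requireKeys <- function(meta, keys) {
  missing <- setdiff(keys, names(meta))
  if (length(missing))
    stop("missing metadata key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
}

#' Write a movie to disk
#'
#' A \linkS4class{HeightMovie} becomes `<path>` (multi-page 32-bit float
#' TIFF) plus `<path>.json` (pixel size, frame interval, scan corners,
#' height quantization constants, artifact log). A \linkS4class{FluorMovie}
#' becomes one 16-bit TIFF per channel, `<path>_<channel>.tif`, plus
#' `<path>.json`.
#'
#' @param movie a HeightMovie or FluorMovie.
#' @param path output path (TIFF for height; prefix for fluorescence).
#' @return invisibly, the sidecar path.
#' @export
writeMovie <- function(movie, path) {
  if (methods::is(movie, "HeightMovie")) {
    fr <- movie@frames
    pages <- lapply(seq_len(dim(fr)[3]), function(k) {
      k01 <- (fr[, , k] - HEIGHT_OFFSET_NM) / HEIGHT_STEP_NM / HEIGHT_MAXCODE
      pmin(pmax(k01, 0), 1)
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    meta <- list(kind = "height", pixel_size_nm = movie@geometry@afmPixelSize,
                 frame_interval_s = movie@frameInterval,
                 n_frames = dim(fr)[3], shape = dim(fr)[1:2],
                 height_offset_nm = HEIGHT_OFFSET_NM,
                 height_step_nm = HEIGHT_STEP_NM,
                 height_maxcode = HEIGHT_MAXCODE,
                 corners_nm = movie@geometry@corners,
                 optical_pixel_size_nm = movie@geometry@opticalPixelSize,
                 probe_origin_px = movie@geometry@probeOrigin,
                 artifact_log = movie@artifactLog)
  } else if (methods::is(movie, "FluorMovie")) {
    for (ch in names(movie@channels)) {
      pages <- lapply(seq_len(nFrames(movie)), function(k)
        pmin(movie@channels[[ch]][, , k] / 65535, 1))
      tiff::writeTIFF(pages, paste0(path, "_", ch, ".tif"),
                      bits.per.sample = 16L, compression = "none",
                      reduce = FALSE)
    }
    meta <- list(kind = "fluor", channels = names(movie@channels),
                 pixel_size_nm = movie@pixelSize,
                 frame_interval_s = movie@frameInterval,
                 n_frames = nFrames(movie),
                 shape = dim(movie@channels[[1]])[1:2])
  } else stop("unsupported movie class", call. = FALSE)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(sidecarPath(path))
}

#' Read a movie written by [writeMovie()]
#'
#' @param path the path given to [writeMovie()].
#' @param kind "height" or "fluor"; defaults to the sidecar's kind.
#' @return a \linkS4class{HeightMovie} or \linkS4class{FluorMovie}.
#' @export
readMovie <- function(path, kind = NULL) {
  sc <- sidecarPath(path)
  if (!file.exists(sc))
    stop("missing metadata sidecar '", sc, "'; required keys: kind, ",
         "pixel_size_nm, frame_interval_s, n_frames, shape", call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  requireKeys(meta, c("kind", "pixel_size_nm", "frame_interval_s",
                      "n_frames", "shape"))
  if (is.null(kind)) kind <- meta$kind
  if (kind == "height") {
    requireKeys(meta, c("height_offset_nm", "height_step_nm", "height_maxcode"))
    pages <- tiff::readTIFF(path, all = TRUE)
    shapes <- unique(lapply(pages, dim))
    if (length(shapes) != 1L)
      stop("format error: TIFF pages differ in shape", call. = FALSE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) {
      kcode <- round(pages[[k]] * meta$height_maxcode)
      arr[, , k] <- kcode * meta$height_step_nm + meta$height_offset_nm
    }
    alog <- if (!is.null(meta$artifact_log) && length(meta$artifact_log))
      as.data.frame(meta$artifact_log) else
      data.frame(frame = integer(), row = integer(), width = integer(),
                 type = character(), stringsAsFactors = FALSE)
    geom <- scanGeometry(
      corners = if (!is.null(meta$corners_nm)) matrix(unlist(meta$corners_nm), 4, 2) else NULL,
      afmPixelSize = meta$pixel_size_nm,
      opticalPixelSize = if (!is.null(meta$optical_pixel_size_nm))
        meta$optical_pixel_size_nm else 83,
      probeOrigin = if (!is.null(meta$probe_origin_px))
        unlist(meta$probe_origin_px) else c(0, 0))
    new("HeightMovie", frames = arr, frameInterval = meta$frame_interval_s,
        geometry = geom, artifactLog = alog)
  } else {
    requireKeys(meta, "channels")
    chn <- meta$channels
    channels <- stats::setNames(lapply(chn, function(ch) {
      pages <- tiff::readTIFF(paste0(path, "_", ch, ".tif"), all = TRUE)
      shapes <- unique(lapply(pages, dim))
      if (length(shapes) != 1L)
        stop("format error: TIFF pages differ in shape", call. = FALSE)
      arr <- array(0, c(dim(pages[[1]]), length(pages)))
      for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * 65535)
      arr
    }), chn)
    new("FluorMovie", channels = channels,
        frameInterval = meta$frame_interval_s, pixelSize = meta$pixel_size_nm)
  }
}

#' Write a full simulated bundle to a directory
#'
#' Writes `afm.tif` (+ sidecar), `fluor_<channel>.tif` (+ sidecar),
#' `ground_truth.json` and `config.json`.
#'
#' @param bundle a \linkS4class{MovieBundle}.
#' @param outdir output directory (created if needed).
#' @return invisibly, `outdir`.
#' @export
writeBundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeMovie(bundle@height, file.path(outdir, "afm.tif"))
  writeMovie(bundle@fluor, file.path(outdir, "fluor"))
  tr <- bundle@truth
  jsonlite::write_json(
    list(events = tr@events, perFrame = tr@perFrame,
         drift = tr@drift, artifactLog = tr@artifactLog),
    file.path(outdir, "ground_truth.json"),
    digits = NA, dataframe = "columns", na = "null")
  jsonlite::write_json(configAsList(bundle@config),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}
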