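# Calibrated I/O. Images travel as (OME-)TIFF with a YAML sidecar carrying
# the calibration and intensity scale (r-tiff stores float samples clipped
# to [0, 1], so intensities are rescaled on write and restored on read);
# height maps as plain-text matrices or single-page TIFF; tables as CSV.
# Calibration is never silently defaulted: reading fails unless the pixel
# size is present in metadata (TIFF resolution tags or sidecar) or supplied
# as an override.

sidecarPath <- function(path) paste0(path, ".yml")

pixelSizeFromTiffInfo <- function(a) {
  xr <- a$x.resolution
  if (is.null(xr) || !is.finite(xr) || xr <= 0) return(NULL)
  unit <- a$resolution.unit
  if (is.null(unit)) return(NULL)
  switch(unit, cm = 1e4 / xr, inch = 25400 / xr, NULL)
}

#' Read a calibrated image stack from (OME-)TIFF
#'
#' TIFF pages map to `(time, channel)` with channel varying fastest; the
#' page layout and calibration are taken from the YAML sidecar written by
#' [writeImageStack()] when present, else from the TIFF resolution tags,
#' else from the overrides.
#'
#' @param path TIFF file
#' @param pixelSize um/px override (required when no metadata carries it)
#' @param frameInterval s/frame override
#' @param nChannels number of channels the pages interleave (override)
#' @param channelLabels channel names (override)
#' @return an [ImageStack-class]
#' @export
readImageStack <- function(path, pixelSize = NULL, frameInterval = NULL,
                           nChannels = NULL, channelLabels = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("format error reading '", path, "': ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(sidecarPath(path)))
    meta <- yaml::read_yaml(sidecarPath(path))
  if (is.null(pixelSize))
    pixelSize <- meta$pixel_size_um %||%
      pixelSizeFromTiffInfo(attributes(pages[[1L]]))
  if (is.null(pixelSize))
    stop("calibration error: no pixel size in metadata for '", path,
         "' and no override supplied")
  frameInterval <- frameInterval %||% meta$frame_interval_s %||% 0
  nChannels <- nChannels %||% meta$n_channels %||% 1L
  channelLabels <- channelLabels %||% unlist(meta$channel_labels) %||%
    paste0("ch", seq_len(nChannels))
  scale <- meta$intensity_scale %||% 1
  if (length(pages) %% nChannels != 0L)
    stop("format error: ", length(pages), " pages are not a multiple of ",
         nChannels, " channels")
  nT <- length(pages) %/% nChannels
  shp <- dim(pages[[1L]])[1:2]
  px <- array(0, c(nT, nChannels, shp))
  for (t in seq_len(nT)) for (c in seq_len(nChannels)) {
    pg <- pages[[(t - 1L) * nChannels + c]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # grayscale stored as RGB
    px[t, c, , ] <- pg * scale
  }
  ImageStack(px, pixelSize, frameInterval, channelLabels)
}

#' Write an ImageStack as TIFF plus a YAML calibration sidecar
#'
#' Pages are written `(time, channel)` with channel fastest, as 32-bit
#' float samples rescaled to `[0, 1]`; the scale factor, pixel size, frame
#' interval and channel labels go to `<path>.yml`.
#'
#' @param stack an [ImageStack-class]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
writeImageStack <- function(stack, path) {
  px <- pixels(stack)
  scale <- max(px, 1e-12)
  pages <- list()
  for (t in seq_len(dim(px)[1L])) for (c in seq_len(dim(px)[2L]))
    pages[[length(pages) + 1L]] <- px[t, c, , ] / scale
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  yaml::write_yaml(list(pixel_size_um = pixelSize(stack),
                        frame_interval_s = frameInterval(stack),
                        n_channels = dim(px)[2L],
                        channel_labels = as.list(channelLabels(stack)),
                        intensity_scale = scale),
                   sidecarPath(path))
  invisible(path)
}

#' Read an AFM height map
#'
#' Accepts a plain-text numeric matrix (whitespace- or comma-separated) or
#' a single-page TIFF of heights in nm.
#'
#' @param path input file; `.tif`/`.tiff` extensions are read as TIFF
#' @param pixelSize nm/px (required for text matrices; overrides TIFF tags)
#' @param setpointLabel `"low"`, `"high"` or `"unspecified"`
#' @return a [HeightMap-class]
#' @export
readHeightMap <- function(path, pixelSize, setpointLabel = "unspecified") {
  isTiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (isTiff) {
    m <- tryCatch(tiff::readTIFF(path),
                  error = function(e) stop("format error reading '", path,
                                           "': ", conditionMessage(e)))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first)) "," else ""
    m <- tryCatch(as.matrix(utils::read.table(path, sep = sep,
                                              header = FALSE)),
                  error = function(e) stop("format error reading '", path,
                                           "': ", conditionMessage(e)))
  }
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
    stop("format error: non-numeric or non-finite heights in '", path, "'")
  HeightMap(m, pixelSize, setpointLabel)
}

#' Write a height map as a plain-text matrix
#'
#' @param map a [HeightMap-class]
#' @param path output path (tab-separated text)
#' @return `path`, invisibly
#' @export
writeHeightMap <- function(map, path) {
  utils::write.table(heights(map), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

measurementColumns <- c("unit_id", "condition", "replicate", "quantity",
                        "value", "units")

#' Validate a measurement table
#'
#' The canonical long-format table: one row per measured unit with columns
#' `unit_id`, `condition`, `replicate`, `quantity`, `value`, `units`; extra
#' columns are carried as annotations.
#'
#' @param table data.frame
#' @param conditionLevels optional declared set of condition labels; any
#'   other label is a schema error
#' @return the validated data.frame (invisibly unchanged)
#' @export
validateMeasurementTable <- function(table, conditionLevels = NULL) {
  missing <- setdiff(measurementColumns, names(table))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  if (nrow(table) && any(!is.finite(table$value)))
    stop("schema error: non-finite values")
  if (!is.null(conditionLevels) && nrow(table)) {
    bad <- setdiff(unique(table$condition), conditionLevels)
    if (length(bad))
      stop("schema error: unknown condition label(s) ",
           paste(bad, collapse = ", "))
  }
  invisible(table)
}

#' Read / write the canonical measurement CSV
#'
#' `readMeasurementTable(writeMeasurementTable(t, p))` is the identity,
#' including extra annotation columns.
#'
#' @param path CSV path
#' @param conditionLevels optional strict condition-label set
#' @return data.frame (see [validateMeasurementTable()])
#' @export
readMeasurementTable <- function(path, conditionLevels = NULL) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateMeasurementTable(t, conditionLevels)
  t
}

#' @rdname readMeasurementTable
#' @param table data.frame satisfying the measurement schema
#' @export
writeMeasurementTable <- function(table, path) {
  validateMeasurementTable(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a measurement table
#'
#' @param values numeric measurements
#' @param condition condition label(s)
#' @param quantity quantity name
#' @param units unit string
#' @param replicate replicate id(s)
#' @param unitId per-row unit ids (default sequential)
#' @return measurement data.frame
#' @export
measurementTable <- function(values, condition, quantity, units,
                             replicate = 1L, unitId = NULL) {
  n <- length(values)
  data.frame(unit_id = unitId %||% seq_len(n),
             condition = rep_len(condition, n),
             replicate = rep_len(replicate, n),
             quantity = rep_len(quantity, n),
             value = values,
             units = rep_len(units, n))
}

#' Read a YAML run configuration
#'
#' One YAML file per run; the CLI logs it verbatim at start and every CLI
#' flag mirrors a config key.
#'
#' @param path YAML file
#' @return named list
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

`%||%` <- function(a, b) if (is.null(a)) b else a
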