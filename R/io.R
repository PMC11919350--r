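# File formats: TIFF imagery (32-bit samples; multi-page for 4D fields and
# focal stacks), YAML sidecars and configuration, CSV pattern and emitter
# tables. Sidecars are one structured-text file per image artifact
# (diffable), schema-versioned as "plenoscope-sidecar-1".

SIDECAR_SCHEMA <- "plenoscope-sidecar-1"

configToList <- function(config) {
  list(objectiveMagnification = config@objectiveMagnification,
       objectiveNA = config@objectiveNA,
       mlaPitch = config@mlaPitch,
       pixelsPerLens = as.integer(config@pixelsPerLens),
       lensesPerTile = as.integer(config@lensesPerTile),
       totalMagnification = config@totalMagnification,
       refractiveIndex = config@refractiveIndex)
}

configFromList <- function(x) {
  do.call(OpticalConfig, x[c("objectiveMagnification", "objectiveNA",
                             "mlaPitch", "pixelsPerLens", "lensesPerTile",
                             "totalMagnification", "refractiveIndex")])
}

#' Read / write an optical configuration
#'
#' Key-value structured text (YAML). The packaged default
#' (`system.file("extdata", "instrument-default.yaml", package =
#' "plenoscope")`) reproduces a 20x / NA 0.75 instrument with a 100 um MLA
#' pitch, 15 px per lens and 140 lenses per tile.
#'
#' @param path file path.
#' @return `readOpticalConfig` returns an [OpticalConfig-class].
#' @export
readOpticalConfig <- function(path) {
  x <- yaml::read_yaml(path)
  configFromList(x$optics)
}

#' @param config an [OpticalConfig-class].
#' @rdname readOpticalConfig
#' @export
writeOpticalConfig <- function(config, path) {
  yaml::write_yaml(list(schema = SIDECAR_SCHEMA,
                        optics = configToList(config)), path)
  invisible(path)
}

sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path), ".yaml")

writeSidecar <- function(path, fields) {
  yaml::write_yaml(c(list(schema = SIDECAR_SCHEMA), fields),
                   sidecarPath(path))
}

readSidecar <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp)) stop("format error: missing sidecar ", sp)
  x <- yaml::read_yaml(sp)
  if (!identical(x$schema, SIDECAR_SCHEMA))
    stop("format error: sidecar schema mismatch in ", sp)
  x
}

# TIFF pages are written as 32-bit samples of (value - offset) / scale with
# offset = min(0, data minimum) and scale the next power of two above the
# maximum; the normalization lives in the sidecar. The tiff package stores
# normalized data as 32-bit fixed point, so imagery round-trips to within
# 2^-32 of the dynamic range (absolute error scale * 2^-32).
pageNorm <- function(pages) {
  mn <- min(vapply(pages, min, numeric(1)))
  offset <- min(0, mn)
  mx <- max(vapply(pages, max, numeric(1))) - offset
  scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
  list(offset = offset, scale = scale)
}

writePages <- function(pages, path, norm = pageNorm(pages)) {
  pages <- lapply(pages, function(p) {
    storage.mode(p) <- "double"
    (p - norm$offset) / norm$scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  norm
}

readPages <- function(path, norm = list(offset = 0, scale = 1)) {
  x <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(x)) x <- list(x)
  lapply(x, function(p) p * norm$scale + norm$offset)
}

normFrom <- function(meta) {
  if (is.null(meta$norm)) list(offset = 0, scale = 1)
  else list(offset = as.numeric(meta$norm$offset),
            scale = as.numeric(meta$norm$scale))
}

#' Read / write a raw sensor frame
#'
#' Single-page 32-bit TIFF plus a YAML sidecar carrying the acquisition
#' metadata (optical configuration, event, noise model).
#'
#' @param frame a [RawFrame-class].
#' @param path TIFF path; the sidecar is written beside it.
#' @return `readRawFrame` returns a [RawFrame-class].
#' @export
writeRawFrame <- function(frame, path) {
  norm <- writePages(list(framePixels(frame)), path)
  meta <- frame@metadata[setdiff(names(frame@metadata), "schema")]
  meta$norm <- norm
  writeSidecar(path, meta)
  invisible(path)
}

#' @rdname writeRawFrame
#' @export
readRawFrame <- function(path) {
  meta <- readSidecar(path)
  RawFrame(readPages(path, normFrom(meta))[[1]], metadata = meta)
}

#' Read / write a 4D light field as multi-page TIFF
#'
#' Page order is v-major: page index `(vIdx - 1) * P + uIdx` holds the
#' spatial slice at angular storage indices (uIdx, vIdx), so a 15 x 15
#' angular field yields 225 pages. The sidecar records the sampling,
#' angular count and provenance.
#'
#' @param lf a [LightField4D-class].
#' @param path TIFF path.
#' @return `readLightField` returns a [LightField4D-class].
#' @export
writeLightField <- function(lf, path) {
  d <- dim(lf@intensities)
  pages <- vector("list", d[3] * d[4])
  for (vI in seq_len(d[4]))
    for (uI in seq_len(d[3]))
      pages[[(vI - 1L) * d[3] + uI]] <- lf@intensities[, , uI, vI]
  norm <- writePages(pages, path)
  writeSidecar(path, list(kind = "lightfield4d",
                          sampleSampling = lf@sampleSampling,
                          angularCount = d[3],
                          norm = norm,
                          provenance = lf@provenance))
  invisible(path)
}

#' @rdname writeLightField
#' @export
readLightField <- function(path) {
  meta <- readSidecar(path)
  if (!identical(meta$kind, "lightfield4d"))
    stop("format error: sidecar kind is not lightfield4d")
  pages <- readPages(path, normFrom(meta))
  P <- as.integer(meta$angularCount)
  if (length(pages) != P^2)
    stop("format error: page count does not match angularCount^2")
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], P, P))
  for (vI in seq_len(P))
    for (uI in seq_len(P))
      arr[, , uI, vI] <- pages[[(vI - 1L) * P + uI]]
  LightField4D(arr, meta$sampleSampling,
               provenance = if (is.null(meta$provenance)) list()
                            else meta$provenance)
}

#' Read / write a focal stack as multi-page TIFF
#'
#' One page per plane; the per-page z values live in the sidecar and their
#' count must match the page count.
#'
#' @param stack a [FocalStack-class].
#' @param path TIFF path.
#' @return `readFocalStack` returns a [FocalStack-class].
#' @export
writeFocalStack <- function(stack, path) {
  d <- dim(stack@planes)
  pages <- lapply(seq_len(d[3]), function(i) stack@planes[, , i])
  norm <- writePages(pages, path)
  writeSidecar(path, list(kind = "focalstack", z = as.list(stack@z),
                          sampleSampling = stack@sampleSampling,
                          norm = norm))
  invisible(path)
}

#' @rdname writeFocalStack
#' @export
readFocalStack <- function(path) {
  meta <- readSidecar(path)
  if (!identical(meta$kind, "focalstack"))
    stop("format error: sidecar kind is not focalstack")
  pages <- readPages(path, normFrom(meta))
  z <- unlist(meta$z)
  if (length(pages) != length(z))
    stop("format error: sidecar z list length must equal page count")
  planes <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) planes[, , i] <- pages[[i]]
  FocalStack(planes, z, meta$sampleSampling)
}

#' Read / write a scan pattern as CSV
#'
#' Columns: mode, gx, gy, sx, sy, dx, dy (um), plus a header comment-free
#' attribute block in a YAML sidecar (overlap, subdivisions, tile FOV).
#'
#' @param pattern a [ScanPattern-class].
#' @param path CSV path.
#' @return `readScanPattern` returns a [ScanPattern-class].
#' @export
writeScanPattern <- function(pattern, path) {
  e <- patternEntries(pattern)
  # 17 significant digits make the decimal text round-trip doubles exactly
  e$dx <- formatC(e$dx, digits = 17, format = "g")
  e$dy <- formatC(e$dy, digits = 17, format = "g")
  utils::write.csv(e, path, row.names = FALSE)
  writeSidecar(path, list(kind = "scanpattern",
                          overlapFraction = pattern@overlapFraction,
                          subdivisions = as.integer(pattern@subdivisions),
                          tileFov = pattern@tileFov))
  invisible(path)
}

#' @rdname writeScanPattern
#' @export
readScanPattern <- function(path) {
  meta <- readSidecar(path)
  if (!identical(meta$kind, "scanpattern"))
    stop("format error: sidecar kind is not scanpattern")
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  ScanPattern(e, overlapFraction = meta$overlapFraction,
              subdivisions = as.integer(meta$subdivisions),
              tileFov = if (is.null(meta$tileFov)) NA_real_
                        else meta$tileFov)
}

#' Read / write a plain 2D image as TIFF
#'
#' Single-page 32-bit TIFF with a minimal sidecar carrying the
#' intensity normalization; used for mosaics and other derived imagery.
#'
#' @param image numeric matrix.
#' @param path TIFF path.
#' @return `readImage` returns a matrix.
#' @export
writeImage <- function(image, path) {
  m <- as.matrix(image)
  attributes(m) <- attributes(m)["dim"]
  norm <- writePages(list(m), path)
  writeSidecar(path, list(kind = "image", norm = norm))
  invisible(path)
}

#' @rdname writeImage
#' @export
readImage <- function(path) {
  meta <- readSidecar(path)
  readPages(path, normFrom(meta))[[1]]
}

#' Write a scene emitter table as CSV
#'
#' @param scene a [Scene-class].
#' @param path CSV path.
#' @export
writeEmitters <- function(scene, path) {
  utils::write.csv(emitters(scene), path, row.names = FALSE)
  invisible(path)
}
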