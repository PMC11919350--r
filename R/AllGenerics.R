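#' Sample-plane spatial sampling
#'
#' The lateral sampling step in the sample plane, i.e. the microlens pitch
#' demagnified by the total magnification. For the default instrument the
#' 100 um pitch corresponds to 3.1 um in the sample plane.
#'
#' @param object an [OpticalConfig-class] or [LightField4D-class].
#' @return length in um.
#' @export
setGeneric("sampleSampling", function(object) standardGeneric("sampleSampling"))

#' @rdname sampleSampling
setMethod("sampleSampling", "OpticalConfig", function(object) {
  object@mlaPitch / object@totalMagnification
})

#' @rdname sampleSampling
setMethod("sampleSampling", "LightField4D", function(object) {
  object@sampleSampling
})

#' Angular half-range of a light field
#'
#' Largest centered angular index: `(pixelsPerLens - 1) / 2`.
#'
#' @param object an [OpticalConfig-class] or [LightField4D-class].
#' @return integer half-range.
#' @export
setGeneric("uMax", function(object) standardGeneric("uMax"))

#' @rdname uMax
setMethod("uMax", "OpticalConfig", function(object) {
  (object@pixelsPerLens - 1L) %/% 2L
})

#' @rdname uMax
setMethod("uMax", "LightField4D", function(object) {
  (dim(object@intensities)[3] - 1L) %/% 2L
})

#' Angular sample count per axis
#' @param object an [OpticalConfig-class] or [LightField4D-class].
#' @return odd integer count.
#' @export
setGeneric("angularCount", function(object) standardGeneric("angularCount"))

#' @rdname angularCount
setMethod("angularCount", "OpticalConfig", function(object) object@pixelsPerLens)

#' @rdname angularCount
setMethod("angularCount", "LightField4D", function(object) {
  dim(object@intensities)[3]
})

#' Tile field of view
#'
#' Lateral extent of one captured tile in the sample plane:
#' `lensesPerTile * sampleSampling` (um).
#'
#' @param object an [OpticalConfig-class].
#' @return length in um.
#' @export
setGeneric("tileFov", function(object) standardGeneric("tileFov"))

#' @rdname tileFov
setMethod("tileFov", "OpticalConfig", function(object) {
  object@lensesPerTile * sampleSampling(object)
})

#' Emitter table of a scene
#' @param object a [Scene-class].
#' @return data.frame with columns x, y, z, intensity.
#' @export
setGeneric("emitters", function(object) standardGeneric("emitters"))

#' @rdname emitters
setMethod("emitters", "Scene", function(object) object@emitters)

#' Pattern entry table
#' @param object a [ScanPattern-class].
#' @return data.frame of ordered shift entries.
#' @export
setGeneric("patternEntries", function(object) standardGeneric("patternEntries"))

#' @rdname patternEntries
setMethod("patternEntries", "ScanPattern", function(object) object@entries)

#' Raw pixel matrix
#' @param object a [RawFrame-class].
#' @return intensity matrix.
#' @export
setGeneric("framePixels", function(object) standardGeneric("framePixels"))

#' @rdname framePixels
setMethod("framePixels", "RawFrame", function(object) object@pixels)

#' Depths of a focal stack
#' @param object a [FocalStack-class].
#' @return numeric vector of z, um.
#' @export
setGeneric("stackDepths", function(object) standardGeneric("stackDepths"))

#' @rdname stackDepths
setMethod("stackDepths", "FocalStack", function(object) object@z)

#' Plane of a focal stack
#' @param object a [FocalStack-class].
#' @param i plane index.
#' @return 2D image matrix.
#' @export
setGeneric("stackPlane", function(object, i) standardGeneric("stackPlane"))

#' @rdname stackPlane
setMethod("stackPlane", "FocalStack", function(object, i) {
  object@planes[, , i, drop = TRUE]
})

#' Tile positions of a mosaic layout
#' @param object a [MosaicLayout-class].
#' @return n x 2 matrix of (x, y) fine-pixel tile origins.
#' @export
setGeneric("tilePositions", function(object) standardGeneric("tilePositions"))

#' @rdname tilePositions
setMethod("tilePositions", "MosaicLayout", function(object) object@positions)

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig:", sprintf("%gx / NA %.2f", object@objectiveMagnification,
                                object@objectiveNA), "\n")
  cat(sprintf("  MLA pitch %g um, %d px/lens, %d lenses/tile\n",
              object@mlaPitch, object@pixelsPerLens, object@lensesPerTile))
  cat(sprintf("  sample sampling %.3g um (total magnification %.4g), n = %g\n",
              sampleSampling(object), object@totalMagnification,
              object@refractiveIndex))
})

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene '%s': %d emitters, extent x [%g, %g] y [%g, %g] um\n",
              object@label, nrow(object@emitters), object@extent[1],
              object@extent[2], object@extent[3], object@extent[4]))
  if (nrow(object@layout))
    cat(sprintf("  %d USAF tri-bar blocks (%d elements)\n",
                nrow(object@layout), nrow(object@layout) %/% 2L))
})

setMethod("show", "LightField4D", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("LightField4D: %d x %d lenses, %d x %d angular, %.3g um sampling\n",
              d[2], d[1], d[3], d[4], object@sampleSampling))
})

setMethod("show", "GridCalibration", function(object) {
  cat(sprintf(
    "GridCalibration: origin (%.2f, %.2f) px, pitch %.3f px, rotation %.4g rad\n",
    object@origin[1], object@origin[2], object@pitchPx, object@rotation))
  cat(sprintf("  %d x %d lenses, residual RMS %.3g px\n",
              object@nLenses[1], object@nLenses[2], object@residualRms))
})

setMethod("show", "ScanPattern", function(object) {
  e <- object@entries
  cat(sprintf("ScanPattern: %d entries (%s), n_sub = %d, overlap = %.3g\n",
              nrow(e), paste(unique(e$mode), collapse = "+"),
              object@subdivisions, object@overlapFraction))
})

setMethod("show", "FocalStack", function(object) {
  d <- dim(object@planes)
  cat(sprintf("FocalStack: %d planes of %d x %d px, z [%g, %g] um\n",
              d[3], d[2], d[1], min(object@z), max(object@z)))
})

setMethod("show", "MosaicLayout", function(object) {
  cat(sprintf("MosaicLayout: %d tiles, %d scored pairs (%d by phase correlation)\n",
              nrow(object@positions), nrow(object@pairScores),
              sum(object@pairScores$used == "phase")))
})
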