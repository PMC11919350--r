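#' @import methods
NULL

# ---------------------------------------------------------------------------
# Coordinate conventions, stated once and used everywhere:
#   * Images are R matrices [row, col] = [y, x]; origin top-left, y increases
#     downward. Sensor pixel centers sit at integer (row, col) coordinates.
#   * Sample-plane coordinates are in micrometers; a tile of nL lenses spans
#     [-W/2, W/2] per axis with W = nL * sampleSampling; lens (i, j)
#     (1-based col i = x, row j = y) covers the half-open cell
#     [x0 + (i-1)*ds, x0 + i*ds).
#   * Angular indices (u, v) are centered integers in [-uMax, uMax]; u is
#     parallax along x (columns), v along y (rows); storage index = u+uMax+1.
#   * Depth z is signed micrometers, positive toward the objective; z = 0 is
#     the native focal plane.
# ---------------------------------------------------------------------------

#' Optical configuration of a light-field microscope
#'
#' Bundles the instrument geometry used throughout the package: objective,
#' microlens array (MLA), sensor sampling under each lens, and the total
#' magnification from sample plane to MLA plane. The bundled default
#' reproduces a 20x NA 0.75 setup with a 100 um pitch MLA sampled by
#' 15x15 sensor pixels per lens and about 140 usable lenses per captured
#' tile, for which the pitch maps to 3.1 um in the sample plane.
#'
#' @slot objectiveMagnification nominal objective magnification.
#' @slot objectiveNA objective numerical aperture (0-1).
#' @slot mlaPitch microlens pitch, micrometers at the MLA plane.
#' @slot pixelsPerLens odd integer, sensor pixels under one lens per axis.
#' @slot lensesPerTile integer, microlenses per axis in one capture.
#' @slot totalMagnification sample plane to MLA plane magnification. Stored,
#'   not derived from relay focal lengths: the pitch-to-sample-plane mapping
#'   is taken as the defining calibration.
#' @slot refractiveIndex refractive index of the sample medium.
#' @export
setClass("OpticalConfig", slots = c(
  objectiveMagnification = "numeric",
  objectiveNA = "numeric",
  mlaPitch = "numeric",
  pixelsPerLens = "integer",
  lensesPerTile = "integer",
  totalMagnification = "numeric",
  refractiveIndex = "numeric"
))

setValidity("OpticalConfig", function(object) {
  msg <- character()
  if (length(object@pixelsPerLens) != 1L || object@pixelsPerLens < 3L ||
      object@pixelsPerLens %% 2L == 0L)
    msg <- c(msg, "pixelsPerLens must be odd and >= 3 (a center angular sample must exist)")
  if (!isTRUE(object@mlaPitch > 0))
    msg <- c(msg, "mlaPitch must be positive")
  if (!isTRUE(object@totalMagnification > 0))
    msg <- c(msg, "totalMagnification must be positive")
  if (!isTRUE(object@objectiveNA > 0 && object@objectiveNA < object@refractiveIndex))
    msg <- c(msg, "objectiveNA must satisfy 0 < NA < refractiveIndex")
  if (!isTRUE(object@lensesPerTile >= 1L))
    msg <- c(msg, "lensesPerTile must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param objectiveMagnification,objectiveNA,mlaPitch,pixelsPerLens,lensesPerTile,totalMagnification,refractiveIndex
#'   see slot documentation.
#' @return An `OpticalConfig` object.
#' @examples
#' cfg <- OpticalConfig()
#' sampleSampling(cfg)   # 3.1 um
#' @rdname OpticalConfig-class
#' @export
OpticalConfig <- function(objectiveMagnification = 20,
                          objectiveNA = 0.75,
                          mlaPitch = 100,
                          pixelsPerLens = 15L,
                          lensesPerTile = 140L,
                          totalMagnification = 100 / 3.1,
                          refractiveIndex = 1.0) {
  new("OpticalConfig",
      objectiveMagnification = as.numeric(objectiveMagnification),
      objectiveNA = as.numeric(objectiveNA),
      mlaPitch = as.numeric(mlaPitch),
      pixelsPerLens = as.integer(pixelsPerLens),
      lensesPerTile = as.integer(lensesPerTile),
      totalMagnification = as.numeric(totalMagnification),
      refractiveIndex = as.numeric(refractiveIndex))
}

#' Sensor noise model
#'
#' sCMOS-like camera model: photon shot noise (Poisson), Gaussian read noise,
#' linear gain and a constant dark offset. Defaults are typical sCMOS values
#' (read noise 2 counts, gain 1 count/photon, offset 100 counts) and are a
#' package choice, exposed in configuration.
#'
#' @slot photonNoise logical, apply Poisson noise to photon counts.
#' @slot readNoiseSd Gaussian read noise standard deviation, counts.
#' @slot gain counts per photon.
#' @slot offset dark level, counts.
#' @export
setClass("NoiseModel", slots = c(
  photonNoise = "logical",
  readNoiseSd = "numeric",
  gain = "numeric",
  offset = "numeric"
))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (!isTRUE(object@readNoiseSd >= 0)) msg <- c(msg, "readNoiseSd must be >= 0")
  if (!isTRUE(object@gain > 0)) msg <- c(msg, "gain must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param photonNoise,readNoiseSd,gain,offset see slot documentation.
#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(photonNoise = TRUE, readNoiseSd = 2, gain = 1,
                       offset = 100) {
  new("NoiseModel", photonNoise = photonNoise,
      readNoiseSd = as.numeric(readNoiseSd), gain = as.numeric(gain),
      offset = as.numeric(offset))
}

#' @details `noiseOff()` returns the identity model (no Poisson, no read
#' noise, gain 1, offset 0), under which raw rendering and rectification are
#' exact inverses.
#' @rdname NoiseModel-class
#' @export
noiseOff <- function() NoiseModel(photonNoise = FALSE, readNoiseSd = 0,
                                  gain = 1, offset = 0)

#' A 3D phantom scene
#'
#' A scene is a table of point emitters with sample-plane coordinates (um),
#' depth z (um) and intensity (photons), plus a lateral extent. Resolution
#' target scenes additionally carry the placement table of their tri-bar
#' elements so metrology can extract profiles at known positions.
#'
#' @slot emitters data.frame with columns x, y, z, intensity.
#' @slot extent numeric(4), c(xmin, xmax, ymin, ymax) in um.
#' @slot label free-text description.
#' @slot layout data.frame of USAF element placements (possibly empty):
#'   columns group, element, orientation ("h"/"v"), cx, cy, width.
#' @export
setClass("Scene", slots = c(
  emitters = "data.frame",
  extent = "numeric",
  label = "character",
  layout = "data.frame"
))

setValidity("Scene", function(object) {
  msg <- character()
  em <- object@emitters
  if (!all(c("x", "y", "z", "intensity") %in% names(em)))
    msg <- c(msg, "emitters needs columns x, y, z, intensity")
  else {
    if (nrow(em) && any(em$intensity < 0))
      msg <- c(msg, "emitter intensities must be >= 0")
    ex <- object@extent
    if (length(ex) != 4L)
      msg <- c(msg, "extent must be c(xmin, xmax, ymin, ymax)")
    else if (nrow(em) &&
             (any(em$x < ex[1] - 1e-9) || any(em$x > ex[2] + 1e-9) ||
              any(em$y < ex[3] - 1e-9) || any(em$y > ex[4] + 1e-9)))
      msg <- c(msg, "emitters must lie within extent")
  }
  if (length(msg)) msg else TRUE
})

#' @param emitters data.frame with columns x, y, z, intensity.
#' @param extent numeric(4) lateral bounding box, um.
#' @param label free-text description.
#' @param layout optional USAF placement table.
#' @rdname Scene-class
#' @export
Scene <- function(emitters, extent, label = "", layout = NULL) {
  if (is.null(layout))
    layout <- data.frame(group = integer(), element = integer(),
                         orientation = character(), cx = numeric(),
                         cy = numeric(), width = numeric())
  new("Scene", emitters = emitters, extent = as.numeric(extent),
      label = label, layout = layout)
}

#' A single acquisition event
#'
#' One capture: the mirror-induced lateral shift in the sample plane, an
#' exposure scale, and the RNG seed for the sensor noise of this frame. A
#' mirror tilt in the Fourier plane is modeled as a pure lateral shift of the
#' image on the MLA.
#'
#' @slot lateralShift numeric(2), c(dx, dy) um in the sample plane.
#' @slot exposureScale dimensionless exposure multiplier, > 0.
#' @slot seed integer RNG seed for this frame's noise.
#' @export
setClass("AcquisitionEvent", slots = c(
  lateralShift = "numeric",
  exposureScale = "numeric",
  seed = "integer"
))

setValidity("AcquisitionEvent", function(object) {
  if (!isTRUE(object@exposureScale > 0)) "exposureScale must be > 0" else TRUE
})

#' @param dx,dy lateral shift, um in the sample plane.
#' @param exposureScale exposure multiplier.
#' @param seed integer noise seed.
#' @rdname AcquisitionEvent-class
#' @export
acquisitionEvent <- function(dx = 0, dy = 0, exposureScale = 1, seed = 1L) {
  new("AcquisitionEvent", lateralShift = c(dx, dy),
      exposureScale = as.numeric(exposureScale), seed = as.integer(seed))
}

#' Raw sensor frame
#'
#' @slot pixels 2D non-negative intensity matrix (row = sensor y).
#' @slot metadata acquisition sidecar as a named list.
#' @export
setClass("RawFrame", slots = c(pixels = "matrix", metadata = "list"))

#' @param pixels intensity matrix.
#' @param metadata named list (sidecar fields).
#' @rdname RawFrame-class
#' @export
RawFrame <- function(pixels, metadata = list()) {
  new("RawFrame", pixels = pixels, metadata = metadata)
}

#' Rectified 4D light field
#'
#' Intensity field I(x, y, u, v) stored as a 4D array indexed
#' `[y, x, uIdx, vIdx]` with centered angular indices (storage index
#' uIdx = u + uMax + 1). Both angular axes have the same odd length.
#'
#' @slot intensities 4D array (ny, nx, nu, nv), non-negative.
#' @slot sampleSampling spatial sampling, um per lens in the sample plane.
#' @slot provenance list: calibration, acquisition metadata, tile origin.
#' @export
setClass("LightField4D", slots = c(
  intensities = "array",
  sampleSampling = "numeric",
  provenance = "list"
))

setValidity("LightField4D", function(object) {
  d <- dim(object@intensities)
  msg <- character()
  if (length(d) != 4L)
    msg <- c(msg, "intensities must be a 4D array (y, x, u, v)")
  else {
    if (d[3] != d[4] || d[3] %% 2L == 0L)
      msg <- c(msg, "angular axes must have equal odd length")
    if (any(object@intensities < 0))
      msg <- c(msg, "intensities must be >= 0")
  }
  if (!isTRUE(object@sampleSampling > 0))
    msg <- c(msg, "sampleSampling must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param intensities 4D array (y, x, u, v).
#' @param sampleSampling um per lens.
#' @param provenance named list.
#' @rdname LightField4D-class
#' @export
LightField4D <- function(intensities, sampleSampling, provenance = list()) {
  new("LightField4D", intensities = intensities,
      sampleSampling = as.numeric(sampleSampling), provenance = provenance)
}

#' Microlens grid calibration
#'
#' Result of fitting the MLA grid on a uniform-illumination (white) frame:
#' sensor position of the first lens center, pixel pitch, in-plane rotation,
#' usable lens counts and the RMS residual of the least-squares fit.
#'
#' @slot origin numeric(2), (x, y) sensor px of lens (1,1) center.
#' @slot pitchPx sensor pixels per lens.
#' @slot rotation grid rotation, radians.
#' @slot nLenses integer(2), usable lens count per axis (x, y).
#' @slot residualRms fit residual, px.
#' @export
setClass("GridCalibration", slots = c(
  origin = "numeric",
  pitchPx = "numeric",
  rotation = "numeric",
  nLenses = "integer",
  residualRms = "numeric"
))

setValidity("GridCalibration", function(object) {
  msg <- character()
  if (!isTRUE(object@pitchPx > 0)) msg <- c(msg, "pitchPx must be > 0")
  if (!isTRUE(object@residualRms >= 0)) msg <- c(msg, "residualRms must be >= 0")
  if (length(object@nLenses) != 2L || any(object@nLenses < 1L))
    msg <- c(msg, "nLenses must be two positive counts")
  if (length(msg)) msg else TRUE
})

#' @param origin,pitchPx,rotation,nLenses,residualRms see slot documentation.
#' @rdname GridCalibration-class
#' @export
GridCalibration <- function(origin, pitchPx, rotation, nLenses, residualRms) {
  new("GridCalibration", origin = as.numeric(origin),
      pitchPx = as.numeric(pitchPx), rotation = as.numeric(rotation),
      nLenses = as.integer(nLenses), residualRms = as.numeric(residualRms))
}

#' Focal stack
#'
#' Refocused images over a strictly increasing list of depths, all sharing
#' one shape and sample-plane sampling.
#'
#' @slot planes 3D array (ny, nx, nz).
#' @slot z numeric, depth of each plane, um, strictly increasing.
#' @slot sampleSampling um per pixel.
#' @export
setClass("FocalStack", slots = c(
  planes = "array",
  z = "numeric",
  sampleSampling = "numeric"
))

setValidity("FocalStack", function(object) {
  msg <- character()
  d <- dim(object@planes)
  if (length(d) != 3L) msg <- c(msg, "planes must be a 3D array (y, x, z)")
  else if (d[3] != length(object@z))
    msg <- c(msg, "number of planes must match length(z)")
  if (length(object@z) > 1L && any(diff(object@z) <= 0))
    msg <- c(msg, "z must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @param planes 3D array (y, x, plane).
#' @param z depths, um.
#' @param sampleSampling um per pixel.
#' @rdname FocalStack-class
#' @export
FocalStack <- function(planes, z, sampleSampling) {
  new("FocalStack", planes = planes, z = as.numeric(z),
      sampleSampling = as.numeric(sampleSampling))
}

#' Scan pattern
#'
#' Ordered list of mirror-induced lateral shifts. Each entry is tagged as
#' tile-scale or sub-pitch, with its tile grid index, sub-pitch raster index
#' and expected sample-plane displacement in um.
#'
#' @slot entries data.frame: mode ("tile"/"subpixel"), gx, gy, sx, sy, dx, dy.
#' @slot overlapFraction tile overlap fraction (tile mode).
#' @slot subdivisions sub-pitch refinement factor n (1 when unused).
#' @slot tileFov tile field of view per axis, um.
#' @export
setClass("ScanPattern", slots = c(
  entries = "data.frame",
  overlapFraction = "numeric",
  subdivisions = "integer",
  tileFov = "numeric"
))

setValidity("ScanPattern", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("mode", "gx", "gy", "sx", "sy", "dx", "dy")
  if (!all(need %in% names(e)))
    msg <- c(msg, paste("entries needs columns", paste(need, collapse = ", ")))
  else {
    if (nrow(e) && !all(is.finite(e$dx) & is.finite(e$dy)))
      msg <- c(msg, "shifts must be finite")
    n <- object@subdivisions
    if (nrow(e) && any(e$sx < 0 | e$sx >= n | e$sy < 0 | e$sy >= n))
      msg <- c(msg, "sub indices must lie in [0, n-1]")
    if (anyDuplicated(e[c("gx", "gy", "sx", "sy")]))
      msg <- c(msg, "(tile_index, sub_index) pairs must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' @param entries ordered entry data.frame (see slots).
#' @param overlapFraction,subdivisions,tileFov see slot documentation.
#' @rdname ScanPattern-class
#' @export
ScanPattern <- function(entries, overlapFraction = 0, subdivisions = 1L,
                        tileFov = NA_real_) {
  new("ScanPattern", entries = entries,
      overlapFraction = as.numeric(overlapFraction),
      subdivisions = as.integer(subdivisions), tileFov = as.numeric(tileFov))
}

#' Mosaic layout
#'
#' Global tile placement after stitching: per-tile positions on the fine
#' pixel canvas and the pairwise registration scores (normalized cross
#' correlation at the chosen offset) for every adjacent pair.
#'
#' @slot positions n x 2 matrix of (x, y) tile origins, fine px.
#' @slot pairScores data.frame: i, j, dy, dx, score, used ("phase"/"nominal").
#' @slot provenance list (pattern, sampling, anchor).
#' @export
setClass("MosaicLayout", slots = c(
  positions = "matrix",
  pairScores = "data.frame",
  provenance = "list"
))

setValidity("MosaicLayout", function(object) {
  msg <- character()
  if (ncol(object@positions) != 2L)
    msg <- c(msg, "positions must be an n x 2 matrix")
  if (nrow(object@pairScores) &&
      any(abs(object@pairScores$score) > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "scores must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @param positions n x 2 position matrix (x, y), fine px.
#' @param pairScores pairwise registration table (see slots).
#' @param provenance named list.
#' @rdname MosaicLayout-class
#' @export
MosaicLayout <- function(positions, pairScores, provenance = list()) {
  new("MosaicLayout", positions = positions, pairScores = pairScores,
      provenance = provenance)
}
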