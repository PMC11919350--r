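# Geometric-optics forward model. Each perspective is a pinhole view:
# defocus manifests purely as parallax (an emitter at depth z appears
# displaced by z * u * deltaTan in perspective u) plus microlens binning.
# No wave-optics blur, vignetting or apodization is modeled; emitter
# intensity is split equally across the angular samples.

#' Render a scene directly into a 4D light field
#'
#' For each emitter at (xe, ye, ze) and each angular index (u, v), deposits
#' intensity into the microlens cell containing
#' `(xe + ze*u*dTan - dx, ye + ze*v*dTan - dy)` where
#' `dTan = tan(asin(NA/n)) / uMax` and (dx, dy) is the mirror-induced
#' lateral shift of the acquisition event. Binning is nearest-cell
#' assignment of the sub-resolution emitter raster (box integration over the
#' lens footprint). Total deposited intensity per emitter equals
#' `intensity * exposureScale`, shared equally across angular samples;
#' emitters projecting outside the tile are silently clipped.
#'
#' The tile covers `[-W/2, W/2]` per axis, `W = lensesPerTile *
#' sampleSampling`, in the unshifted frame.
#'
#' @param scene a [Scene-class].
#' @param config an [OpticalConfig-class].
#' @param event an [AcquisitionEvent-class].
#' @return a [LightField4D-class].
#' @export
renderLightField <- function(scene, config, event = acquisitionEvent()) {
  stopifnot(is(scene, "Scene"), is(config, "OpticalConfig"),
            is(event, "AcquisitionEvent"))
  ds <- sampleSampling(config)
  nL <- config@lensesPerTile
  P <- config@pixelsPerLens
  um <- uMax(config)
  dtan <- .deltaTan(config)
  x0 <- -nL * ds / 2; y0 <- x0
  em <- emitters(scene)
  share <- em$intensity * event@exposureScale / P^2
  dx <- event@lateralShift[1]; dy <- event@lateralShift[2]
  arr <- array(0, c(nL, nL, P, P))
  if (nrow(em)) {
    if (all(em$z == 0)) {
      # planar in-focus scene: zero parallax, all perspectives identical
      ix <- as.integer(floor((em$x - dx - x0) / ds)) + 1L
      iy <- as.integer(floor((em$y - dy - y0) / ds)) + 1L
      img <- binAccumulate(iy, ix, share, nL, nL)
      arr <- array(img, c(nL, nL, P, P))
    } else {
      for (uI in seq_len(P)) {
        u <- uI - um - 1L
        ix <- as.integer(floor((em$x + em$z * u * dtan - dx - x0) / ds)) + 1L
        for (vI in seq_len(P)) {
          v <- vI - um - 1L
          iy <- as.integer(floor((em$y + em$z * v * dtan - dy - y0) / ds)) + 1L
          arr[, , uI, vI] <- binAccumulate(iy, ix, share, nL, nL)
        }
      }
    }
  }
  LightField4D(arr, ds, provenance = list(
    event = list(lateralShift = event@lateralShift,
                 exposureScale = event@exposureScale, seed = event@seed),
    origin = c(x0, y0), config = configToList(config)))
}

# Tile a 4D field (y, x, u, v) onto the 2D sensor: block (i, j) of
# pixelsPerLens^2 pixels holds the angular samples of lens (i, j), with v
# along sensor rows and u along columns.
lightFieldToSensor <- function(arr) {
  d <- dim(arr)
  m <- aperm(arr, c(4, 1, 3, 2))        # (v, y, u, x)
  dim(m) <- c(d[4] * d[1], d[3] * d[2])
  m
}

sensorToLightField <- function(m, P) {
  nY <- nrow(m) %/% P; nX <- ncol(m) %/% P
  dim(m) <- c(P, nY, P, nX)
  aperm(m, c(2, 4, 3, 1))               # back to (y, x, u, v)
}

#' Render a raw sensor frame
#'
#' Renders the 4D field and tiles it onto the sensor as
#' `pixelsPerLens x pixelsPerLens` blocks per microlens (lens grid
#' axis-aligned, first lens center at pixel `(P+1)/2`), then applies the
#' noise model: Poisson photon noise, gain, dark offset and Gaussian read
#' noise, seeded by the acquisition event. With [noiseOff()] the result
#' round-trips exactly through [rectify()].
#'
#' @inheritParams renderLightField
#' @param noise a [NoiseModel-class].
#' @return a [RawFrame-class] with sidecar metadata.
#' @export
renderRaw <- function(scene, config, event = acquisitionEvent(),
                      noise = NoiseModel()) {
  lf <- renderLightField(scene, config, event)
  m <- lightFieldToSensor(lf@intensities)
  m <- withSeed(event@seed, {
    if (noise@photonNoise)
      m <- matrix(rpois(length(m), m), nrow(m), ncol(m))
    m <- noise@gain * m + noise@offset
    if (noise@readNoiseSd > 0)
      m <- m + matrix(rnorm(length(m), 0, noise@readNoiseSd), nrow(m), ncol(m))
    m
  })
  RawFrame(m, metadata = list(
    schema = "plenoscope-sidecar-1",
    config = configToList(config),
    event = list(lateralShift = event@lateralShift,
                 exposureScale = event@exposureScale, seed = event@seed),
    noise = list(photonNoise = noise@photonNoise,
                 readNoiseSd = noise@readNoiseSd, gain = noise@gain,
                 offset = noise@offset),
    scene = scene@label))
}

#' Render an acquisition sequence
#'
#' One raw frame per scan-pattern entry, each with the entry's lateral shift
#' applied; per-frame noise seeds are derived deterministically from the
#' master seed.
#'
#' @inheritParams renderRaw
#' @param pattern a [ScanPattern-class] (non-empty).
#' @param seed master seed.
#' @return list of [RawFrame-class], in pattern order.
#' @export
renderSequence <- function(scene, config, pattern, noise = NoiseModel(),
                           seed = 1L) {
  e <- patternEntries(pattern)
  if (nrow(e) == 0L) stop("pattern must be non-empty")
  lapply(seq_len(nrow(e)), function(i) {
    ev <- acquisitionEvent(e$dx[i], e$dy[i], seed = splitSeed(seed, i))
    fr <- renderRaw(scene, config, ev, noise)
    fr@metadata$patternEntry <- as.list(e[i, ])
    fr
  })
}

#' Synthetic uniform-illumination calibration frame
#'
#' Emulates the white frame used for microlens grid calibration: under
#' uniform illumination each microlens images the pupil, producing one
#' smooth intensity peak per lens. The peak is modeled as a Gaussian of the
#' distance to the nearest lens center (width 0.25 pitch), on an arbitrary
#' rotated grid, plus sensor noise.
#'
#' @param config an [OpticalConfig-class].
#' @param origin numeric(2), (x, y) px of the first lens center; default
#'   centers lens (1,1) at `(P+1)/2`.
#' @param rotation grid rotation, radians.
#' @param nLenses lenses per axis; default `lensesPerTile`.
#' @param peak peak photon count per lens center.
#' @param noise a [NoiseModel-class].
#' @param seed noise seed.
#' @return a [RawFrame-class].
#' @export
renderWhiteFrame <- function(config, origin = NULL, rotation = 0,
                             nLenses = NULL, peak = 1000,
                             noise = noiseOff(), seed = 1L) {
  P <- config@pixelsPerLens
  if (is.null(nLenses)) nLenses <- config@lensesPerTile
  if (is.null(origin)) origin <- c((P + 1) / 2, (P + 1) / 2)
  H <- nLenses * P; W <- H
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  ct <- cos(rotation); st <- sin(rotation)
  # lattice coordinates (lens units) of every pixel
  qx <- (ct * (xs - origin[1]) + st * (ys - origin[2])) / P
  qy <- (-st * (xs - origin[1]) + ct * (ys - origin[2])) / P
  rx <- qx - round(qx); ry <- qy - round(qy)
  sigma <- 0.25
  m <- peak * exp(-(rx^2 + ry^2) / (2 * sigma^2))
  m <- withSeed(seed, {
    if (noise@photonNoise) m <- matrix(rpois(length(m), m), H, W)
    m <- noise@gain * m + noise@offset
    if (noise@readNoiseSd > 0)
      m <- m + matrix(rnorm(length(m), 0, noise@readNoiseSd), H, W)
    m
  })
  RawFrame(m, metadata = list(
    schema = "plenoscope-sidecar-1",
    config = configToList(config),
    white = list(origin = origin, rotation = rotation, nLenses = nLenses,
                 peak = peak)))
}
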