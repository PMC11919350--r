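# Mirror scan patterns: sub-pitch rasters for super-resolution, tile grids
# for extended field of view, and adaptive ROI-driven combinations. A tilt
# of the mirror in the Fourier plane is modeled as a pure lateral shift in
# the (sample-conjugate) MLA plane.

#' Sub-pitch scan pattern
#'
#' n^2 shifts of `(sx/n, sy/n) * sampleSampling`, sx, sy in 0..n-1, raster
#' (row-major, sx fastest) order: the n^2 residues of the sampling lattice
#' refined n-fold. For n = 3 on the default instrument each step is a third
#' of a microlens, i.e. `pixelsPerLens / 3 = 5` sensor pixels.
#'
#' @param n refinement factor per axis (>= 1).
#' @param config an [OpticalConfig-class].
#' @return a [ScanPattern-class] with n^2 entries.
#' @examples
#' subpixelPattern(3, OpticalConfig())  # 9 entries, 1.033 um step
#' @export
subpixelPattern <- function(n, config) {
  if (!isTRUE(n >= 1) || n != round(n)) stop("n must be a positive integer")
  n <- as.integer(n)
  ds <- sampleSampling(config)
  g <- expand.grid(sx = 0:(n - 1L), sy = 0:(n - 1L))
  e <- data.frame(mode = "subpixel", gx = 0L, gy = 0L, sx = g$sx, sy = g$sy,
                  dx = g$sx / n * ds, dy = g$sy / n * ds)
  ScanPattern(e, overlapFraction = 0, subdivisions = n,
              tileFov = tileFov(config))
}

#' Sensor-pixel size of one sub-pitch step
#' @inheritParams subpixelPattern
#' @return step in sensor pixels (`pixelsPerLens / n`).
#' @export
subpixelStepPx <- function(n, config) config@pixelsPerLens / n

#' Tile scan pattern for an extended field of view
#'
#' gx x gy tile centers on a centered grid with step
#' `tileFov * (1 - overlapFraction)`, serpentine-ordered (rows scanned
#' alternately left-right and right-left) to minimize mirror travel. The
#' default overlap of 0.217 makes a 5 x 5 grid of 450 um tiles span 1.86 mm
#' per axis.
#'
#' @param grid integer(2), tiles per axis (gx, gy).
#' @param overlapFraction fraction of tile FOV shared by adjacent tiles,
#'   in [0, 1).
#' @param config an [OpticalConfig-class].
#' @return a [ScanPattern-class] with gx*gy entries.
#' @export
tilePattern <- function(grid, overlapFraction = 0.217, config) {
  grid <- as.integer(rep(grid, length.out = 2))
  if (any(grid < 1L)) stop("grid counts must be >= 1")
  if (!isTRUE(overlapFraction >= 0 && overlapFraction < 1))
    stop("overlapFraction must lie in [0, 1)")
  fov <- tileFov(config)
  step <- fov * (1 - overlapFraction)
  cx <- (seq_len(grid[1]) - (grid[1] + 1) / 2) * step
  cy <- (seq_len(grid[2]) - (grid[2] + 1) / 2) * step
  rows <- lapply(seq_len(grid[2]), function(j) {
    ix <- seq_len(grid[1])
    if (j %% 2L == 0L) ix <- rev(ix)          # serpentine
    data.frame(mode = "tile", gx = ix, gy = j, sx = 0L, sy = 0L,
               dx = cx[ix], dy = cy[j])
  })
  ScanPattern(do.call(rbind, rows), overlapFraction = overlapFraction,
              subdivisions = 1L, tileFov = fov)
}

#' Total span of a tile pattern per axis
#' @inheritParams tilePattern
#' @return span in um: `tileFov * (1 + (g - 1) * (1 - overlap))`.
#' @export
tileSpan <- function(grid, overlapFraction = 0.217, config) {
  tileFov(config) * (1 + (grid - 1) * (1 - overlapFraction))
}

#' Adaptive ROI-driven scan pattern
#'
#' The minimal subset of [tilePattern()] tiles whose footprints intersect
#' any region of interest, each expanded with a sub-pitch raster of `nSub^2`
#' entries (tiles not touching a ROI are omitted). This is the
#' capture-only-what-matters strategy for sparse samples: large mirror
#' angles select tiles, small angles refine resolution locally.
#'
#' @param rois list of numeric(4) rectangles c(xmin, xmax, ymin, ymax), um,
#'   within the reachable field.
#' @param nSub sub-pitch refinement per tile (1 = plain tiles).
#' @param config an [OpticalConfig-class].
#' @param grid,overlapFraction the underlying full tile grid.
#' @return a [ScanPattern-class].
#' @export
adaptivePattern <- function(rois, nSub, config, grid = c(5L, 5L),
                            overlapFraction = 0.217) {
  base <- tilePattern(grid, overlapFraction, config)
  be <- patternEntries(base)
  fov <- base@tileFov
  grid <- as.integer(rep(grid, length.out = 2))
  reach <- c(range(be$dx) + c(-1, 1) * fov / 2,
             range(be$dy) + c(-1, 1) * fov / 2)
  sub <- patternEntries(subpixelPattern(nSub, config))
  hit <- logical(nrow(be))
  for (roi in rois) {
    if (roi[1] < reach[1] - 1e-9 || roi[2] > reach[2] + 1e-9 ||
        roi[3] < reach[3] - 1e-9 || roi[4] > reach[4] + 1e-9)
      stop("ROI outside the reachable field")
    hit <- hit | (be$dx - fov / 2 < roi[2] & be$dx + fov / 2 > roi[1] &
                  be$dy - fov / 2 < roi[4] & be$dy + fov / 2 > roi[3])
  }
  kept <- be[hit, , drop = FALSE]
  e <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i) {
    data.frame(mode = if (nSub > 1L) "subpixel" else "tile",
               gx = kept$gx[i], gy = kept$gy[i], sx = sub$sx, sy = sub$sy,
               dx = kept$dx[i] + sub$dx, dy = kept$dy[i] + sub$dy)
  }))
  if (is.null(e)) e <- be[integer(0), , drop = FALSE]
  ScanPattern(e, overlapFraction = overlapFraction,
              subdivisions = as.integer(nSub), tileFov = fov)
}

#' Mirror tilt to sample-plane shift
#'
#' Small-angle linear map between mirror tilt and the lateral shift it
#' produces in the sample plane: `shift = calibrationScale * angle` per
#' axis. The calibration scale is instrument-specific and user-supplied.
#'
#' @param angle tilt in mrad (scalar or length-2).
#' @param calibrationScale um of sample-plane shift per mrad.
#' @return shift in um, same shape as `angle`.
#' @export
tiltToShift <- function(angle, calibrationScale) {
  stopifnot(all(is.finite(angle)), is.finite(calibrationScale))
  calibrationScale * angle
}

#' @rdname tiltToShift
#' @param shift shift in um.
#' @export
shiftToTilt <- function(shift, calibrationScale) {
  stopifnot(all(is.finite(shift)), is.finite(calibrationScale),
            calibrationScale != 0)
  shift / calibrationScale
}
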