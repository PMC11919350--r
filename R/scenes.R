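# Phantom scenes: USAF tri-bar targets, bead fields, encapsulated-aggregate
# shells. All scenes are emitter tables in sample-plane um.

# Rasterize an axis-aligned rectangle into emitter points on a `raster`-pitch
# grid (points at cell centers, independent of the coarse sampling lattice).
rasterRect <- function(x1, x2, y1, y2, z, raster, intensity) {
  xs <- seq(x1 + raster / 2, x2 - raster / 4, by = raster)
  ys <- seq(y1 + raster / 2, y2 - raster / 4, by = raster)
  g <- expand.grid(x = xs, y = ys)
  data.frame(x = g$x, y = g$y, z = z, intensity = intensity)
}

# One tri-bar block. orientation "h": bars run along x, stacked in y
# (profile across bars is taken along y); "v" is the transpose. The block
# spans 5w x 5w (bar length 5w, three bars of width w separated by gaps w),
# centered at (cx, cy).
rasterTriBar <- function(cx, cy, width, orientation, z, raster, intensity) {
  L <- 5 * width
  offs <- c(-2, 0, 2) * width       # bar center offsets across the bars
  parts <- lapply(offs, function(o) {
    if (orientation == "h")
      rasterRect(cx - L / 2, cx + L / 2, cy + o - width / 2, cy + o + width / 2,
                 z, raster, intensity)
    else
      rasterRect(cx + o - width / 2, cx + o + width / 2, cy - L / 2, cy + L / 2,
                 z, raster, intensity)
  })
  do.call(rbind, parts)
}

#' Simulated USAF-1951 resolution target scene
#'
#' Builds a planar scene at depth `z` containing, for each requested element,
#' a horizontal and a vertical tri-bar block with bar width, gap and length
#' (5x width) following the USAF-1951 geometry, rasterized as dense emitters.
#' Blocks are shelf-packed (largest first) into the requested extent with a
#' padding of half a bar width around each block; the placement of every
#' block is recorded in the scene layout so metrology can extract profiles
#' at known positions. Overflowing the extent is a layout error.
#'
#' @param elements data.frame with columns group, element.
#' @param z target depth, um.
#' @param extent lateral extent of the (square) scene, um.
#' @param raster rasterization pitch, um (must be <= 0.25 so bars down to
#'   2.19 um are supersampled at least 8-fold). The default, a fifteenth of
#'   the 3.1 um instrument sampling, divides both the microlens cell and its
#'   3-fold sub-pitch refinement exactly, so box integration over any cell
#'   captures the same raster density regardless of phase.
#' @param intensity photons per raster point.
#' @return a [Scene-class] with a populated layout table.
#' @examples
#' sc <- makeUsafScene(data.frame(group = 7, element = 6), extent = 40)
#' @export
makeUsafScene <- function(elements, z = 0, extent = 186, raster = 3.1 / 15,
                          intensity = 50) {
  if (is.null(nrow(elements)) || nrow(elements) == 0L)
    stop("layout error: empty element list")
  if (raster > 0.25) stop("raster pitch must be <= 0.25 um")
  ord <- elements[order(-usafLineWidth(elements$group, elements$element)), ,
                  drop = FALSE]
  x0 <- -extent / 2; y0 <- -extent / 2
  # shelf packing of combined blocks (H beside V): 12w x 6w incl. padding
  penX <- x0; penY <- y0; shelfH <- 0
  layout <- NULL
  for (i in seq_len(nrow(ord))) {
    w <- usafLineWidth(ord$group[i], ord$element[i])
    bw <- 12 * w; bh <- 6 * w
    if (penX + bw > x0 + extent + 1e-9) {     # new shelf
      penX <- x0
      penY <- penY + shelfH
      shelfH <- 0
    }
    if (penX + bw > x0 + extent + 1e-9 || penY + bh > y0 + extent + 1e-9)
      stop("layout error: elements do not fit in the scene extent")
    hx <- penX + 0.5 * w + 2.5 * w            # H block center
    vx <- penX + 6.5 * w + 2.5 * w            # V block center
    cy <- penY + 0.5 * w + 2.5 * w
    layout <- rbind(layout,
      data.frame(group = ord$group[i], element = ord$element[i],
                 orientation = c("h", "v"), cx = c(hx, vx), cy = cy,
                 width = w))
    penX <- penX + bw
    shelfH <- max(shelfH, bh)
  }
  em <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    rasterTriBar(layout$cx[i], layout$cy[i], layout$width[i],
                 layout$orientation[i], z, raster, intensity)
  }))
  Scene(em, extent = c(x0, x0 + extent, y0, y0 + extent),
        label = sprintf("USAF-1951 groups %s, %d elements, z = %g um",
                        paste(sort(unique(ord$group)), collapse = "+"),
                        nrow(ord), z),
        layout = layout)
}

#' Random bead field
#'
#' `n` point emitters placed uniformly in the given lateral extent and depth
#' range; deterministic for a fixed seed.
#'
#' @param n number of beads (>= 1).
#' @param extent lateral extent (square, centered), um.
#' @param zRange numeric(2) depth range, um.
#' @param seed integer seed.
#' @param intensity photons per bead.
#' @return a [Scene-class].
#' @export
makeBeadScene <- function(n, extent = 100, zRange = c(0, 0), seed = 1L,
                          intensity = 1e4) {
  stopifnot(n >= 1)
  withSeed(seed, {
    em <- data.frame(
      x = runif(n, -extent / 2, extent / 2),
      y = runif(n, -extent / 2, extent / 2),
      z = if (diff(range(zRange)) > 0) runif(n, zRange[1], zRange[2])
          else rep(zRange[1], n),
      intensity = rep(intensity, n))
    Scene(em, extent = c(-1, 1, -1, 1) * extent / 2,
          label = sprintf("%d beads, z in [%g, %g] um", n, min(zRange),
                          max(zRange)))
  })
}

# rasterize one nucleus as a small ball of emitters (visible blob rather
# than a single point)
rasterNucleus <- function(cx, cy, cz, radius, pitch, intensity) {
  s <- seq(-radius, radius, by = pitch)
  g <- expand.grid(x = s, y = s, z = s)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE]
  data.frame(x = cx + g$x, y = cy + g$y, z = cz + g$z,
             intensity = intensity / nrow(g))
}

#' Encapsulated multi-cellular aggregate phantom
#'
#' Emulates a population of alginate capsules containing cell aggregates:
#' capsules are placed without overlap on a jittered grid, and nuclei are
#' sampled on or just inside each capsule's spherical shell, reproducing the
#' hollow arrangement where cells sit close to the alginate wall.
#' Deterministic for a fixed seed.
#'
#' @param nCapsules number of capsules (>= 1).
#' @param capsuleRadius capsule radius, um.
#' @param nucleiPerCapsule nuclei per capsule (>= 1).
#' @param seed integer seed.
#' @param extent optional lateral extent, um; default sizes a jittered grid
#'   with cells 2.4 radii wide.
#' @param nucleusRadius nucleus radius, um.
#' @param intensity photons per nucleus.
#' @param shellIntensity photons per capsule-wall sample point; the alginate
#'   wall itself is visible in bright field, rendered as points scattered on
#'   the capsule sphere (0 disables the wall, e.g. for pure fluorescence).
#' @param shellSpacing approximate spacing of wall sample points, um.
#' @return a [Scene-class].
#' @export
makeAggregateScene <- function(nCapsules, capsuleRadius = 40,
                               nucleiPerCapsule = 30, seed = 1L,
                               extent = NULL, nucleusRadius = 2.5,
                               intensity = 2e4, shellIntensity = 300,
                               shellSpacing = 2.5) {
  stopifnot(nCapsules >= 1, nucleiPerCapsule >= 1)
  g <- ceiling(sqrt(nCapsules))
  cell <- 2.4 * capsuleRadius
  if (is.null(extent)) extent <- g * cell
  if (extent / g < 2 * capsuleRadius)
    stop("layout error: capsules cannot be placed without overlap")
  centers <- capsuleCenters(nCapsules, capsuleRadius, seed, extent)
  withSeed(splitSeed(seed, 1L), {
    shell <- NULL
    if (shellIntensity > 0) {
      nShell <- max(8L, round(4 * pi * capsuleRadius^2 / shellSpacing^2))
      shell <- do.call(rbind, lapply(seq_len(nCapsules), function(i) {
        phi <- runif(nShell, 0, 2 * pi)
        cosT <- runif(nShell, -1, 1)
        sinT <- sqrt(1 - cosT^2)
        data.frame(x = centers$x[i] + capsuleRadius * sinT * cos(phi),
                   y = centers$y[i] + capsuleRadius * sinT * sin(phi),
                   z = capsuleRadius * cosT,
                   intensity = shellIntensity)
      }))
    }
    em <- do.call(rbind, lapply(seq_len(nCapsules), function(i) {
      # uniform directions on the sphere; radius at 95-100% of the shell
      phi <- runif(nucleiPerCapsule, 0, 2 * pi)
      cosT <- runif(nucleiPerCapsule, -1, 1)
      sinT <- sqrt(1 - cosT^2)
      r <- capsuleRadius * runif(nucleiPerCapsule, 0.95, 1)
      do.call(rbind, lapply(seq_len(nucleiPerCapsule), function(k) {
        rasterNucleus(centers$x[i] + r[k] * sinT[k] * cos(phi[k]),
                      centers$y[i] + r[k] * sinT[k] * sin(phi[k]),
                      r[k] * cosT[k],
                      nucleusRadius, 1.25, intensity)
      }))
    }))
    # lateral extent can exceed the capsule grid by a nucleus radius
    pad <- nucleusRadius + 1e-6
    Scene(rbind(em, shell), extent = c(-1, 1, -1, 1) * (extent / 2 + pad),
          label = sprintf("%d capsules r=%g um, %d nuclei each, seed %d",
                          nCapsules, capsuleRadius, nucleiPerCapsule,
                          as.integer(seed)),
          layout = data.frame(group = integer(), element = integer(),
                              orientation = character(), cx = numeric(),
                              cy = numeric(), width = numeric()))
  })
}

#' Capsule centers of an aggregate phantom
#'
#' Deterministic capsule placement used by [makeAggregateScene()]: capsules
#' on a jittered grid, jitter bounded so footprints never overlap. Exposed so
#' adaptive scan planning and tests can target individual capsules.
#'
#' @inheritParams makeAggregateScene
#' @return data.frame with columns x, y (um).
#' @export
capsuleCenters <- function(nCapsules, capsuleRadius = 40, seed = 1L,
                           extent = NULL) {
  g <- ceiling(sqrt(nCapsules))
  if (is.null(extent)) extent <- g * 2.4 * capsuleRadius
  if (extent / g < 2 * capsuleRadius)
    stop("layout error: capsules cannot be placed without overlap")
  cellSize <- extent / g
  jitterMax <- cellSize / 2 - capsuleRadius
  withSeed(splitSeed(seed, 0L), {
    slots <- expand.grid(ix = seq_len(g), iy = seq_len(g))
    slots <- slots[sample.int(nrow(slots), nCapsules), , drop = FALSE]
    data.frame(
      x = -extent / 2 + (slots$ix - 0.5) * cellSize +
        runif(nCapsules, -jitterMax, jitterMax),
      y = -extent / 2 + (slots$iy - 0.5) * cellSize +
        runif(nCapsules, -jitterMax, jitterMax))
  })
}
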