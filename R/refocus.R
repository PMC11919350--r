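# Perspective extraction and shift-and-sum synthetic refocusing.

#' Extract a perspective (sub-aperture) image
#'
#' Spatial slice of the 4D field at a fixed angular index: the sample viewed
#' from one direction.
#'
#' @param lf a [LightField4D-class].
#' @param u,v centered angular indices in `[-uMax, uMax]`.
#' @return 2D image matrix (y, x).
#' @export
extractPerspective <- function(lf, u, v) {
  um <- uMax(lf)
  if (abs(u) > um || abs(v) > um || u != round(u) || v != round(v))
    stop("angular index out of range")
  lf@intensities[, , u + um + 1L, v + um + 1L, drop = TRUE]
}

#' Shift-and-sum synthetic refocusing
#'
#' Synthesizes the image focused at depth z by translating each perspective
#' (u, v) by `(-k*z*u, -k*z*v)` spatial samples (bilinear sub-sample
#' interpolation) and averaging. Out-of-frame samples are excluded from the
#' per-pixel mean (normalization by the valid weight), which avoids
#' vignette-like edge dimming in mosaics. At z = 0 this is the exact mean of
#' all perspectives.
#'
#' @param lf a [LightField4D-class].
#' @param z refocus depth, um (finite; positive toward the objective).
#' @param k disparity slope, samples per (angular step * um); defaults to
#'   [disparitySlope()] of the configuration recorded in the field's
#'   provenance when available.
#' @return 2D image matrix; pixels never covered by any perspective are 0.
#' @export
refocus <- function(lf, z, k = NULL) {
  stopifnot(is(lf, "LightField4D"), is.finite(z))
  if (is.null(k)) k <- .provenanceSlope(lf)
  P <- angularCount(lf)
  um <- uMax(lf)
  d <- dim(lf@intensities)
  acc <- matrix(0, d[1], d[2])
  wacc <- matrix(0, d[1], d[2])
  for (uI in seq_len(P)) {
    u <- uI - um - 1L
    for (vI in seq_len(P)) {
      v <- vI - um - 1L
      s <- shiftBilinear(lf@intensities[, , uI, vI], -k * z * v, -k * z * u)
      acc <- acc + s$image
      wacc <- wacc + s$weight
    }
  }
  out <- acc
  pos <- wacc > 0
  out[pos] <- acc[pos] / wacc[pos]
  out[!pos] <- 0
  out
}

# disparity slope from the config recorded at render/rectify time
.provenanceSlope <- function(lf) {
  cfg <- lf@provenance$config
  if (is.null(cfg)) cfg <- lf@provenance$metadata$config
  if (is.null(cfg))
    stop("no configuration in provenance; supply k explicitly")
  disparitySlope(configFromList(cfg))
}

#' Focal stack over a depth range
#'
#' [refocus()] applied over the inclusive range `zMin` to `zMax` in steps of
#' `dz`; plane count is `floor((zMax - zMin)/dz) + 1`.
#'
#' @inheritParams refocus
#' @param zMin,zMax depth range, um.
#' @param dz depth step, um (> 0).
#' @return a [FocalStack-class].
#' @export
focalStack <- function(lf, zMin, zMax, dz, k = NULL) {
  if (!isTRUE(dz > 0)) stop("dz must be > 0")
  if (zMax < zMin) stop("empty depth range")
  if (is.null(k)) k <- .provenanceSlope(lf)
  zs <- zMin + dz * seq(0L, floor((zMax - zMin) / dz + 1e-9))
  d <- dim(lf@intensities)
  planes <- array(0, c(d[1], d[2], length(zs)))
  for (i in seq_along(zs)) planes[, , i] <- refocus(lf, zs[i], k)
  FocalStack(planes, zs, lf@sampleSampling)
}

#' Depth of best focus
#'
#' The z of the focal-stack plane maximizing the variance of a 3x3 Laplacian
#' within the given window. Sharpness ties are broken toward the smallest
#' |z|, then toward the first plane.
#'
#' @param stack a [FocalStack-class].
#' @param window optional integer c(rowMin, rowMax, colMin, colMax) region;
#'   default is the full image.
#' @return depth z in um.
#' @export
bestFocusDepth <- function(stack, window = NULL) {
  d <- dim(stack@planes)
  if (is.null(window)) window <- c(1L, d[1], 1L, d[2])
  if (window[1] < 1L || window[2] > d[1] || window[3] < 1L || window[4] > d[2])
    stop("window outside the image")
  sharp <- vapply(seq_along(stack@z), function(i) {
    img <- stack@planes[window[1]:window[2], window[3]:window[4], i]
    stats::var(as.vector(laplacian3(img)))
  }, numeric(1))
  best <- which(sharp >= max(sharp) - 1e-12 * max(abs(sharp), 1))
  stack@z[best[order(abs(stack@z[best]))][1]]
}
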