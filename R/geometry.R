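#' Nyquist-limited lateral resolution
#'
#' Two-point resolution achievable at a given lateral sampling step under
#' Nyquist sampling: twice the step. At the default 3.1 um microlens
#' sampling this gives 6.2 um.
#'
#' @param sampling lateral sampling step, um (> 0).
#' @return resolution in um.
#' @examples
#' nyquistResolution(3.1)  # 6.2
#' @export
nyquistResolution <- function(sampling) {
  if (!all(is.finite(sampling)) || any(sampling <= 0))
    stop("sampling must be a positive length")
  2 * sampling
}

#' USAF-1951 single-bar line width
#'
#' The USAF-1951 chart defines element (group g, element e) as a tri-bar
#' pattern at `2^(g + (e - 1)/6)` line pairs per mm; the single-bar width is
#' therefore `500 / 2^(g + (e - 1)/6)` micrometers. Group 7 element 6 is
#' 2.19 um, group 6 element 3 is 6.20 um.
#'
#' @param group integer group index (may be negative).
#' @param element integer element index in 1..6.
#' @return line width in um (vectorized).
#' @examples
#' usafLineWidth(7, 6)  # 2.19
#' usafLineWidth(6, 3)  # 6.20
#' @export
usafLineWidth <- function(group, element) {
  if (any(element < 1 | element > 6) || any(element != round(element)))
    stop("element must be an integer in 1..6")
  500 / 2^(group + (element - 1) / 6)
}

#' Standard USAF element ordering
#'
#' All (group, element) pairs for the given groups, ordered by decreasing
#' line width (group ascending, element ascending).
#'
#' @param groups integer vector of groups.
#' @return data.frame with columns group, element, width (um).
#' @export
usafElements <- function(groups) {
  out <- expand.grid(element = 1:6, group = sort(groups))[, c("group", "element")]
  out$width <- usafLineWidth(out$group, out$element)
  out[order(-out$width), , drop = FALSE]
}

#' Disparity slope of the refocusing geometry
#'
#' Proportionality constant k linking depth to per-perspective lateral
#' shift: a point at depth z appears displaced by `k * z * u` spatial
#' samples in perspective u. Under the geometric model the marginal ray
#' angle is `tan(asin(NA / n))`, shared equally across the uMax outermost
#' angular samples, so
#' `k = tan(asin(NA / n)) / (uMax * sampleSampling)` per (angular index, um).
#'
#' @param config an [OpticalConfig-class].
#' @return slope k, samples per (angular step * um).
#' @examples
#' disparitySlope(OpticalConfig())  # ~0.0523
#' @export
disparitySlope <- function(config) {
  stopifnot(is(config, "OpticalConfig"))
  validObject(config)
  tanTheta <- tan(asin(config@objectiveNA / config@refractiveIndex))
  tanTheta / (uMax(config) * sampleSampling(config))
}

# tangent step between adjacent angular samples (sample-plane um of lateral
# displacement per um of depth, per unit angular index)
.deltaTan <- function(config) {
  tan(asin(config@objectiveNA / config@refractiveIndex)) / uMax(config)
}

#' Information bookkeeping for a combined scan
#'
#' Pixel counts for a combined extended-FOV plus sub-pitch acquisition: a
#' mosaic of `mosaicPx` coarse spatial samples, refined `nSub`-fold per axis,
#' each spatial sample carrying the full angular stack. For the default
#' instrument with a 600 x 550 coarse mosaic and 3-fold refinement this gives
#' 1800 x 1650 spatial samples (about 3 Mpixels) and 668.25 Mpixels in total.
#'
#' @param config an [OpticalConfig-class].
#' @param mosaicPx integer(2), coarse mosaic size in spatial samples (x, y).
#' @param nSub sub-pitch refinement factor.
#' @return list: spatialSamples (x, y), spatialMpixels, totalMpixels.
#' @export
scanInformation <- function(config, mosaicPx = c(600L, 550L), nSub = 3L) {
  fine <- as.integer(mosaicPx) * as.integer(nSub)
  spatial <- prod(fine)
  total <- spatial * as.numeric(config@pixelsPerLens)^2
  list(spatialSamples = fine,
       spatialMpixels = spatial / 1e6,
       totalMpixels = total / 1e6)
}
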