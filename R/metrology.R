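# Reconstruction quality metrology: tri-bar Michelson contrast, smallest
# resolvable USAF element, bead FWHM.

#' Michelson contrast of a tri-bar intensity profile
#'
#' Finds the `nBars` local maxima and the `nBars - 1` interleaved local
#' minima of the smoothed profile and returns the Michelson contrast
#' `(Imax - Imin) / (Imax + Imin)` of their means. Returns 0 when the
#' expected maximum/minimum alternation is absent (e.g. unresolved or
#' constant profiles). Smoothing is a fixed 3-sample moving average
#' (end samples averaged over the available 2): it suppresses single-sample
#' noise and alias structure, so a bar pattern needs about two samples per
#' bar to survive — the Nyquist-style requirement under which a tri-bar
#' element counts as resolved rather than aliased. Invariant to rescaling
#' the profile by a positive gain.
#'
#' @param profile 1D intensity trace across the bars (length >= 2*nBars+1).
#' @param nBars number of bars (3 for USAF elements).
#' @return contrast in [0, 1].
#' @examples
#' sq <- rep(c(0, 1, 0, 1, 0, 1, 0), each = 6)  # well-sampled 0/1 tri-bar
#' barContrast(sq, 3)  # 1
#' @export
barContrast <- function(profile, nBars = 3L) {
  profile <- as.numeric(profile)
  if (!any(is.finite(profile)) || all(profile == 0))
    stop("degenerate profile: all zero")
  if (length(profile) < 2L * nBars + 1L)
    stop("profile too short for the requested bar count")
  n <- length(profile)
  p <- as.numeric(stats::filter(profile, rep(1 / 3, 3), sides = 2))
  p[1] <- mean(profile[1:2])
  p[n] <- mean(profile[(n - 1L):n])
  # plateau-aware local maxima: runs of equal value strictly above both
  # neighboring runs, represented by their middle sample
  r <- rle(p)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  maxima <- integer(0)
  if (k >= 3L) {
    for (ri in 2:(k - 1L)) {
      if (r$values[ri] > r$values[ri - 1L] && r$values[ri] > r$values[ri + 1L])
        maxima <- c(maxima, (starts[ri] + ends[ri]) %/% 2L)
    }
  }
  if (length(maxima) < nBars) return(0)
  # keep the nBars strongest peaks, in spatial order
  maxima <- sort(maxima[order(p[maxima], decreasing = TRUE)][seq_len(nBars)])
  minima <- numeric(nBars - 1L)
  for (k in seq_len(nBars - 1L)) {
    seg <- p[(maxima[k] + 1L):(maxima[k + 1L] - 1L)]
    if (!length(seg)) return(0)
    minima[k] <- min(seg)
  }
  Imax <- mean(p[maxima]); Imin <- mean(minima)
  if (any(minima >= p[maxima[-length(maxima)]]) ||
      any(minima >= p[maxima[-1L]]))
    return(0)
  if (Imax + Imin <= 0) return(0)
  max(0, (Imax - Imin) / (Imax + Imin))
}

# Extract the across-bar profile of one placed tri-bar block from a
# reconstructed image. Coordinates: pixel (r, c) center is at
# origin + (c - 1/2) * sampling (x), origin + (r - 1/2) * sampling (y).
# The profile runs across the bars (y for "h" blocks, x for "v"), averaged
# over the central 60% of the bar length, extended half a bar width beyond
# the outer bars.
usafProfile <- function(image, placement, sampling, origin) {
  w <- placement$width
  L <- 5 * w
  across <- c(placement$cy, placement$cx)[1 + (placement$orientation == "v")]
  along <- c(placement$cx, placement$cy)[1 + (placement$orientation == "v")]
  lo <- across - 2.5 * w - 0.5 * w
  hi <- across + 2.5 * w + 0.5 * w
  aLo <- along - 0.3 * L; aHi <- along + 0.3 * L
  centers <- function(nPix, orig) orig + (seq_len(nPix) - 0.5) * sampling
  if (placement$orientation == "h") {
    ys <- centers(nrow(image), origin[2])
    xs <- centers(ncol(image), origin[1])
    rows <- which(ys >= lo & ys <= hi)
    cols <- which(xs >= aLo & xs <= aHi)
    if (length(rows) < 3L || !length(cols)) return(NULL)
    rowMeans(image[rows, cols, drop = FALSE])
  } else {
    xs <- centers(ncol(image), origin[1])
    ys <- centers(nrow(image), origin[2])
    cols <- which(xs >= lo & xs <= hi)
    rows <- which(ys >= aLo & ys <= aHi)
    if (length(cols) < 3L || !length(rows)) return(NULL)
    colMeans(image[rows, cols, drop = FALSE])
  }
}

#' Smallest resolvable USAF element of a reconstruction
#'
#' Walks the elements recorded in the scene layout in order of decreasing
#' line width; an element is resolved when both its horizontal and vertical
#' tri-bar profiles reach [barContrast()] of at least `threshold`. Returns
#' the last element resolved before the first failure (profiles are
#' extracted at the known simulated positions — no bar detection step).
#'
#' @param image reconstructed 2D image.
#' @param scene the [makeUsafScene()] scene the image was rendered from.
#' @param sampling um per image pixel (e.g. `sampleSampling` or, for a
#'   fused image, `sampleSampling / n`).
#' @param origin numeric(2) (x, y) um of the image grid origin (top-left
#'   cell edge); the unshifted tile has origin `-tileFov/2`, a fused image
#'   additionally shifts by [fusedOriginOffset()].
#' @param threshold Michelson contrast criterion, default 0.2.
#' @return one-row data.frame (group, element, lineWidth, contrastH,
#'   contrastV); group is NA when nothing is resolved.
#' @export
smallestResolvable <- function(image, scene, sampling, origin,
                               threshold = 0.2) {
  lay <- scene@layout
  if (!nrow(lay)) stop("scene has no recorded USAF layout")
  el <- unique(lay[c("group", "element", "width")])
  el <- el[order(-el$width), , drop = FALSE]
  none <- data.frame(group = NA_integer_, element = NA_integer_,
                     lineWidth = NA_real_, contrastH = NA_real_,
                     contrastV = NA_real_)
  last <- none
  for (i in seq_len(nrow(el))) {
    cons <- vapply(c("h", "v"), function(o) {
      pl <- lay[lay$group == el$group[i] & lay$element == el$element[i] &
                  lay$orientation == o, ]
      prof <- usafProfile(image, pl[1, ], sampling, origin)
      # an element whose profile has too few samples or no signal at this
      # sampling is unresolved, not an error
      if (is.null(prof) || length(prof) < 7L || all(prof == 0)) return(0)
      barContrast(prof, 3L)
    }, numeric(1))
    if (all(cons >= threshold)) {
      last <- data.frame(group = el$group[i], element = el$element[i],
                         lineWidth = el$width[i], contrastH = cons[["h"]],
                         contrastV = cons[["v"]])
    } else {
      break
    }
  }
  last
}

#' Full width at half maximum of a peak profile
#'
#' Width of a unimodal peak at half its maximum, with linear interpolation
#' between samples, in physical units. The profile must exceed half of its
#' maximum at three or more samples' support, i.e. both half-maximum
#' crossings must exist.
#'
#' @param profile 1D trace containing one peak (baseline near 0).
#' @param sampling physical spacing of the samples, um.
#' @return FWHM in um.
#' @examples
#' x <- seq(-10, 10)
#' fwhm(exp(-x^2 / (2 * 2^2)), 1)  # ~4.71 = 2*sqrt(2*log(2))*2
#' @export
fwhm <- function(profile, sampling) {
  profile <- as.numeric(profile)
  pk <- which.max(profile)
  half <- profile[pk] / 2
  if (pk <= 1L || pk >= length(profile))
    stop("no half-maximum crossing: peak at the profile edge")
  left <- NULL
  for (i in pk:2) {
    if (profile[i - 1L] < half && profile[i] >= half) {
      left <- (i - 1L) + (half - profile[i - 1L]) / (profile[i] - profile[i - 1L])
      break
    }
  }
  right <- NULL
  for (i in pk:(length(profile) - 1L)) {
    if (profile[i + 1L] < half && profile[i] >= half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1L])
      break
    }
  }
  if (is.null(left) || is.null(right))
    stop("no half-maximum crossing: insufficient peak support")
  (right - left) * sampling
}
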