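# Extended-FOV stitching on refocused (spatial-domain) tiles: pairwise
# phase-correlation offsets, spanning-tree global placement, feathered
# blending. Re-implements the Preibisch-style pairwise phase correlation +
# global placement approach rather than wrapping external software.

# Tukey (tapered cosine) window, taper fraction alpha per end
.tukey <- function(n, alpha) {
  x <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

#' Translation between two images by phase correlation
#'
#' Locates the peak of the inverse transform of the normalized cross-power
#' spectrum of `a` and `b`, then disambiguates the four periodic candidate
#' shifts by direct normalized cross correlation (NCC) on the overlap.
#' The returned offset (dy, dx) satisfies `b[y, x] ~ a[y - dy, x - dx]`
#' (content of b displaced by +(dy, dx) relative to a).
#'
#' @param a,b equal-shape, non-constant image matrices.
#' @param maxShift largest |offset| considered per axis, px; default is the
#'   full wrap-around range.
#' @param nominal optional numeric(2) c(dy, dx) expected offset; candidates
#'   further than `maxDev` from it are discarded.
#' @param maxDev allowed deviation from `nominal`, px.
#' @return list(dy, dx, score) with score the overlap NCC in [-1, 1].
#' @export
phaseOffset <- function(a, b, maxShift = NULL, nominal = NULL,
                        maxDev = NULL) {
  if (!identical(dim(a), dim(b))) stop("images must share one shape")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate input: constant image")
  H <- nrow(a); W <- ncol(a)
  # Tukey window (20% taper): suppresses the spectral leakage of the
  # non-periodic frame edges (which otherwise buries the correlation peak
  # under axis artifacts) while keeping edge-near overlap content usable
  win <- outer(.tukey(H, 0.2), .tukey(W, 0.2))
  Fa <- stats::fft((a - mean(a)) * win)
  Fb <- stats::fft((b - mean(b)) * win)
  R <- Fa * Conj(Fb)
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  # rank peaks, then test the periodic unwrappings of the best few by NCC
  ord <- order(r, decreasing = TRUE)[1:min(10L, length(r))]
  best <- list(dy = 0, dx = 0, score = -Inf)
  for (idx in ord) {
    p <- idx - 1L
    py <- p %% H; px <- p %/% H
    # peak at index p corresponds to offsets -p modulo the period
    for (dy in unique(c(-py, H - py))) {
      for (dx in unique(c(-px, W - px))) {
        if (!is.null(maxShift) && (abs(dy) > maxShift || abs(dx) > maxShift))
          next
        if (!is.null(nominal) && !is.null(maxDev) &&
            (abs(dy - nominal[1]) > maxDev || abs(dx - nominal[2]) > maxDev))
          next
        sc <- overlapNcc(a, b, dy, dx)
        if (is.finite(sc) && sc > best$score)
          best <- list(dy = dy, dx = dx, score = sc)
      }
    }
  }
  if (!is.finite(best$score))
    best$score <- 0
  best
}

# Pearson correlation between a and b on their overlap at offset (dy, dx)
# (b displaced by +(dy, dx)); NA when the overlap is too small or flat.
# Candidates overlapping less than ~5% of the frame are rejected: the NCC of
# a tiny overlap is dominated by selection noise.
overlapNcc <- function(a, b, dy, dx,
                       minPixels = max(64L, ceiling(0.05 * length(a)))) {
  H <- nrow(a); W <- ncol(a)
  r1 <- max(1L, 1L + dy); r2 <- min(H, H + dy)
  c1 <- max(1L, 1L + dx); c2 <- min(W, W + dx)
  if (r2 - r1 < 1L || c2 - c1 < 1L) return(NA_real_)
  rb <- r1:r2                               # rows of b in the overlap
  cb <- c1:c2
  ra <- rb - dy; ca <- cb - dx
  av <- a[ra, ca]; bv <- b[rb, cb]
  if (length(av) < minPixels) return(NA_real_)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
  stats::cor(as.vector(av), as.vector(bv))
}

#' Global tile placement from pairwise registrations
#'
#' Computes a phase-correlation offset for every adjacent tile pair of the
#' scan grid, initialized at the nominal pattern displacement: the two tiles
#' are cropped to the nominally overlapping strip (expanded by `maxDev`), the
#' residual translation of the strips is found with [phaseOffset()], and the
#' pair offset is nominal plus residual. Tiles are then placed by walking a
#' maximum-score spanning tree anchored at the most central tile. Pairs
#' scoring below `scoreThreshold` fall back to their nominal displacement;
#' if all pairs fall back the layout equals the nominal pattern (warning,
#' not failure).
#'
#' @param tiles list of equal-shape tile images, ordered like the pattern
#'   entries.
#' @param pattern the tile-mode [ScanPattern-class] used for acquisition.
#' @param sampling um per tile pixel (converts pattern shifts to px).
#' @param scoreThreshold minimum pair NCC to trust a registration.
#' @param maxDev allowed deviation from the nominal offset, px.
#' @return a [MosaicLayout-class]; positions are (x, y) tile origins on the
#'   fine-pixel canvas.
#' @export
globalLayout <- function(tiles, pattern, sampling, scoreThreshold = 0.3,
                         maxDev = 8) {
  e <- patternEntries(pattern)
  stopifnot(length(tiles) == nrow(e))
  nTile <- length(tiles)
  H <- nrow(tiles[[1]]); W <- ncol(tiles[[1]])
  # nominal positions, px (x, y)
  nomX <- e$dx / sampling; nomY <- e$dy / sampling
  # adjacency from grid indices
  pairs <- NULL
  for (i in seq_len(nTile)) {
    for (j in seq_len(nTile)) {
      if (j <= i) next
      dgx <- abs(e$gx[i] - e$gx[j]); dgy <- abs(e$gy[i] - e$gy[j])
      if (dgx + dgy == 1L) pairs <- rbind(pairs, c(i, j))
    }
  }
  registerPair <- function(i, j) {
    # nominal displacement of tile j relative to tile i, px (rounded)
    ty <- round(nomY[j] - nomY[i]); tx <- round(nomX[j] - nomX[i])
    m <- ceiling(maxDev) + 2L
    ra <- max(1L, 1L + ty - m):min(H, H + ty + m)
    ca <- max(1L, 1L + tx - m):min(W, W + tx + m)
    rb <- ra - ty; cb <- ca - tx
    keepR <- rb >= 1L & rb <= H
    keepC <- cb >= 1L & cb <= W
    if (sum(keepR) < 4L || sum(keepC) < 4L)
      stop("no usable overlap for this pair")
    cropA <- tiles[[i]][ra[keepR], ca[keepC]]
    cropB <- tiles[[j]][rb[keepR], cb[keepC]]
    po <- phaseOffset(cropA, cropB, nominal = c(0, 0), maxDev = maxDev)
    # strip residual r means p_j = p_i + t - r
    list(dy = -ty + po$dy, dx = -tx + po$dx, score = po$score)
  }
  scores <- data.frame(i = integer(), j = integer(), dy = numeric(),
                       dx = numeric(), score = numeric(), used = character())
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      nomOff <- c(-(nomY[j] - nomY[i]), -(nomX[j] - nomX[i]))  # b rel. a
      po <- tryCatch(registerPair(i, j),
                     error = function(e) list(dy = nomOff[1], dx = nomOff[2],
                                              score = 0))
      ok <- is.finite(po$score) && po$score >= scoreThreshold
      scores <- rbind(scores, data.frame(
        i = i, j = j,
        dy = if (ok) po$dy else nomOff[1],
        dx = if (ok) po$dx else nomOff[2],
        score = if (is.finite(po$score)) po$score else 0,
        used = if (ok) "phase" else "nominal"))
    }
    if (nrow(scores) && all(scores$used == "nominal"))
      warning("all pair registrations below threshold; layout is nominal")
  }
  # maximum-score spanning tree (Prim) anchored at the most central tile
  anchor <- which.min((nomX - mean(nomX))^2 + (nomY - mean(nomY))^2)
  posX <- nomX; posY <- nomY
  placed <- rep(FALSE, nTile); placed[anchor] <- TRUE
  while (!all(placed) && nrow(scores)) {
    front <- scores[xor(placed[scores$i], placed[scores$j]), , drop = FALSE]
    if (!nrow(front)) break                    # disconnected: stay nominal
    f <- front[which.max(front$score), ]
    if (placed[f$i]) {                         # place j relative to i
      posX[f$j] <- posX[f$i] - f$dx
      posY[f$j] <- posY[f$i] - f$dy
      placed[f$j] <- TRUE
    } else {
      posX[f$i] <- posX[f$j] + f$dx
      posY[f$i] <- posY[f$j] + f$dy
      placed[f$i] <- TRUE
    }
  }
  MosaicLayout(cbind(x = posX, y = posY), scores,
               provenance = list(sampling = sampling, anchor = anchor,
                                 scoreThreshold = scoreThreshold))
}

#' Feather-blend placed tiles onto a canvas
#'
#' Linear feathering: each tile contributes with a weight equal to the
#' distance of the pixel to the nearest tile border, and every canvas pixel
#' is the weight-normalized average of the tiles covering it (weights over
#' covered pixels sum to one by construction). Tile positions are rounded
#' to the nearest integer canvas pixel. Pixels covered by no tile are 0 and
#' flagged in the coverage attribute.
#'
#' @param tiles list of equal-shape tile images.
#' @param layout a [MosaicLayout-class].
#' @return mosaic matrix with attribute `coverage` (logical matrix) and
#'   `origin` (canvas origin in layout px, c(x, y)).
#' @export
blendTiles <- function(tiles, layout) {
  pos <- tilePositions(layout)
  stopifnot(length(tiles) == nrow(pos))
  H <- nrow(tiles[[1]]); W <- ncol(tiles[[1]])
  px <- round(pos[, "x"]); py <- round(pos[, "y"])
  x0 <- min(px); y0 <- min(py)
  cw <- max(px) - x0 + W; ch <- max(py) - y0 + H
  acc <- matrix(0, ch, cw); wacc <- matrix(0, ch, cw)
  fr <- pmin(seq_len(H), H + 1 - seq_len(H))
  fc <- pmin(seq_len(W), W + 1 - seq_len(W))
  feather <- outer(fr, fc, pmin)
  for (i in seq_along(tiles)) {
    rows <- (py[i] - y0) + seq_len(H)
    cols <- (px[i] - x0) + seq_len(W)
    acc[rows, cols] <- acc[rows, cols] + feather * tiles[[i]]
    wacc[rows, cols] <- wacc[rows, cols] + feather
  }
  covered <- wacc > 0
  out <- acc
  out[covered] <- acc[covered] / wacc[covered]
  attr(out, "coverage") <- covered
  attr(out, "origin") <- c(x = x0, y = y0)
  out
}

#' Rectify, refocus and stitch an acquisition sequence
#'
#' End-to-end extended-FOV pipeline: each capture is rectified, refocused at
#' a single depth z (the same registration is meant to be applied to every
#' plane of a stack afterwards), tiles are registered and placed with
#' [globalLayout()] and blended with [blendTiles()]. Deterministic for fixed
#' inputs.
#'
#' @param captures list of [RawFrame-class] in pattern order.
#' @param cal a [GridCalibration-class] shared by all captures.
#' @param config an [OpticalConfig-class].
#' @param pattern the tile [ScanPattern-class] used for the captures.
#' @param z refocus depth, um.
#' @param darkOffset dark level passed to [rectify()].
#' @param scoreThreshold see [globalLayout()].
#' @return list(mosaic, layout, tiles).
#' @export
stitchSequence <- function(captures, cal, config, pattern, z = 0,
                           darkOffset = 0, scoreThreshold = 0.3) {
  k <- disparitySlope(config)
  tiles <- lapply(captures, function(fr) {
    refocus(rectify(fr, cal, config, darkOffset = darkOffset), z, k)
  })
  layout <- globalLayout(tiles, pattern, sampleSampling(config),
                         scoreThreshold = scoreThreshold)
  list(mosaic = blendTiles(tiles, layout), layout = layout, tiles = tiles)
}
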