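# Raw frame -> 4D light field: grid calibration on a uniform-illumination
# frame, then per-lens angular extraction. Lens indexing is 0-based
# row-major internally with x = column axis; partial edge lenses are
# discarded (only complete pixelsPerLens^2 blocks are kept).

#' Calibrate the microlens grid from a white frame
#'
#' Detects one intensity maximum per lens on a uniform-illumination capture,
#' refines each to sub-pixel precision by intensity centroid, and fits
#' origin, pitch and in-plane rotation by linear least squares over all
#' detected centers (a similarity transform of the integer lens lattice).
#'
#' @param white a [RawFrame-class] uniform-scene capture.
#' @param approxPitchPx approximate lens pitch in sensor px (within 20%).
#' @return a [GridCalibration-class] with the RMS fit residual.
#' @export
calibrateGrid <- function(white, approxPitchPx) {
  img <- framePixels(white)
  H <- nrow(img); W <- ncol(img)
  h <- max(1L, as.integer(floor(0.35 * approxPitchPx)))
  mx <- maxFilter(img, h)
  thr <- stats::quantile(img, 0.6) + 1e-12
  peaks <- which(img == mx & img > thr, arr.ind = TRUE)
  # drop peaks whose centroid window would leave the frame
  cw <- max(1L, as.integer(floor(approxPitchPx / 2)) - 1L)
  keep <- peaks[, 1] > cw & peaks[, 1] <= H - cw &
          peaks[, 2] > cw & peaks[, 2] <= W - cw
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) < 4L)
    stop("calibration error: fewer than 4 lens centers detected")
  # centroid refinement
  centers <- t(vapply(seq_len(nrow(peaks)), function(k) {
    r <- peaks[k, 1]; c <- peaks[k, 2]
    win <- img[(r - cw):(r + cw), (c - cw):(c + cw)]
    win <- win - min(win)
    s <- sum(win)
    if (s <= 0) return(c(c, r))
    rows <- (r - cw):(r + cw); cols <- (c - cw):(c + cw)
    c(sum(colSums(win) * cols) / s, sum(rowSums(win) * rows) / s)  # (x, y)
  }, numeric(2)))
  # local orientation from right-hand neighbors (spatial hashing keeps this
  # linear in the number of lenses)
  cellId <- paste(floor(centers[, 1] / approxPitchPx),
                  floor(centers[, 2] / approxPitchPx))
  byCell <- split(seq_len(nrow(centers)), cellId)
  angles <- numeric(0); pitches <- numeric(0)
  for (k in seq_len(nrow(centers))) {
    cx <- floor(centers[k, 1] / approxPitchPx)
    cy <- floor(centers[k, 2] / approxPitchPx)
    cand <- unlist(byCell[paste(cx + rep(0:2, 3), rep(cy + -1:1, each = 3))],
                   use.names = FALSE)
    if (is.null(cand)) next
    ddx <- centers[cand, 1] - centers[k, 1]
    ddy <- centers[cand, 2] - centers[k, 2]
    ok <- ddx > 0.5 * approxPitchPx & ddx < 1.5 * approxPitchPx &
          abs(ddy) < 0.5 * approxPitchPx
    if (!any(ok)) next
    d <- sqrt(ddx[ok]^2 + ddy[ok]^2)
    j <- which.min(d)
    angles <- c(angles, atan2(ddy[ok][j], ddx[ok][j]))
    pitches <- c(pitches, d[j])
  }
  if (!length(angles))
    stop("calibration error: could not establish grid orientation")
  th1 <- stats::median(angles); p1 <- stats::median(pitches)
  # integer lattice assignment relative to the most central lens
  mid <- which.min((centers[, 1] - mean(centers[, 1]))^2 +
                   (centers[, 2] - mean(centers[, 2]))^2)
  ct <- cos(th1); st <- sin(th1)
  qx <- (ct * (centers[, 1] - centers[mid, 1]) +
         st * (centers[, 2] - centers[mid, 2])) / p1
  qy <- (-st * (centers[, 1] - centers[mid, 1]) +
         ct * (centers[, 2] - centers[mid, 2])) / p1
  ix <- round(qx) - min(round(qx))
  iy <- round(qy) - min(round(qy))
  # least-squares similarity fit: center = t + [a -b; b a] (ix, iy)
  n <- nrow(centers)
  A <- rbind(cbind(1, 0, ix, -iy), cbind(0, 1, iy, ix))
  b <- c(centers[, 1], centers[, 2])
  beta <- qr.coef(qr(A), b)
  res <- A %*% beta - b
  rms <- sqrt(mean(matrix(res^2, n, 2) |> rowSums()))
  pitch <- sqrt(beta[3]^2 + beta[4]^2)
  rot <- atan2(beta[4], beta[3])
  GridCalibration(origin = beta[1:2], pitchPx = pitch, rotation = rot,
                  nLenses = c(max(ix) + 1L, max(iy) + 1L),
                  residualRms = rms)
}

#' Rectify a raw frame into a 4D light field
#'
#' For each lens (i, j) and angular offset (du, dv) in
#' `[-uMax, uMax]`, samples the raw frame by bilinear interpolation at the
#' rotated grid position
#' `origin + R(theta) * ((i-1, j-1) * pitch + (du, dv) * pitch/P)`.
#' On an axis-aligned integer grid this reduces to exact pixel extraction,
#' making rectification the exact inverse of [renderRaw()] without noise.
#' A uniform dark level (`darkOffset`) is subtracted first and negative
#' values are clamped to zero.
#'
#' @param raw a [RawFrame-class].
#' @param cal a [GridCalibration-class] with `residualRms < 0.5` px.
#' @param config an [OpticalConfig-class].
#' @param darkOffset constant dark level to subtract, counts.
#' @return a [LightField4D-class].
#' @export
rectify <- function(raw, cal, config, darkOffset = 0) {
  stopifnot(is(raw, "RawFrame"), is(cal, "GridCalibration"))
  if (!isTRUE(cal@residualRms < 0.5))
    stop("calibration residual too large for rectification")
  img <- framePixels(raw)
  P <- config@pixelsPerLens
  um <- uMax(config)
  nX <- cal@nLenses[1]; nY <- cal@nLenses[2]
  ct <- cos(cal@rotation); st <- sin(cal@rotation)
  # partial edge lenses are discarded: keep the largest lens rectangle whose
  # complete angular blocks sample inside the frame (rotation pushes corner
  # lenses out, so trim borders greedily until everything fits)
  half <- um * cal@pitchPx / P
  fits <- function(i, j) {
    lx <- (i - 1) * cal@pitchPx; ly <- (j - 1) * cal@pitchPx
    x <- cal@origin[1] + ct * lx - st * ly
    y <- cal@origin[2] + st * lx + ct * ly
    r <- half * (abs(ct) + abs(st))
    x - r >= 0.5 & x + r <= ncol(img) + 0.5 &
      y - r >= 0.5 & y + r <= nrow(img) + 0.5
  }
  F <- outer(seq_len(nY), seq_len(nX), function(j, i) fits(i, j))
  i1 <- 1L; i2 <- nX; j1 <- 1L; j2 <- nY
  while (i2 >= i1 && j2 >= j1 && !all(F[j1:j2, i1:i2])) {
    bad <- c(left = mean(!F[j1:j2, i1]), right = mean(!F[j1:j2, i2]),
             top = mean(!F[j1, i1:i2]), bottom = mean(!F[j2, i1:i2]))
    side <- names(which.max(bad))
    if (side == "left") i1 <- i1 + 1L
    else if (side == "right") i2 <- i2 - 1L
    else if (side == "top") j1 <- j1 + 1L
    else j2 <- j2 - 1L
  }
  if (i2 < i1 || j2 < j1)
    stop("shape error: calibration does not fit the frame geometry")
  nX <- i2 - i1 + 1L; nY <- j2 - j1 + 1L
  origin <- cal@origin +
    c(ct * (i1 - 1) - st * (j1 - 1), st * (i1 - 1) + ct * (j1 - 1)) *
      cal@pitchPx
  du <- ((seq_len(P) - 1L) - um) * cal@pitchPx / P
  lensX <- (seq_len(nX) - 1L) * cal@pitchPx
  lensY <- (seq_len(nY) - 1L) * cal@pitchPx
  # lattice coordinates for all (lens, angular) samples per axis
  gx <- outer(lensX, du, "+")              # nX x P
  gy <- outer(lensY, du, "+")              # nY x P
  # expand to full (y, x, u, v) position grids
  lx <- aperm(array(gx, c(nX, P, nY, P)), c(3, 1, 2, 4)) # (y, x, u, v): x-lattice
  ly <- aperm(array(gy, c(nY, P, nX, P)), c(1, 3, 4, 2)) # (y, x, u, v): y-lattice
  sx <- origin[1] + ct * lx - st * ly
  sy <- origin[2] + st * lx + ct * ly
  if (min(sx) < 0.5 || max(sx) > ncol(img) + 0.5 ||
      min(sy) < 0.5 || max(sy) > nrow(img) + 0.5)
    stop("shape error: calibration samples outside the frame")
  vals <- sampleBilinear(img, as.vector(sx), as.vector(sy))
  arr <- array(pmax(vals - darkOffset, 0), c(nY, nX, P, P))
  LightField4D(arr, sampleSampling(config), provenance = list(
    calibration = list(origin = cal@origin, pitchPx = cal@pitchPx,
                       rotation = cal@rotation, residualRms = cal@residualRms),
    metadata = raw@metadata,
    origin = c(-nX, -nY) * sampleSampling(config) / 2,
    darkOffset = darkOffset))
}
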