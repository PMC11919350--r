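# Internal numerics shared across modules.

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards. All stochastic package output goes through this.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic seed splitting: master seed + event index -> per-event seed.
# Keeps results below 2^31 so they remain valid R integers.
splitSeed <- function(master, index) {
  as.integer((as.numeric(master) %% 65521) * 31013 + as.numeric(index) * 101) %% 2147483647L
}

# Gather img[rows, cols] with zeros outside the frame (rows/cols are integer
# vectors indexing output rows/cols one-to-one).
gatherPad <- function(img, rows, cols) {
  H <- nrow(img); W <- ncol(img)
  rv <- rows >= 1L & rows <= H
  cv <- cols >= 1L & cols <= W
  out <- matrix(0, length(rows), length(cols))
  if (any(rv) && any(cv))
    out[rv, cv] <- img[rows[rv], cols[cv], drop = FALSE]
  out
}

# Translate an image by a (possibly fractional) uniform shift with bilinear
# interpolation: out[r, c] = img[r - dy, c - dx]. Returns the shifted image
# and the per-pixel validity weight (bilinear support fraction inside the
# frame), used for valid-count normalization at borders.
shiftBilinear <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  r <- seq_len(H) - dy
  c <- seq_len(W) - dx
  r0 <- floor(r); fr <- r[1] - r0[1]
  c0 <- floor(c); fc <- c[1] - c0[1]
  r0 <- as.integer(r0); c0 <- as.integer(c0)
  out <- (1 - fr) * (1 - fc) * gatherPad(img, r0, c0)
  if (fc > 0) out <- out + (1 - fr) * fc * gatherPad(img, r0, c0 + 1L)
  if (fr > 0) out <- out + fr * (1 - fc) * gatherPad(img, r0 + 1L, c0)
  if (fr > 0 && fc > 0) out <- out + fr * fc * gatherPad(img, r0 + 1L, c0 + 1L)
  inR <- function(i) as.numeric(i >= 1L & i <= H)
  inC <- function(i) as.numeric(i >= 1L & i <= W)
  wr <- (1 - fr) * inR(r0) + fr * inR(r0 + 1L)
  wc <- (1 - fc) * inC(c0) + fc * inC(c0 + 1L)
  list(image = out, weight = outer(wr, wc))
}

# Bilinear point sampling of an image at continuous positions (x = col,
# y = row, pixel centers at integers). Out-of-frame support contributes 0.
sampleBilinear <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  (1 - fy) * (1 - fx) * val(y0, x0) +
    (1 - fy) * fx * val(y0, x0 + 1) +
    fy * (1 - fx) * val(y0 + 1, x0) +
    fy * fx * val(y0 + 1, x0 + 1)
}

# Accumulate weights into a ny x nx grid at integer bin indices (iy, ix),
# dropping out-of-range bins.
binAccumulate <- function(iy, ix, w, ny, nx) {
  keep <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  acc <- numeric(ny * nx)
  if (any(keep)) {
    idx <- (ix[keep] - 1L) * ny + iy[keep]
    rs <- rowsum(w[keep], idx)
    acc[as.integer(rownames(rs))] <- rs
  }
  matrix(acc, ny, nx)
}

# 3x3 Laplacian response on the interior (valid region), used as the
# sharpness primitive for depth-from-focus.
laplacian3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  if (H < 3L || W < 3L) stop("image too small for a 3x3 Laplacian")
  i <- 2:(H - 1); j <- 2:(W - 1)
  img[i - 1, j] + img[i + 1, j] + img[i, j - 1] + img[i, j + 1] - 4 * img[i, j]
}

# Grey-scale maximum filter with a (2h+1)^2 square window, via shifted pmax.
maxFilter <- function(img, h) {
  out <- img
  H <- nrow(img); W <- ncol(img)
  for (dr in -h:h) {
    rs <- pmin(pmax(seq_len(H) + dr, 1L), H)
    row <- img[rs, , drop = FALSE]
    for (dc in -h:h) {
      cs <- pmin(pmax(seq_len(W) + dc, 1L), W)
      out <- pmax(out, row[, cs, drop = FALSE])
    }
  }
  out
}
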