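# Sub-pitch super-resolution by deterministic pixel interleaving: no
# deconvolution, no re-weighting — every output voxel is sourced from
# exactly one input voxel, so total intensity is conserved exactly.

# slot mapping shared by the 2D and 3D paths. A capture shifted by
# +s*ds/n samples the scene on a lattice displaced by +s*ds/n, so its pixels
# occupy fine-lattice residue s (fine pixel (i-1)*n + s + 1 for coarse pixel
# i); the fused grid origin is offset by (n-1)/(2n) * ds relative to the
# unshifted capture (see fusedOriginOffset). Sign fixed by the delta-lattice
# round trip with the forward simulator.
.checkFuseInputs <- function(vols, pattern, n) {
  n <- as.integer(n)
  e <- patternEntries(pattern)
  if (length(vols) != n^2 || nrow(e) != n^2)
    stop(sprintf("expected %d shifted inputs, got %d", n^2, length(vols)))
  d1 <- dim(vols[[1]])
  for (v in vols)
    if (!identical(dim(v), d1)) stop("shifted inputs must share one shape")
  if (any(e$sx < 0 | e$sx >= n | e$sy < 0 | e$sy >= n))
    stop("pattern sub indices out of range for n")
  if (anyDuplicated(e[c("sx", "sy")]))
    stop("pattern sub indices must be distinct")
  e
}

#' Fuse sub-pitch shifted focal stacks
#'
#' Interleaves n^2 volumes reconstructed from captures shifted by the
#' sub-pitch pattern onto an n-fold finer lateral grid: volume with sub
#' index (sx, sy) fills output voxels
#' `[(y-1)*n + sy + 1, (x-1)*n + sx + 1, z]`. No interpolation and no
#' re-weighting; the z axis is untouched. Nine 140 x 140 x 40 stacks fuse
#' into a 420 x 420 x 40 volume.
#'
#' @param volumes list of n^2 3D arrays (y, x, z), identical shapes,
#'   ordered like the pattern entries.
#' @param pattern the [ScanPattern-class] used for the captures (its
#'   sub-index columns define the placement of each volume).
#' @param n refinement factor.
#' @return 3D array (n*Y, n*X, Z); its grid origin is displaced by
#'   [fusedOriginOffset()] relative to the unshifted capture.
#' @export
fuseShifted <- function(volumes, pattern, n) {
  e <- .checkFuseInputs(volumes, pattern, n)
  n <- as.integer(n)
  d <- dim(volumes[[1]])
  out <- array(0, c(d[1] * n, d[2] * n, d[3]))
  for (i in seq_along(volumes)) {
    rows <- seq(e$sy[i] + 1L, by = n, length.out = d[1])
    cols <- seq(e$sx[i] + 1L, by = n, length.out = d[2])
    out[rows, cols, ] <- volumes[[i]]
  }
  out
}

#' Fuse sub-pitch shifted images
#'
#' 2D specialization of [fuseShifted()] for single refocused planes: nine
#' 140 x 140 images fuse into a 420 x 420 image.
#'
#' @param images list of n^2 2D matrices, identical shapes.
#' @inheritParams fuseShifted
#' @return matrix (n*Y, n*X).
#' @export
fuseShiftedImages <- function(images, pattern, n) {
  e <- .checkFuseInputs(images, pattern, n)
  n <- as.integer(n)
  d <- dim(images[[1]])
  out <- matrix(0, d[1] * n, d[2] * n)
  for (i in seq_along(images)) {
    rows <- seq(e$sy[i] + 1L, by = n, length.out = d[1])
    cols <- seq(e$sx[i] + 1L, by = n, length.out = d[2])
    out[rows, cols] <- images[[i]]
  }
  out
}

#' Coordinate origin offset of a fused image
#'
#' The fused fine grid is displaced by `(n - 1) / (2n) * ds` per axis
#' relative to the unshifted capture's grid origin (fine pixel m has center
#' `origin + (n-1)/(2n)*ds + (m - 1/2) * ds/n`).
#'
#' @param ds coarse sampling, um.
#' @param n refinement factor.
#' @return offset in um.
#' @export
fusedOriginOffset <- function(ds, n) ds * (n - 1) / (2 * n)
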