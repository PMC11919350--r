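test_that("interleaving fusion is bijective and conserves intensity", {
  cfg <- OpticalConfig(lensesPerTile = 12L)
  pat <- subpixelPattern(3, cfg)
  set.seed(1)
  vols <- lapply(1:9, function(i) array(runif(12 * 12 * 4), c(12, 12, 4)))
  fused <- fuseShifted(vols, pat, 3)
  expect_identical(dim(fused), c(36L, 36L, 4L))
  expect_equal(sum(fused), sum(vapply(vols, sum, numeric(1))),
               tolerance = 1e-9)
  # every output voxel sourced from exactly one input voxel
  expect_identical(sort(as.vector(fused)),
                   sort(as.vector(unlist(vols))))
  # n = 1 is the identity
  p1 <- subpixelPattern(1, cfg)
  expect_identical(fuseShifted(vols[1], p1, 1), vols[[1]])
  expect_error(fuseShifted(vols[1:8], pat, 3), "expected 9")
  badShape <- vols; badShape[[2]] <- array(0, c(12, 12, 5))
  expect_error(fuseShifted(badShape, pat, 3), "shape")
})

test_that("2D fusion places constant inputs onto a constant fine grid", {
  cfg <- OpticalConfig(lensesPerTile = 14L)
  pat <- subpixelPattern(3, cfg)
  imgs <- lapply(1:9, function(i) matrix(5, 14, 14))
  out <- fuseShiftedImages(imgs, pat, 3)
  expect_identical(dim(out), c(42L, 42L))
  expect_true(all(out == 5))
})

test_that("delta-lattice oracle: fused support is centered on the emitter", {
  for (n in c(2L, 3L)) {
    cfg <- OpticalConfig(lensesPerTile = 20L)
    ds <- sampleSampling(cfg)
    pat <- subpixelPattern(n, cfg)
    e <- patternEntries(pat)
    x0 <- -10 * ds
    fine <- ds / n
    # every sub-lattice residue in the tile interior
    for (m in 10 * n + seq_len(n)) {
      xc <- x0 + fusedOriginOffset(ds, n) + (m - 0.5) * fine
      imgs <- lapply(seq_len(n^2), function(i) {
        refocusedDelta(xc, xc, cfg, acquisitionEvent(e$dx[i], e$dy[i]))
      })
      fused <- fuseShiftedImages(imgs, pat, n)
      cs <- colSums(fused)
      supp <- which(cs > 0)
      # the delta lands in one bin of every capture: n consecutive fine
      # pixels whose centroid is the delta's fine-lattice position (odd n
      # symmetric about m; even n offset by the half-pixel origin shift)
      if (n == 3L) {
        expect_identical(supp, (m - 1L):(m + 1L))
        expect_equal(sum(seq_along(cs) * cs) / sum(cs), m, tolerance = 1e-9)
      } else {
        expect_identical(supp, m:(m + 1L))
        expect_equal(sum(seq_along(cs) * cs) / sum(cs), m + 0.5,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("fusion resolves sub-lattice structure a nearest upsampling cannot", {
  cfg <- OpticalConfig(lensesPerTile = 30L)
  ds <- sampleSampling(cfg)
  n <- 3
  rp <- ds / 15
  W <- 30 * ds
  # band-limited planar scene: sinusoidal grating of 8 um period
  xs <- seq(-W / 2 + rp / 2, W / 2 - rp / 4, by = rp)
  g <- expand.grid(x = xs, y = xs)
  scene <- plenoscope:::Scene(
    data.frame(x = g$x, y = g$y, z = 0,
               intensity = 1 + sin(2 * pi * g$x / 8)),
    extent = c(-1, 1, -1, 1) * W / 2)
  k <- disparitySlope(cfg)
  pat <- subpixelPattern(n, cfg)
  e <- patternEntries(pat)
  imgs <- lapply(seq_len(9), function(i) {
    refocus(renderLightField(scene, cfg, acquisitionEvent(e$dx[i], e$dy[i])),
            0, k)
  })
  fused <- fuseShiftedImages(imgs, pat, n)
  # ground truth at the fine sampling (the fused grid sits one fine pixel
  # further along each axis: fusedOriginOffset = ds/3 = one fine pixel)
  fcfg <- OpticalConfig(lensesPerTile = 90L,
                        totalMagnification = 100 / (3.1 / 3))
  gt <- refocus(renderLightField(scene, fcfg), 0, disparitySlope(fcfg))
  idx <- 5:85
  rmseFused <- sqrt(mean((fused[idx, idx] / 9 - gt[idx + 1, idx + 1])^2))
  up <- kronecker(imgs[[1]], matrix(1, n, n))
  rmseUp <- sqrt(mean((up[idx, idx] / 9 - gt[idx, idx])^2))
  expect_lt(rmseFused, rmseUp)
})
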