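test_that("phase correlation recovers constructed translations exactly", {
  tex <- smoothTexture()
  a <- tex[51:190, 51:190]
  # identity
  id <- phaseOffset(a, a)
  expect_equal(c(id$dy, id$dx), c(0, 0))
  expect_gt(id$score, 0.999)
  # constructed shift with ~77% overlap
  b <- tex[51:190 + 17, 51:190 - 5]
  po <- phaseOffset(a, b)
  expect_equal(c(po$dy, po$dx), c(-17, 5))
  expect_gt(po$score, 0.99)
  expect_error(phaseOffset(a, matrix(1, 140, 140)), "constant")
  expect_error(phaseOffset(matrix(0, 10, 10), matrix(0, 10, 10)), "constant")
})

test_that("offset recovery holds down to 10% overlap (sweep)", {
  tex <- smoothTexture()
  a <- tex[51:190, 51:190]
  shifts <- list(c(17, -5), c(100, 0), c(100, 30), c(-50, 0), c(110, 0),
                 c(0, 110), c(-45, -40))
  for (sh in shifts) {
    b <- tex[51:190 + sh[1], 51:190 + sh[2]]
    po <- phaseOffset(a, b)
    expect_lte(max(abs(c(po$dy + sh[1], po$dx + sh[2]))), 1)
    expect_gt(po$score, 0.9)
  }
  # independent noise fields score in rejection territory
  set.seed(11)
  scores <- vapply(1:5, function(i) {
    n1 <- matrix(rnorm(100^2), 100)
    n2 <- matrix(rnorm(100^2), 100)
    phaseOffset(n1, n2)$score
  }, numeric(1))
  expect_true(all(scores < 0.2))
})

test_that("global layout recovers nominal tile positions", {
  fx <- mosaic25()
  lay <- fx$res$layout
  e <- patternEntries(fx$pattern)
  ds <- sampleSampling(fx$config)
  pos <- tilePositions(lay)
  expect_lte(max(abs(pos[, 1] - e$dx / ds)), 0.5)
  expect_lte(max(abs(pos[, 2] - e$dy / ds)), 0.5)
  expect_true(all(abs(lay@pairScores$score) <= 1))
  # 2x1 grid: the layout is a single pair registration
  tex <- smoothTexture()
  cfg2 <- OpticalConfig(lensesPerTile = 100L)
  p21 <- tilePattern(c(2, 1), 0.3, cfg2)
  step <- round(tileFov(cfg2) * 0.7 / sampleSampling(cfg2))
  tiles <- list(tex[1:100, 1:100], tex[1:100, 1:100 + step])
  lay21 <- globalLayout(tiles, p21, sampleSampling(cfg2))
  expect_identical(nrow(lay21@pairScores), 1L)
  expect_equal(diff(tilePositions(lay21)[, 1]), step, tolerance = 1e-9)
})

test_that("a blank tile falls back to its nominal position", {
  cfg <- smallConfig()
  ds <- sampleSampling(cfg)
  pat <- tilePattern(c(2, 2), 0.25, cfg)
  scene <- makeAggregateScene(2, capsuleRadius = 22, nucleiPerCapsule = 20,
                              seed = 5L, extent = 180)
  frames <- renderSequence(scene, cfg, pat, noiseOff(), seed = 9L)
  cal <- calibrateGrid(renderWhiteFrame(cfg), 15)
  tiles <- lapply(frames, function(fr)
    refocus(rectify(fr, cal, cfg), 0, disparitySlope(cfg)))
  tiles[[4]] <- matrix(0, 40, 40)            # empty capsule region
  lay <- globalLayout(tiles, pat, ds)
  e <- patternEntries(pat)
  expect_true(all(lay@pairScores$used[lay@pairScores$i == 4 |
                                        lay@pairScores$j == 4] == "nominal"))
  expect_equal(tilePositions(lay)[4, ], c(x = e$dx[4], y = e$dy[4]) / ds,
               tolerance = 1e-9)
})

test_that("feather blending averages overlaps and partitions unity", {
  # single tile: identity
  t1 <- matrix(runif(64), 8, 8)
  lay1 <- MosaicLayout(cbind(x = 0, y = 0),
                       data.frame(i = integer(), j = integer(),
                                  dy = numeric(), dx = numeric(),
                                  score = numeric(), used = character()))
  m1 <- blendTiles(list(t1), lay1)
  expect_equal(unclass(m1)[seq_len(8), seq_len(8)], t1,
               tolerance = 1e-12, ignore_attr = TRUE)
  # two identical overlapping tiles reproduce the common values exactly
  lay2 <- MosaicLayout(cbind(x = c(0, 4), y = c(0, 0)), lay1@pairScores)
  m2 <- blendTiles(list(t1, t1[, c(5:8, 1:4)]), lay2)
  expect_equal(m2[, 5:8], t1[, 5:8], tolerance = 1e-12, ignore_attr = TRUE)
  # partition of unity: weights over covered pixels sum to one
  H <- 8; W <- 8
  feather <- outer(pmin(seq_len(H), H + 1 - seq_len(H)),
                   pmin(seq_len(W), W + 1 - seq_len(W)), pmin)
  ones <- matrix(1, H, W)
  m3 <- blendTiles(list(ones, ones, ones),
                   MosaicLayout(cbind(x = c(0, 3, 5), y = c(0, 2, 1)),
                                lay1@pairScores))
  cov <- attr(m3, "coverage")
  expect_true(all(abs(m3[cov] - 1) < 1e-9))
  expect_true(all(m3[!cov] == 0))
})

test_that("layout translation moves the mosaic, not the pairwise offsets", {
  tex <- smoothTexture()
  cfg2 <- OpticalConfig(lensesPerTile = 100L)
  p21 <- tilePattern(c(2, 1), 0.3, cfg2)
  step <- round(tileFov(cfg2) * 0.7 / sampleSampling(cfg2))
  tilesA <- list(tex[1:100, 1:100], tex[1:100, 1:100 + step])
  tilesB <- list(tex[1:100 + 9, 1:100 + 13], tex[1:100 + 9, 1:100 + step + 13])
  layA <- globalLayout(tilesA, p21, sampleSampling(cfg2))
  layB <- globalLayout(tilesB, p21, sampleSampling(cfg2))
  expect_equal(layA@pairScores[c("dy", "dx")], layB@pairScores[c("dy", "dx")],
               tolerance = 1e-9)
})

test_that("25-tile mosaic matches a directly rendered ground truth", {
  fx <- mosaic25()
  m <- fx$res$mosaic
  gt <- fx$gt
  expect_identical(dim(unclass(m)), dim(gt))
  b <- 12
  cropA <- m[(b + 1):(nrow(m) - b), (b + 1):(ncol(m) - b)]
  cropB <- gt[(b + 1):(nrow(gt) - b), (b + 1):(ncol(gt) - b)]
  expect_lt(sqrt(mean((cropA - cropB)^2)) / diff(range(cropB)), 0.02)
})

test_that("stitching a single capture returns the refocused tile", {
  cfg <- OpticalConfig(lensesPerTile = 16L)
  scene <- makeBeadScene(5, extent = 30, zRange = c(0, 0), seed = 8L)
  pat <- tilePattern(c(1, 1), 0.217, cfg)
  frames <- renderSequence(scene, cfg, pat, noiseOff(), seed = 1L)
  cal <- calibrateGrid(renderWhiteFrame(cfg), 15)
  res <- stitchSequence(frames, cal, cfg, pat, z = 0)
  ref <- refocus(rectify(frames[[1]], cal, cfg), 0, disparitySlope(cfg))
  expect_equal(unclass(res$mosaic)[1:16, 1:16], ref, tolerance = 1e-9,
               ignore_attr = TRUE)
})
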