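test_that("grid calibration recovers pitch, rotation and origin", {
  cfg <- OpticalConfig(lensesPerTile = 30L)
  cal <- calibrateGrid(renderWhiteFrame(cfg), 15)
  expect_equal(cal@pitchPx, 15, tolerance = 0.05 / 15)
  expect_lt(abs(cal@rotation), 0.002)
  expect_equal(cal@origin, c(8, 8), tolerance = 0.05)
  expect_identical(cal@nLenses, c(30L, 30L))
  expect_lt(cal@residualRms, 0.1)
  # injected rotation and off-grid origin are recovered
  cal2 <- calibrateGrid(renderWhiteFrame(cfg, origin = c(8.3, 7.6),
                                         rotation = 0.01), 15)
  expect_lt(abs(cal2@rotation - 0.01), 0.002)
  expect_equal(cal2@pitchPx, 15, tolerance = 0.05 / 15)
  # approximate pitch off by 15% still converges
  cal3 <- calibrateGrid(renderWhiteFrame(cfg), 17)
  expect_equal(cal3@pitchPx, 15, tolerance = 0.05 / 15)
})

test_that("degenerate white frames raise calibration errors", {
  zero <- RawFrame(matrix(0, 60, 60))
  expect_error(calibrateGrid(zero, 15), "calibration error")
})

test_that("rectification inverts noise-free raw rendering", {
  cfg <- OpticalConfig(lensesPerTile = 12L)
  scene <- makeBeadScene(6, extent = 20, zRange = c(-15, 15), seed = 3L)
  raw <- renderRaw(scene, cfg, noise = noiseOff())
  cal <- calibrateGrid(renderWhiteFrame(cfg, nLenses = 12L), 15)
  lf <- rectify(raw, cal, cfg)
  truth <- renderLightField(scene, cfg)
  expect_equal(lf@intensities, truth@intensities, tolerance = 1e-9)
  # energy preservation over the calibrated area
  expect_equal(sum(lf@intensities), sum(framePixels(raw)),
               tolerance = 0.01 * sum(framePixels(raw)))
})

test_that("rectifying a constant frame yields a uniform 4D field", {
  cfg <- OpticalConfig(lensesPerTile = 10L)
  flat <- RawFrame(matrix(7, 150, 150))
  cal <- GridCalibration(origin = c(8, 8), pitchPx = 15, rotation = 0,
                         nLenses = c(10L, 10L), residualRms = 0)
  lf <- rectify(flat, cal, cfg)
  expect_lt(diff(range(lf@intensities)) / 7, 1e-3)
})

test_that("rotated grids round-trip through calibration and rectification", {
  cfg <- OpticalConfig(lensesPerTile = 30L)
  white <- renderWhiteFrame(cfg, rotation = 0.01)
  cal <- calibrateGrid(white, 15)
  expect_lt(cal@residualRms, 0.5)
  lf <- rectify(white, cal, cfg)
  # ground truth from the white-frame model: Gaussian of the angular offset
  um <- uMax(cfg)
  du <- (seq_len(15) - 1 - um) / 15
  gt1 <- 1000 * exp(-outer(du^2, du^2, "+") / (2 * 0.25^2))
  d <- dim(lf@intensities)
  expect_gte(min(d[1:2]), 26)               # a few edge lenses may be trimmed
  sub <- lf@intensities[3:(d[1] - 2), 3:(d[2] - 2), , ]
  gtArr <- aperm(array(gt1, c(15, 15, d[1] - 4, d[2] - 4)), c(3, 4, 1, 2))
  expect_lt(sqrt(mean((sub - gtArr)^2)) / 1000, 0.02)  # RMSE < 2% of range
})

test_that("rectification rejects bad calibrations and geometry mismatch", {
  cfg <- OpticalConfig(lensesPerTile = 8L)
  raw <- renderRaw(makeBeadScene(1, 10, c(0, 0), 1L), cfg, noise = noiseOff())
  bad <- GridCalibration(origin = c(8, 8), pitchPx = 15, rotation = 0,
                         nLenses = c(8L, 8L), residualRms = 0.9)
  expect_error(rectify(raw, bad, cfg), "residual")
  offFrame <- GridCalibration(origin = c(500, 500), pitchPx = 15,
                              rotation = 0, nLenses = c(8L, 8L),
                              residualRms = 0)
  expect_error(rectify(raw, offFrame, cfg), "shape error")
  # a calibration claiming more lenses than the frame holds is trimmed to
  # the complete blocks that fit
  tooBig <- GridCalibration(origin = c(8, 8), pitchPx = 15, rotation = 0,
                            nLenses = c(20L, 20L), residualRms = 0)
  lf2 <- rectify(raw, tooBig, cfg)
  expect_identical(dim(lf2@intensities)[1:2], c(8L, 8L))
})

test_that("dark offset is subtracted and clamped at zero", {
  cfg <- OpticalConfig(lensesPerTile = 8L)
  scene <- makeBeadScene(2, extent = 12, zRange = c(0, 0), seed = 9L)
  raw <- renderRaw(scene, cfg, acquisitionEvent(seed = 2L), NoiseModel())
  cal <- GridCalibration(origin = c(8, 8), pitchPx = 15, rotation = 0,
                         nLenses = c(8L, 8L), residualRms = 0)
  lf <- rectify(raw, cal, cfg, darkOffset = 100)
  expect_true(all(lf@intensities >= 0))
  # background (dark) lenses sit near zero after subtraction
  expect_lt(stats::median(lf@intensities), 2)
})
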