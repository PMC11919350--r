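test_that("rendering conserves flux and splits angular samples equally", {
  cfg <- OpticalConfig(lensesPerTile = 20L)
  scene <- makeBeadScene(5, extent = 30, zRange = c(-20, 20), seed = 2L)
  lf <- renderLightField(scene, cfg)
  expect_identical(dim(lf@intensities), c(20L, 20L, 15L, 15L))
  expect_equal(sum(lf@intensities), sum(emitters(scene)$intensity),
               tolerance = 1e-9)
  # exposure scaling is linear
  lf2 <- renderLightField(scene, cfg, acquisitionEvent(exposureScale = 2))
  expect_equal(sum(lf2@intensities), 2 * sum(emitters(scene)$intensity),
               tolerance = 1e-9)
  # in-focus emitter: identical across all perspectives
  one <- makeBeadScene(1, extent = 10, zRange = c(0, 0), seed = 1L)
  lf0 <- renderLightField(one, cfg)
  p00 <- extractPerspective(lf0, 0, 0)
  pmax <- extractPerspective(lf0, 7, -7)
  expect_equal(p00, pmax, tolerance = 1e-12)
})

test_that("off-focus emitters show the linear parallax of the model", {
  cfg <- smallConfig()
  dtan <- tan(asin(0.75)) / 7
  scene <- makeBeadScene(1, extent = 8, zRange = c(30, 30), seed = 1L)
  lf <- renderLightField(scene, cfg)
  em <- emitters(scene)
  ds <- sampleSampling(cfg)
  for (u in c(-7, -3, 0, 4, 7)) {
    img <- extractPerspective(lf, u, 0)
    hit <- which(img > 0, arr.ind = TRUE)
    expect_identical(nrow(hit), 1L)
    predicted <- floor((em$x + em$z * u * dtan + 20 * ds) / ds) + 1
    expect_identical(unname(hit[1, 2]), as.integer(predicted))
  }
  # fitted centroid displacement is linear in u with slope z * dtan
  us <- -7:7
  cents <- vapply(us, function(u) {
    img <- extractPerspective(lf, u, 0)
    sum(col(img) * img) / sum(img)
  }, numeric(1))
  slope <- stats::coef(stats::lm(cents ~ us))[2] * ds
  expect_equal(unname(slope), 30 * dtan, tolerance = 0.1)
})

test_that("sub-pitch mirror shifts move the binning boundaries", {
  cfg <- OpticalConfig(lensesPerTile = 20L)
  ds <- sampleSampling(cfg)
  # emitter a hair past a bin edge: an extra +ds/3 shift moves it one bin
  x0 <- -10 * ds
  xe <- x0 + 5 * ds + 0.1 * ds
  sc <- plenoscope:::Scene(data.frame(x = xe, y = 0, z = 0, intensity = 1),
                           extent = c(-31, 31, -31, 31))
  i1 <- which(extractPerspective(renderLightField(sc, cfg), 0, 0) > 0,
              arr.ind = TRUE)
  i2 <- which(extractPerspective(
    renderLightField(sc, cfg, acquisitionEvent(dx = ds / 3)), 0, 0) > 0,
    arr.ind = TRUE)
  expect_identical(unname(i1[1, 2] - i2[1, 2]), 1L)  # boundary moved past it
})

test_that("raw rendering applies the noise model reproducibly", {
  cfg <- OpticalConfig(lensesPerTile = 8L)
  scene <- makeBeadScene(3, extent = 12, zRange = c(0, 0), seed = 5L)
  # identity model: exact inverse pair with rectification
  raw0 <- renderRaw(scene, cfg, noise = noiseOff())
  cal <- GridCalibration(origin = c(8, 8), pitchPx = 15, rotation = 0,
                         nLenses = c(8L, 8L), residualRms = 0)
  lf <- rectify(raw0, cal, cfg)
  expect_equal(lf@intensities, renderLightField(scene, cfg)@intensities,
               tolerance = 1e-12)
  # dark scene reads the offset, within read noise
  dark <- plenoscope:::Scene(
    data.frame(x = numeric(), y = numeric(), z = numeric(),
               intensity = numeric()), extent = c(-1, 1, -1, 1))
  d <- renderRaw(dark, cfg, acquisitionEvent(seed = 3L), NoiseModel())
  expect_equal(mean(framePixels(d)), 100, tolerance = 0.1)
  expect_equal(stats::sd(framePixels(d)), 2, tolerance = 0.1)
  # same seed gives identical frames, different seeds differ
  a <- renderRaw(scene, cfg, acquisitionEvent(seed = 4L), NoiseModel())
  b <- renderRaw(scene, cfg, acquisitionEvent(seed = 4L), NoiseModel())
  c <- renderRaw(scene, cfg, acquisitionEvent(seed = 5L), NoiseModel())
  expect_identical(framePixels(a), framePixels(b))
  expect_false(identical(framePixels(a), framePixels(c)))
})

test_that("doubling exposure doubles the mean signal above the offset", {
  cfg <- OpticalConfig(lensesPerTile = 8L)
  scene <- makeBeadScene(10, extent = 20, zRange = c(0, 0), seed = 6L,
                         intensity = 2e4)
  m <- vapply(1:8, function(s) {
    e1 <- acquisitionEvent(seed = s)
    e2 <- acquisitionEvent(exposureScale = 2, seed = 100L + s)
    c(mean(framePixels(renderRaw(scene, cfg, e1, NoiseModel()))) - 100,
      mean(framePixels(renderRaw(scene, cfg, e2, NoiseModel()))) - 100)
  }, numeric(2))
  expect_equal(mean(m[2, ]) / mean(m[1, ]), 2, tolerance = 0.02)
})

test_that("sequence rendering follows the pattern deterministically", {
  cfg <- OpticalConfig(lensesPerTile = 10L)
  scene <- makeBeadScene(4, extent = 15, zRange = c(0, 0), seed = 2L)
  s9 <- renderSequence(scene, cfg, subpixelPattern(3, cfg), seed = 1L)
  expect_length(s9, 9L)
  s25 <- renderSequence(scene, cfg, tilePattern(c(5, 5), 0.217, cfg),
                        noiseOff(), seed = 1L)
  expect_length(s25, 25L)
  empty <- subpixelPattern(1, cfg)
  empty@entries <- empty@entries[integer(0), ]
  expect_error(renderSequence(scene, cfg, empty), "non-empty")
  # per-frame seeds derive from the master seed
  t1 <- renderSequence(scene, cfg, subpixelPattern(2, cfg), seed = 7L)
  t2 <- renderSequence(scene, cfg, subpixelPattern(2, cfg), seed = 7L)
  for (i in seq_along(t1))
    expect_identical(framePixels(t1[[i]]), framePixels(t2[[i]]))
})
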