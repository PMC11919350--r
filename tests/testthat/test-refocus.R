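test_that("perspective extraction slices the field and checks bounds", {
  cfg <- OpticalConfig(lensesPerTile = 10L)
  lf <- LightField4D(array(3, c(10, 10, 15, 15)), 3.1)
  expect_equal(extractPerspective(lf, 0, 0), matrix(3, 10, 10))
  expect_equal(extractPerspective(lf, -7, 7), matrix(3, 10, 10))
  expect_error(extractPerspective(lf, 8, 0), "out of range")
  expect_error(extractPerspective(lf, 0, -8), "out of range")
})

test_that("refocusing concentrates energy at the source depth", {
  cfg <- smallConfig()
  k <- disparitySlope(cfg)
  scene <- makeBeadScene(1, extent = 8, zRange = c(30, 30), seed = 1L)
  lf <- renderLightField(scene, cfg)
  r30 <- refocus(lf, 30, k)
  pk <- which(r30 == max(r30), arr.ind = TRUE)[1, ]
  nb <- r30[(pk[1] - 1):(pk[1] + 1), (pk[2] - 1):(pk[2] + 1)]
  expect_gt(sum(nb) / sum(r30), 0.6)
  # defocused rendering spreads the bead across the parallax disc
  r0 <- refocus(lf, 0, k)
  expect_gt(sum(r0 > max(r0) * 0.01), 2 * k * 30 * 7)
  # z = 0 is the exact mean of the perspectives
  expect_equal(refocus(lf, 0, k), apply(lf@intensities, c(1, 2), mean),
               tolerance = 1e-12)
})

test_that("a planar scene is sharpest at its own depth", {
  cfg <- smallConfig()
  k <- disparitySlope(cfg)
  sc <- makeUsafScene(data.frame(group = 6, element = 2), extent = 90)
  lf <- renderLightField(sc, cfg)
  sharp <- function(img) stats::var(as.vector(plenoscope:::laplacian3(img)))
  s0 <- sharp(refocus(lf, 0, k))
  for (z in c(-20, -10, 10, 20))
    expect_lt(sharp(refocus(lf, z, k)), s0)
})

test_that("focal stacks cover the inclusive depth range", {
  cfg <- OpticalConfig(lensesPerTile = 12L)
  lf <- renderLightField(makeBeadScene(2, 15, c(0, 0), 1L), cfg)
  k <- disparitySlope(cfg)
  st <- focalStack(lf, -50, 50, 2.5, k)
  expect_length(stackDepths(st), 41L)
  st40 <- focalStack(lf, -48.75, 48.75, 2.5, k)
  expect_length(stackDepths(st40), 40L)   # the instrument's 40-plane stacks
  one <- focalStack(lf, 10, 10, 5, k)
  expect_equal(stackPlane(one, 1), refocus(lf, 10, k), tolerance = 1e-12)
  expect_error(focalStack(lf, 0, 10, 0, k), "dz")
  expect_error(focalStack(lf, 10, 0, 2, k), "empty")
})

test_that("depth of best focus recovers bead depths within one step", {
  cfg <- smallConfig()
  ds <- sampleSampling(cfg)
  zTrue <- c(-40, -20, 0, 20, 40)
  xs <- c(-30, -15, 0, 15, 30)
  scene <- plenoscope:::Scene(
    data.frame(x = xs, y = 0, z = zTrue, intensity = 1e4),
    extent = c(-40, 40, -40, 40))
  lf <- renderLightField(scene, cfg)
  st <- focalStack(lf, -50, 50, 5, disparitySlope(cfg))
  for (i in seq_along(zTrue)) {
    col <- floor((xs[i] + 20 * ds) / ds) + 1
    win <- c(14L, 26L, col - 4L, col + 4L)
    expect_lte(abs(bestFocusDepth(st, win) - zTrue[i]), 5)
  }
  expect_error(bestFocusDepth(st, c(0L, 10L, 1L, 10L)), "window")
})

test_that("planar USAF scene focuses at its plane within one step", {
  cfg <- smallConfig()
  sc <- makeUsafScene(data.frame(group = 6, element = c(4, 6)), extent = 120)
  lf <- renderLightField(sc, cfg)
  st <- focalStack(lf, -20, 20, 4, disparitySlope(cfg))
  expect_lte(abs(bestFocusDepth(st)), 4)
  # uniform stack: documented tie-break toward smallest |z|
  flat <- FocalStack(array(1, c(8, 8, 5)), c(-10, -5, 0, 5, 10), 3.1)
  expect_identical(bestFocusDepth(flat), 0)
})

test_that("refocus conserves mean intensity and respects scene symmetry", {
  cfg <- usafConfig()
  ds <- sampleSampling(cfg)
  k <- disparitySlope(cfg)
  # textured planar scene: fully-valid interior keeps the 4D mean
  W <- 60 * ds
  rp <- ds / 15
  xs <- seq(-W / 2 + rp / 2, W / 2 - rp / 4, by = rp)
  g <- expand.grid(x = xs, y = xs)
  scene <- plenoscope:::Scene(
    data.frame(x = g$x, y = g$y, z = 0,
               intensity = 1 + 0.8 * sin(2 * pi * g$x / 12.4)),
    extent = c(-1, 1, -1, 1) * W / 2)
  lf <- renderLightField(scene, cfg)
  m4 <- mean(lf@intensities)
  for (z in c(-50, -20, 0, 20, 50)) {
    s <- ceiling(k * abs(z) * 7) + 2L
    interior <- (s + 1L):(60L - s)
    expect_equal(mean(refocus(lf, z, k)[interior, interior]), m4,
                 tolerance = 0.01)
  }
  # point-symmetric scene: refocus at +z mirrors refocus at -z
  cfg2 <- smallConfig()
  k2 <- disparitySlope(cfg2)
  sym <- plenoscope:::Scene(
    data.frame(x = c(13.95, -13.95), y = c(7.75, -7.75), z = c(25, -25),
               intensity = 1),
    extent = c(-40, 40, -40, 40))
  lfs <- renderLightField(sym, cfg2)
  a <- refocus(lfs, 25, k2)
  b <- refocus(lfs, -25, k2)
  flipped <- b[rev(seq_len(nrow(b))), rev(seq_len(ncol(b)))]
  expect_lt(sqrt(mean((a - flipped)^2)) / max(a), 1e-3)
})
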