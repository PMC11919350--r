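# Shared fixtures, built once per test run and memoized across files.
# Everything is generated in code; no stored imagery.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# 40-lens instrument used by most pipeline tests (124 um tile)
smallConfig <- function() OpticalConfig(lensesPerTile = 40L)

# 60-lens instrument for the USAF resolution experiments (186 um tile)
usafConfig <- function() OpticalConfig(lensesPerTile = 60L)

usafSceneGroups67 <- function() {
  cfg <- usafConfig()
  fixture("usafScene", function()
    makeUsafScene(usafElements(6:7)[c("group", "element")],
                  extent = tileFov(cfg)))
}

# shared calibration from a noisy synthetic white frame
usafCalibration <- function() {
  fixture("usafCal", function()
    calibrateGrid(renderWhiteFrame(usafConfig(), noise = NoiseModel(),
                                   seed = 99L), 15))
}

# conventional single-capture reconstruction of the USAF scene (refocused
# at z = 0, dark level subtracted)
usafConventional <- function() {
  fixture("usafConv", function() {
    cfg <- usafConfig()
    raw <- renderRaw(usafSceneGroups67(), cfg, acquisitionEvent(seed = 11L),
                     NoiseModel())
    refocus(rectify(raw, usafCalibration(), cfg, darkOffset = 100), 0,
            disparitySlope(cfg))
  })
}

# 3x3 sub-pitch fused reconstruction of the same scene
usafFused <- function() {
  fixture("usafFused", function() {
    cfg <- usafConfig()
    pat <- subpixelPattern(3, cfg)
    frames <- renderSequence(usafSceneGroups67(), cfg, pat, NoiseModel(),
                             seed = 11L)
    imgs <- lapply(frames, function(fr)
      refocus(rectify(fr, usafCalibration(), cfg, darkOffset = 100), 0,
              disparitySlope(cfg)))
    fuseShiftedImages(imgs, pat, 3)
  })
}

usafOrigin <- function() -c(1, 1) * tileFov(usafConfig()) / 2

# 25-tile aggregate mosaic against a directly rendered ground truth
mosaic25 <- function() {
  fixture("mosaic25", function() {
    cfg <- smallConfig()
    ds <- sampleSampling(cfg)
    pat <- tilePattern(c(5, 5), 0.25, cfg)
    scene <- makeAggregateScene(16, capsuleRadius = 22,
                                nucleiPerCapsule = 20, seed = 5L,
                                extent = 430)
    cal <- calibrateGrid(renderWhiteFrame(cfg, noise = NoiseModel(),
                                          seed = 50L), 15)
    frames <- renderSequence(scene, cfg, pat, NoiseModel(), seed = 9L)
    res <- stitchSequence(frames, cal, cfg, pat, z = 0, darkOffset = 100)
    span <- tileSpan(5, 0.25, cfg)
    gcfg <- OpticalConfig(lensesPerTile = as.integer(round(span / ds)))
    gt <- refocus(renderLightField(scene, gcfg), 0, disparitySlope(gcfg))
    list(res = res, gt = gt, pattern = pat, scene = scene, config = cfg)
  })
}

# smooth band-limited random texture for registration tests
smoothTexture <- function(n = 300, seed = 3L) {
  fixture(paste0("tex", n, "_", seed), function() {
    set.seed(seed)
    g <- stats::dnorm(-6:6, sd = 2)
    m <- matrix(stats::rnorm(n * n), n, n)
    apply(apply(m, 2, function(cc) stats::filter(cc, g, circular = TRUE)), 1,
          function(rr) stats::filter(rr, g, circular = TRUE))
  })
}

# render a single in-focus delta and return the refocused tile image
refocusedDelta <- function(xc, yc, cfg, event = acquisitionEvent()) {
  scene <- plenoscope:::Scene(
    data.frame(x = xc, y = yc, z = 0, intensity = 1),
    extent = c(-1, 1, -1, 1) * tileFov(cfg) / 2)
  refocus(renderLightField(scene, cfg, event), 0, disparitySlope(cfg))
}
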