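# plenoscope

Processing chain for **mirror-scanned light-field microscopy**: an R
package for reconstructing, fusing and planning acquisitions of a
light-field (plenoptic) microscope augmented with a motorized tilting
mirror in the Fourier plane of its detection module. It is written for
microscopists and imaging-methods developers who want to prototype or
validate this acquisition scheme without standing at the instrument: a
geometric-optics forward simulator generates raw sensor frames from 3D
phantoms, and every processing stage runs on either simulated or real
TIFF data.

## What it computes

A plenoptic camera records the 4D light field *I(x, y, u, v)* — lateral
position at the microlens pitch (3.1 µm in the sample plane for the
default 20×/NA 0.75 instrument with a 100 µm MLA), direction across the
15×15 sensor pixels under each lens. The package implements:

* **Rectification** — microlens grid calibration on a white frame
  (centroid detection + least-squares similarity fit), then per-lens
  bilinear extraction of the 4D field, with dark-level subtraction.
* **Shift-and-sum refocusing** — the image focused at depth *z* is the
  valid-weight-normalized mean of the perspectives, each translated by
  −*k z*·(*u*, *v*) samples, with disparity slope
  *k* = tan(asin(NA/n)) / (*u*max·Δs) ≈ 0.052 samples per (index·µm);
  focal stacks and depth-from-focus (Laplacian variance) included.
* **Sub-pitch super-resolution** — n² captures shifted by Δs/n (a third
  of a microlens = 5 sensor pixels for n = 3) are fused by deterministic
  pixel interleaving onto an n-fold finer lattice: nine 140×140×40
  stacks become one 420×420×40 volume, intensity conserved exactly.
* **Extended-FOV mosaicking** — tile scans (5×5 = 25 captures spanning
  ~1.86 mm with 450 µm tiles at 21.7% overlap) are registered pairwise by
  Tukey-windowed phase correlation on the nominal overlap strips, placed
  by a maximum-score spanning tree, and feather-blended.
* **Adaptive scan planning** — sub-pitch, tile and ROI-driven mirror
  patterns, serialized as CSV for the simulator or an instrument.
* **USAF-1951 metrology** — tri-bar Michelson contrast on smoothed
  profiles at known element positions, smallest-resolvable-element walks,
  bead FWHM.

The S4 classes (`OpticalConfig`, `Scene`, `ScanPattern`, `LightField4D`,
`FocalStack`, `GridCalibration`, `MosaicLayout`) carry the data between
stages; TIFF + YAML-sidecar and CSV readers/writers cover the file
formats, and `inst/cli/lfm.R` exposes the chain as a command line
(`plan | simulate | rectify | refocus | superres | stitch | measure`).

## Worked example: the resolution-doubling experiment

Simulate a USAF-1951 target (groups 6–7) on a reduced 60×60-lens tile,
reconstruct one conventional capture and a 3×3 sub-pitch-fused image, and
measure which element each resolves:

```r
library(plenoscope)
cfg <- OpticalConfig(lensesPerTile = 60L)
scene <- makeUsafScene(usafElements(6:7)[c("group", "element")],
                       extent = tileFov(cfg))
cal <- calibrateGrid(renderWhiteFrame(cfg, noise = NoiseModel(), seed = 2), 15)

raw  <- renderRaw(scene, cfg, acquisitionEvent(seed = 1), NoiseModel())
conv <- refocus(rectify(raw, cal, cfg, darkOffset = 100), 0, disparitySlope(cfg))
smallestResolvable(conv, scene, sampleSampling(cfg), -c(1, 1) * tileFov(cfg) / 2)
#>   group element lineWidth contrastH contrastV
#> 1     6       3  6.200785   0.32468 0.3246326

pat    <- subpixelPattern(3, cfg)
frames <- renderSequence(scene, cfg, pat, NoiseModel(), seed = 1)
imgs   <- lapply(frames, function(fr)
  refocus(rectify(fr, cal, cfg, darkOffset = 100), 0, disparitySlope(cfg)))
fused  <- fuseShiftedImages(imgs, pat, 3)
smallestResolvable(fused, scene, sampleSampling(cfg) / 3,
                   -c(1, 1) * tileFov(cfg) / 2 +
                     fusedOriginOffset(sampleSampling(cfg), 3))
#>   group element lineWidth contrastH contrastV
#> 1     7       5  2.460783 0.2580817 0.2554809
```

The conventional reconstruction stops at group 6 element 3 — 6.2 µm bars,
the Nyquist limit of 3.1 µm sampling — with Michelson contrast 0.32 in
both orientations. The nine-fold acquisition resolves group 7 element 5
(2.46 µm bars, contrast ≈ 0.26): a 6.20/2.46 ≈ 2.5-fold, i.e. roughly
3-fold, resolution improvement for a 9× longer acquisition. (Under the
package's geometric model the fused limit sits one element short of the
2.19 µm the hardware reaches, because the 3.1 µm microlens box kernel
survives interleaving — see the methods vignette.)

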