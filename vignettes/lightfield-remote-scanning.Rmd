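---
title: "Mirror-scanned light-field microscopy: models and methods"
author: "plenoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror-scanned light-field microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The instrument and its trade-off

A light-field (plenoptic) microscope places a microlens array (MLA) in an
image plane and re-images the MLA's back focal plane onto the camera. Each
microlens becomes one *spatial* sample whose block of sensor pixels encodes
the *direction* of the light reaching it, so a single exposure records the
4D field $I(x, y, u, v)$: lateral position $(x, y)$ at the pitch of the
MLA, propagation direction $(u, v)$ at the pixel pitch underneath each
lens. The price is the spatial/angular trade: with a 100 µm pitch MLA
demagnified to 3.1 µm in the sample plane and 15×15 pixels per lens, one
camera tile covers only ~140×140 spatial samples (a 450 µm-class field)
at 6.2 µm Nyquist-limited lateral resolution.

`plenoscope` models the augmentation that relaxes this trade: a motorized
tilting mirror in the Fourier plane of the detection module. A tilt there
translates the image laterally on the MLA without changing viewing angles,
so sequences of captures can either *refine the sampling lattice*
(sub-pitch shifts, fused by pixel interleaving) or *extend the field of
view* (tile-scale shifts, stitched in the spatial domain), or both,
adaptively per region of interest.

The package contains the full processing chain (rectification, refocusing,
fusion, stitching, planning, metrology) plus a geometric-optics forward
simulator that stands in for the instrument, so every stage is testable
without hardware.

## Conventions

Stated once here and used everywhere:

* images are matrices `[row = y, col = x]`, origin top-left, y down;
* a tile of $n_L$ lenses spans $[-W/2, W/2]$ per axis,
  $W = n_L \Delta_s$, with $\Delta_s$ = `sampleSampling(config)` (µm);
* angular indices $(u, v)$ are centered integers in $[-u_{max}, u_{max}]$,
  $u_{max} = (P-1)/2$ for $P$ = `pixelsPerLens`; $(0,0)$ is the central
  perspective;
* depth $z$ is signed µm, positive toward the objective, $z = 0$ at the
  native focal plane.

`totalMagnification` is a stored calibration value, not derived from relay
focal lengths: the pitch-to-sample-plane mapping (100 µm → 3.1 µm,
i.e. 32.26×) *defines* the geometry. The refractive index of the medium
defaults to 1 (air objective); immersion mismatch is not modeled.

## The forward model

Each perspective is treated as a pinhole view: an emitter at
$(x_e, y_e, z_e)$ appears in perspective $(u, v)$ at

$$x = x_e + z_e\, u\, \Delta_{tan}, \qquad
  \Delta_{tan} = \tan(\arcsin(\mathrm{NA}/n))/u_{max},$$

and is box-integrated into the microlens cell containing that position
(nearest-cell assignment of a dense emitter raster). Emitter intensity is
split equally over the $P^2$ angular samples; flux is conserved exactly up
to clipping at the tile edge. Defocus therefore manifests *only* as
parallax plus cell binning — there is no wave-optics blur, no vignetting,
no field-dependent aberration. This is the minimal model under which
shift-and-sum refocusing, sub-pitch super-resolution and Nyquist
resolvability limits all behave like the physical system.

Consequences worth knowing:

* **Alias contrast is real.** Bar patterns finer than the lattice still
  leave high local contrast in a box-sampled image (that residual aliasing
  is exactly what sub-pitch fusion exploits); whether such a pattern counts
  as *resolved* is a metrology question (below), not a rendering one.
* **The microlens box PSF survives fusion.** Interleaving shifts of the
  same $\Delta_s$-wide boxes refines the sampling lattice, not the kernel,
  so fused point images keep their single-capture footprint — the package
  reproduces the observation that bead FWHM does not improve under fusion,
  and the smallest fused-resolvable tri-bar element in simulation is group
  7 element 5 (2.46 µm) at the default 0.2 contrast criterion, one element
  shy of the hardware figure. The conventional endpoint (group 6 element 3,
  6.2 µm) and the ~3-fold improvement ratio are reproduced exactly.

The noise model is sCMOS-like: Poisson photon noise, linear gain
(1 count/photon), dark offset (100 counts), Gaussian read noise
(2 counts RMS) — typical values, exposed in `NoiseModel()` and disabled by
`noiseOff()`. All randomness flows through explicit seeds; sequences derive
per-frame seeds deterministically from a master seed.

Scene generators emulate the study's samples: USAF-1951 tri-bar targets
(shelf-packed blocks with 5:1 bar geometry, placements recorded for
metrology), uniform random bead fields, and encapsulated multi-cellular
aggregates — capsules on a jittered non-overlapping grid, nuclei sampled on
the capsule shell (a hollow arrangement), and the alginate wall itself
rendered as scattered surface points, which is what makes bright-field
tiles feature-rich enough to register. The default raster pitch for dense
targets is $\Delta_s/15 \approx 0.207$ µm: below the 0.25 µm bound needed
to supersample 2.19 µm bars ≥ 8-fold, and commensurate with both the
microlens cell and its 3-fold refinement so box integration is
phase-independent.

What the simulator deliberately does not reproduce: diffraction (the
410 nm-class objective limit), scattering and depth-dependent image
degradation, photobleaching, mirror settle time and vibration. Passing
tests therefore validate the *processing chain* against an idealized
instrument; they do not certify performance on real tissue.

## Rectification

Calibration uses a uniform-illumination (white) frame, on which each lens
images the pupil as one smooth peak. `calibrateGrid()` detects one maximum
per lens, refines it by intensity centroid, assigns integer lattice
indices, and fits a similarity transform (origin, pitch, rotation) by
linear least squares, reporting the RMS residual. `rectify()` then samples
each angular position by bilinear interpolation on the rotated grid;
partial edge lenses are discarded (only complete $P\times P$ blocks are
kept, trimmed greedily from the border with the largest misfit fraction).
On an axis-aligned integer grid this reduces to exact pixel extraction, so
rectification is the exact inverse of raw rendering without noise.
A uniform dark level can be subtracted at this stage (`darkOffset`),
clamping at zero — the standard dark-frame correction, needed before any
contrast metrology.

## Shift-and-sum refocusing

A perspective is the spatial slice at fixed $(u, v)$. Refocusing at depth
$z$ translates perspective $(u,v)$ by $(-k z u, -k z v)$ samples and
averages, with

$$k = \frac{\tan(\arcsin(\mathrm{NA}/n))}{u_{max}\, \Delta_s}
  \approx 0.052\ \text{samples per (index · µm)}$$

for the default instrument (`disparitySlope()`). The sign convention is
fixed by the round trip: a point rendered at $z$ by the simulator refocuses
sharply at $z$. Sub-sample shifts use bilinear interpolation; out-of-frame
samples are excluded from the per-pixel mean by valid-weight normalization,
which avoids vignette-like dimming at tile borders (important for
mosaics). At $z=0$ the operation is the exact mean of all perspectives.

Depth-from-focus uses the variance of a 3×3 Laplacian in a window;
sharpness ties break toward the smallest $|z|$, then the first plane. With
beads across ±40 µm, the recovered depth matches truth within one z-step
over a focal stack spanning ±50 µm — the ~100 µm usable refocusing range.

## Scan planning

* `subpixelPattern(n)`: the $n^2$ residues of the lattice refined $n$-fold,
  raster-ordered; for $n = 3$ each step is $\Delta_s/3$ (5 sensor pixels).
  $n = 8$ would be the diffraction-limit regime.
* `tilePattern(grid, overlap)`: serpentine-ordered centered grid with step
  $\mathrm{FOV}_{tile}(1-\text{overlap})$. The default overlap 0.217 is
  back-computed so that five 450 µm tiles span 1.86 mm per axis; it is a
  configuration value, not a measurement.
* `adaptivePattern(rois, nSub)`: the minimal subset of grid tiles
  intersecting any ROI, each expanded by a sub-pitch raster — the
  capture-only-what-matters mode for sparse samples.
* `tiltToShift()`: mirror tilt to lateral shift is modeled linearly with a
  user-supplied µm/mrad scale (small angles); the hardware calibration
  procedure itself is out of scope.

## Sub-pitch fusion

`fuseShifted()` interleaves $n^2$ reconstructions onto an $n$-fold finer
lattice: the capture with sub-index $(s_x, s_y)$ fills output voxels
$[(y-1)n + s_y + 1,\ (x-1)n + s_x + 1,\ z]$. No interpolation, no
re-weighting, every output voxel sourced from exactly one input voxel, so
intensity is conserved exactly. A capture shifted by $+s\Delta_s/n$ samples
the scene on a lattice displaced by the same amount, which places its
pixels at fine-lattice residue $s$; the fused grid origin is consequently
displaced by $(n-1)/(2n)\,\Delta_s$ (`fusedOriginOffset()`). The sign of
the mapping is pinned by two simulator round trips: a delta's fused support
must be $n$ consecutive fine pixels centered on the emitter, and a
step edge must fuse into a monotone profile (the reversed mapping visibly
scrambles it).

## Extended-FOV stitching

Stitching operates on refocused (spatial-domain) tiles, one plane
registering for all. For each adjacent pair the tiles are cropped to the
nominally overlapping strip (±8 px margin), the residual translation is
found by phase correlation — normalized cross-power spectrum, 20%-taper
Tukey window to suppress frame-edge leakage, the best few peaks
disambiguated among their periodic unwrappings by direct normalized cross
correlation on the overlap (candidates with < 5% overlap rejected) — and
the pair offset is nominal plus residual. Global placement walks a
maximum-score spanning tree anchored at the most central tile; pairs
scoring < 0.3 fall back to their nominal displacement (a fully-nominal
layout is a warning, not a failure — blank tiles from empty capsule regions
do this by design). Blending is linear feathering: per-pixel weights equal
to the distance to the tile border, normalized over covering tiles
(partition of unity by construction), positions rounded to integer canvas
pixels, uncovered pixels zero with a coverage mask attached.

On a simulated 5×5 aggregate scan the mosaic matches a directly rendered
full-field ground truth within 2% RMSE of the dynamic range away from
borders, with all 40 adjacent pairs registered at their nominal offsets.

## Resolution metrology

Profiles are extracted perpendicular to the bars at the *known* simulated
element positions (no bar detection), averaged over the central 60% of the
bar length and extended half a bar width beyond the outer bars.
`barContrast()` smooths with a plain 3-sample moving average, finds the
plateau-aware local maxima, keeps the `nBars` strongest, takes the minima
between them, and returns the Michelson contrast of their means — 0
whenever the max/min alternation is absent. The smoothing is the step that
separates resolution from aliasing: structure carried by single samples
does not survive it, so a bar needs roughly two samples to count, which is
the Nyquist criterion under which the conventional chain stops at
6.2 µm bars (group 6 element 3) at 3.1 µm sampling. The resolvability
threshold (0.2 Michelson, both orientations required) is exposed as a
parameter; `smallestResolvable()` walks elements coarse-to-fine and
returns the last element resolved before the first failure, which makes
the result monotone in the threshold.

`fwhm()` measures a peak's full width at half maximum with linear
interpolation; refocused bead widths land between 1 and 3 samples, and —
by the box-PSF argument above — do not shrink under fusion.

## Numerical and I/O choices

* TIFF imagery (raw frames, 4D fields in v-major page order, focal stacks,
  mosaics) is stored as 32-bit samples of data normalized by a
  power-of-two scale recorded in the YAML sidecar; round trips are exact to
  $2^{-32}$ of the dynamic range. Sidecars are schema-versioned structured
  text, one per artifact, carrying configuration, calibration, pattern
  entries, depth lists and normalization.
* Scan patterns and emitter tables are CSV; pattern coordinates are written
  at 17 significant digits so the decimal text round-trips doubles exactly.
* Seeds: every stochastic output takes an explicit integer seed;
  per-event seeds derive from the master seed by a fixed splitting rule,
  and all derived seeds stay below $2^{31}$.

## Problem sizes

The test suite and the reproduction script run the chain at reduced but
structurally faithful sizes, chosen so each experiment still contains the
feature it probes: USAF experiments on a 60×60-lens tile holding groups
6–7; depth-recovery and fusion oracles on 20–40-lens tiles; the mosaic
validation on 5×5 scans of 40-lens tiles (25 captures, ~500 µm span)
against a directly rendered 160-lens ground truth; fusion dimension checks
on full-size 140×140×40 arrays.

## Known limitations

* Geometric optics only: no diffraction-limited PSF, hence no meaningful
  absolute FWHM in µm below the sampling scale, and fused resolution in
  simulation is bounded by the box kernel rather than by diffraction.
* Square MLA grids only; no per-lens distortion model.
* Stitching assumes rigid translations between tiles; no illumination
  flattening across tiles, no non-rigid registration.
* The mirror is a pure, instantaneous lateral shift: settle time,
  vibration and angle-dependent aberrations are not modeled.
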