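---
title: "Optical sizing and acoustic characterization of microbubbles: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical sizing and acoustic characterization of microbubbles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbsizer)
```

## The measurement problem

Lipid-shelled microbubbles are micron-scale ultrasound contrast agents.
During formulation work three quantities must be re-measured cheaply after
every change to the shell chemistry: the size distribution (bubble radii
set the resonant frequency), the concentration (dosing), and the relative
echogenicity (does the formulation still scatter ultrasound?). This
package implements that workflow end to end: automated segmentation of
brightfield micrographs, population statistics and volumetric
concentration, and mean-intensity/decibel analysis of B-mode phantom
images — together with synthetic image generators that provide exact
ground truth, so that every stage is validated without access to a
microscope or scanner.

## The optical segmentation chain

A frame is processed in a fixed order, with no randomness anywhere:

1. **8-bit conversion.** 16-bit frames are mapped linearly from their own
   `[min, max]` onto `[0, 255]` with round-half-away. A constant frame has
   no range and maps to zeros with a warning.
2. **Polarity.** Brightfield bubbles are darker than the background (a
   dark rim around a slightly brighter gas core), so the default
   `polarity = "dark"` inverts the 8-bit image; everything downstream
   treats objects as bright. Before background estimation the working
   image is clamped from below at its median: the greyscale opening used
   next estimates the background as a *lower envelope*, and
   sub-background pits (the bubble cores after inversion) would otherwise
   drag that envelope down wherever a core falls within the structuring
   radius — in a dense field that collapses the background estimate
   entirely. The clamp assumes objects cover less than half the frame,
   which holds for any sensibly diluted sample.
3. **Gaussian blur** (`blur_sigma_px`, default 1 px), separable
   convolution with reflective boundaries.
4. **Background subtraction** (`background_radius_px`, default 50 px):
   greyscale morphological opening with a disk — the rolling-ball
   analogue — subtracted and clipped at zero. The radius must dwarf any
   bubble so that only slow illumination trends are removed.
5. **Autothreshold.** Either Otsu's between-class-variance criterion or
   Kapur's maximum-entropy criterion, both computed exhaustively over the
   256-level histogram with ties broken toward the lower level for
   determinism. Both implementations are verified in the test suite
   against independent brute-force scans.
6. **Binarization and hole filling.** The rim of a bubble encloses a
   brighter core; without hole filling the detected object would be an
   annulus and its area (hence radius) meaningless. `fill_holes = TRUE`
   by default.
7. **Watershed declumping** on the Euclidean distance transform.
   `watershed_tolerance` (default 0.5 px) is the minimum peak-to-saddle
   depth that keeps two peaks separate: 0.5 px separates heavily fused
   pairs (centre separation down to 1.2 × mean radius) without
   fragmenting single disks of any radius we tested (3–60 px).
8. **Outlier-pixel removal** (`outlier_radius_px` 2 px, `outlier_delta`
   50): pixels deviating from their neighbourhood median by more than the
   delta are replaced by that median; applied to the binary mask this
   strips isolated specks. A conditional median inevitably also shaves
   high-curvature corners of genuine objects (a sub-pixel effect for
   objects above ~5 px radius).
9. **Measurement.** Area (pixel count × pixel area), perimeter by the
   Crofton/Cauchy intercept estimator (crossings with line grids in four
   directions; asymptotically exact for smooth shapes, and a few percent
   different from chain-code estimators — one convention had to be fixed
   and documented), circularity `4πA/P²` clamped to ≤ 1 (single-pixel
   objects are assigned circularity 1 as a degenerate convention),
   solidity as area over convex-hull pixel area, equivalent radius
   `sqrt(A/π)`, centroid, and a border flag.
10. **Pruning and shape filtering.** Objects below `min_area_px`
    (default 4 px) are dropped. Border objects follow the
    `exclude_border` rule, default `"unbiased"`: only objects touching
    the top or left edge are rejected — the standard unbiased
    counting-frame rule, under which each object is counted exactly once
    across a tiling of frames. Excluding *all* border objects (`"all"`)
    is offered for strict sizing but undercounts by roughly the
    perimeter-to-area ratio of the frame. Finally `filter_criteria`
    applies closed intervals on circularity, solidity and radius.

### Why these defaults

The only guidance the workflow inherits is that thresholding must not
overly process the image, plus the practice of calibrating on polystyrene
bead standards. We reproduced that calibration on synthetic monodisperse
bead fields (solid dark disks of 0.5 µm and 1.5 µm radius at 0.16 µm/px —
the 1 µm and 3 µm diameter standards): with `blur_sigma_px = 1` and the
Otsu threshold, recovered mean radii are within about 6 % and 1 % of
truth. A heavier blur (2 px) smears 3-px-radius beads into larger masks,
and the maximum-entropy criterion systematically picks a low threshold on
these sparse-foreground images, inflating small objects by 35–60 %. Otsu
is therefore the default; MaxEntropy remains available and is equally
oracle-verified.

### Known measurement biases

* Bubble-style objects (rim renderings) are sized at the *outer edge* of
  the dark rim; for a 1.5 µm bubble at 0.16 µm/px this overestimates the
  radius by roughly 0.2–0.3 µm. Solid bead-style objects do not show this
  bias. Bead calibration quantifies exactly this class of offset.
* Pairs of overlapping objects whose centre separation is small relative
  to the larger radius can fuse irrecoverably; see the generator notes
  below.

## Population statistics

Radii are pooled across the replicate frames of one sample (not averaged
per frame first). The histogram uses `n_bins = round(sqrt(N))` — nearest
integer, half away from zero, floor of one bin — over `[min, max]` of the
pooled radii, right-closed bins with the lowest bin closed on both sides.
Diameter is exactly `2r`. The imaged volume per frame is
`rows × cols × pixel_size² × chamber_height × 1e-12` mL; concentration is
the mean per-frame count divided by that volume times the dilution
factor, and the quoted ± is the SD of per-frame counts through the same
division (a replicate-frame SD, not an SEM — the convention is stated in
the output). A single frame yields SD 0 with a warning.

## Acoustic well analysis

Wells bored in an agarose phantom have a known 8 mm diameter; the ROI
width in pixels comes from the frame's pixel pitch, with rectangular
(default, echo-band height set explicitly) or circular shapes. The
pixelwise mean of the pre-injection frames is subtracted from each
post-injection frame to remove stationary transducer artifacts; clipping
at zero introduces a positive bias on pure-noise wells, so the unclipped
frames ride along as a diagnostic attribute (subtraction and ROI
averaging commute on the unclipped values, which the suite tests). The
echogenicity change is `I_dB = 10·log10(I_after/I_before)`, computed from
panel-mean intensities rather than averaging per-well dBs.

One conversion subtlety matters: the optical-path 8-bit conversion
stretches each frame by its own min–max, which is harmless for
thresholding but poisons a before/after *ratio* (each frame's extreme
speckle values would enter the statistic). `measure_well_panel` therefore
scales 16-bit B-mode frames by the fixed full-range factor 255/65535,
which preserves intensity ratios exactly; on synthetic panels the
recovered dB then matches `10·log10((B+L)/B)` to about 0.002 dB.

## The synthetic generators

`render_brightfield` emulates a thin-chamber brightfield micrograph: a
Poisson-count field of bubbles, each stamped multiplicatively as a dark
ring at radius *r* (Gaussian softness 1 px) with a 15 % brighter core —
a two-ring profile chosen deliberately so the chain must cope with
intensity on both sides of the background. Options add touching
aggregate pairs (centre separation uniform in 1.2–1.8 × the mean of the
two radii), out-of-focus objects (softness 3 px), additive Gaussian
noise, and a linear illumination gradient. `render_bead_field` renders
solid dark disks (beads have no gas core). `render_bmode_wells` builds a
speckled frame as `(background + lift·inside_well) × field` where
`field = 1 + scale·(R/E[R] − 1)` is a smoothed, unit-mean multiplicative
Rayleigh texture; the mean inside a well is `background + lift` for every
speckle scale, exactly so at scale 0. Ground truth (per-object centre,
radius, flags; per-well mask and lift; the seed) is returned alongside
every frame, and rendering is bit-reproducible for a fixed seed.

Defaults: 1024×1024 px at 0.16 µm/px (no canonical microscope geometry
exists, both are configurable), 10 µm chamber, background level 30000 of
65535, noise SD 400, illumination gradient 5 %, lognormal radii around
1.2 µm — values a practitioner would call typical for a diluted sample on
a 40× objective.

What the generators do *not* model: optical diffraction (the soft edge is
a statistical stand-in for a PSF), acoustic wave propagation or
beamformer behaviour, bubble motion, and uneven chamber filling. Passing
recovery tests on these fixtures therefore demonstrates that the
*algorithmic* chain is correct and unbiased at realistic contrast and
noise, not that any physical microscope is calibrated.

One geometric artifact is worth knowing: with the 1.2–1.8 × mean-radius
pair separation, an unequal pair drawn from a wide size distribution can
place the smaller partner's centre *inside* the larger bubble. Such a
partner is invisible in the rendered image yet present in the ground
truth, so counting recovery on aggregate-heavy polydisperse fixtures
carries an irreducible deficit of a few percent — a property of the
fixture, not of the watershed.

## Validation problem sizes

The acceptance script and suite validate at these scales, chosen as the
smallest sizes at which the statistics are meaningful: 100 random
histograms for threshold-oracle equivalence; 20 frames of 256² px per
bead size (≈ 550–600 objects each); 20 frames of 768² px at an
equivalent density of 3×10⁸ objects/mL for concentration recovery
(≈ 900 objects; recovery lands within ~5 % systematic ± 3 % counting
noise of truth, against a 15 % bound); ≥ 200 touching pairs for
declumping (94–99 % resolved across seeds, bound 90 %); five replicate
wells for the dB statistic (error ≤ 0.01 dB, bound 0.5 dB); and five-frame
batch runs re-executed to byte-identical CSVs.

## Degenerate inputs and tie-breaking

Constant frames convert to zeros with a warning and segment to an empty
record list; single-occupied-bin histograms are an error for the
threshold operators but are intercepted by `segment_image` as "no
particles". Both threshold searches break ties toward the lower level;
`bin_count` rounds half away from zero; identical pooled radii produce a
single bin spanning an epsilon interval; a single image or well yields
spread 0 with a warning rather than NA, so downstream JSON stays numeric.

## Limitations

* Calibration is always supplied per run (`pixel_size_um`,
  `pixel_pitch_mm`); TIFF resolution tags are deliberately ignored, so a
  wrong calibration propagates silently to all µm-denominated outputs.
* The chain assumes sparse objects (< 50 % cover) for the median clamp
  and a single polarity per frame.
* Rim-sized bubbles carry the outer-edge radius bias discussed above;
  comparisons between formulations measured identically are unaffected.
* The dB statistic quantifies *relative* echogenicity on processed
  B-mode greyscale; absolute scattering cross-sections would require raw
  channel data that reconstructed images cannot provide.
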