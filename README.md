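# mbsizer

Rapid benchtop characterization of microbubble ultrasound contrast agents
from two kinds of images:

* **Brightfield micrographs** of bubbles in a thin chamber of known height —
  segmented automatically to give the size distribution and the volumetric
  concentration of the sample;
* **B-mode ultrasound frames** of a multi-well tissue-mimicking phantom —
  quantified as mean ROI greyscale intensities before/after contrast
  injection and the resulting decibel change (echogenicity).

It is aimed at formulation labs iterating on lipid-shelled microbubble
designs, where size distribution, concentration and relative scattering
power must be re-measured after every reformulation.

## Methods in brief

**Optical chain.** Each frame passes through a fixed, deterministic
pipeline: 16-to-8-bit conversion → polarity inversion (bubbles are
dark-rimmed on a bright background) → Gaussian blur → morphological
background subtraction (greyscale opening with a large disk, the
rolling-ball analogue) → automatic histogram thresholding (Otsu's
between-class variance or Kapur's maximum-entropy criterion) → hole
filling → watershed declumping on the Euclidean distance transform →
outlier-pixel (conditional median) cleanup → particle measurement →
shape filtering. Per object the package reports calibrated area `A`,
Crofton-estimator perimeter `P`, circularity `4πA/P²`, solidity
(area / convex-hull area) and equivalent-circle radius `r = sqrt(A/π)`;
shape filters on circularity/solidity reject non-bubble debris.

**Population statistics.** Radii are pooled across the replicate images of
a sample and binned with the square-root rule, `n_bins = round(sqrt(N))`.
Diameters are `2r`. Concentration is

    C = mean(count per frame) / V × dilution,   V = rows × cols × p² × h × 1e-12 mL

with `p` the pixel size (µm) and `h` the chamber height (µm); the quoted
spread is the SD of per-frame counts passed through the same division.

**Acoustics.** Each well of the phantom (8 mm bore) is covered by an ROI;
the echogenicity change is

    I_dB = 10 · log10( I_after / I_before )

computed from panel-mean 8-bit intensities, with the pixelwise mean
background frame subtracted from post-injection frames to remove
stationary transducer artifacts.

**Synthetic ground truth.** Because every stage must be testable without
microscope access, the package ships generators for brightfield bubble
fields (dark annulus + brighter core, touching aggregates, out-of-focus
objects, noise, illumination gradients), monodisperse calibration-bead
fields (solid dark disks, the 1 µm / 3 µm polystyrene standard analogue)
and speckled B-mode well frames with known intensity lifts.

## Worked example

```r
library(mbsizer)

# five synthetic frames of 1.5 um-radius calibration beads, 0.16 um/px
frames <- lapply(1:5, function(s)
  render_bead_field(1.5, field_of_view_px = c(256L, 256L),
                    target_count_per_image = 30, seed = s))
records <- do.call(rbind, lapply(frames, function(f) segment_image(f$frame)))
build_distribution(records)
#> Size distribution: n = 131 objects, 11 bins (sqrt-N rule)
#>   radius 1.508 +/- 0.01173 um (mean +/- SD), range [1.483, 1.545] um

vol    <- imaged_volume(c(256, 256), 0.16, 10)   # 10 um chamber
counts <- vapply(frames, function(f) nrow(segment_image(f$frame)), numeric(1))
estimate_concentration(counts, vol)
#> Concentration: 1.562e+09 +/- 1.654e+08 particles/mL (SD over 5 images)
#>   mean count 26.20 / frame, imaged volume 1.678e-08 mL, dilution x1

# acoustic panel: three 8 mm wells lifted +3000 over a 6000 background
centers <- cbind(90, c(90, 260, 430))
mk   <- function(lift, seed) render_bmode_wells(bmode_spec(
  frame_px = c(180L, 520L), pixel_pitch_mm = 0.05, well_centers = centers,
  background_mean = 6000, well_intensity_lift = lift, seed = seed))$frame
rois <- lapply(1:3, function(k) well_roi(centers[k, ], 0.05, shape = "circle"))
summarize_wells(measure_well_panel(
  lapply(1:2, function(s) mk(0, s)), lapply(3:4, function(s) mk(3000, s)), rois))
#> Well panel (n = 3): I_after 35.04 +/- 0.03 (I_before 23.37), dB change +1.760
```

The recovered mean radius (1.508 µm vs. the true 1.5 µm), the counts/volume
concentration, and the +1.760 dB panel change (theory:
`10·log10(9000/6000) = 1.761 dB`) illustrate the three outputs of the
workflow.

A thin command-line front end wrapping the same functions ships at
`inst/cli/mbsizer.R` with subcommands `simulate`, `segment`, `sizes`,
`concentration` and `wells`; each run writes its fully resolved
configuration next to its outputs.

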