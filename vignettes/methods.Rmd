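---
title: "Quantifying the synaptic vesicle replacement zone: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the synaptic vesicle replacement zone: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclezone)
```

## Scope

`vesiclezone` implements, as one tested pipeline, the quantification chains
used to characterize the ~20-nm "replacement zone" adjacent to the
presynaptic active zone (AZ): 2D STED punctum morphometry relative to the
Bassoon scaffold, electron-microscopy (EM) vesicle docking/distance
morphometry, condensate dynamics metrics (FRAP, coefficient-of-variation
dispersion, activity-driven dispersion time courses), glutamate-sensor
paired-pulse analysis, and readily-releasable-pool (RRP) estimation by
cumulative back-extrapolation. Because no raw imaging or slice data are
publicly deposited, every analysis stage is exercised on synthetic data with
planted ground truth; the generators are first-class, tested code.

## STED morphometry

The analysis chain mirrors the standard side-view-synapse workflow:

1. **Pre-smoothing.** A Gaussian blur of radius 1.2 px reduces Poisson noise
   (`preblur()`). Circular FFT convolution with a normalized kernel
   conserves total intensity to well below 0.1%.
2. **Two-pass blind deconvolution.** `blind_deconvolve()` runs blind
   Richardson-Lucy alternation (multiplicative image and PSF updates), ten
   iterations per pass, two passes; the second pass restarts from the
   original image using the PSF refined by the first. This is a functional
   equivalent of the proprietary `deconvblind` routine, not a bit-level
   clone. With circular boundaries the image update conserves flux exactly
   at each iteration, and multiplicative updates keep intensities
   non-negative.
3. **Punctum detection.** Local maxima (8-neighborhood) above a threshold.
   The threshold rule is not specified anywhere authoritative, so the
   default is ROI mean + 4 SD, configurable; minimum punctum separation
   defaults to 100 nm. A punctum whose above-half-maximum connected region
   touches the ROI border is excluded ("continuous with the edge of ROIs").
   Centers are refined to the intensity-weighted centroid of that region.
4. **Half-intensity boundary.** `extract_boundary()` returns the
   iso-intensity contour at half the local peak intensity; with nested
   contours the innermost one containing the peak wins.
5. **Midline and distances.** `fit_midline()` takes the principal axis of
   the above-half-maximum pixel mass of the scaffold (Bassoon) channel.
   `measure_distances()` reports the perpendicular distance to the
   midline's supporting line (not the clipped segment: segment-end effects
   would double-count the midpoint distance), the Euclidean distance to the
   midline midpoint, and a signed distance to the boundary contour
   (negative inside). Distances are unsigned with respect to synaptic side,
   matching the cumulative-distribution convention of the source analyses.

**Width estimation.** The bar width is the full width at half maximum of
the transverse intensity profile, with half-max crossings interpolated
linearly between pixel-sized bins along the minor axis. An earlier design
(RMS extent of the binary half-max mask rescaled by `sqrt(12)`) is exact for
a continuous uniform strip but overestimates a 100-nm bar by ~15-20% at
20 nm/px because pixel-center thresholding quantizes the mask to whole
pixels; the interpolated FWHM is unbiased to ~3% and is what
`bassoon_window_halfwidth()` (bar width / 2, the ~50-nm classification
window) builds on.

**Coordinate convention.** Pixel `(i, j)` (1-based row, column) has its
center at `((j - 0.5), (i - 0.5)) * pixel_size_nm`; all nm-valued outputs
use this convention.

## EM morphometry

Annotations (membrane polyline, AZ sub-polyline as a 0-based half-open
vertex-index interval, vesicle circles, pit markers) are consumed from JSON;
the package never segments raw micrographs. Key conventions:

- **Edge distance** = minimum Euclidean distance from vesicle center to the
  AZ sub-polyline minus the radius, clamped at 0 (`edge_distance()`).
  Distances are measured against the AZ only, since all downstream metrics
  are "from the AZ membrane".
- **Docked** = edge distance at most 0.5 nm. The source definition is
  "touching" with no number; synthetic docked vesicles are exactly tangent
  while real annotations carry tracing noise, hence a small positive,
  configurable tolerance.
- **Replacement zone** = undocked vesicles with edge distance at most
  20 nm. The upper bound is closed by declared convention (whether exactly
  20 nm is "within 20 nm" is not stated at the source).
- **Distance histogram**: undocked vesicles with edge distance in [2, 50)
  nm binned into 24 half-open 2-nm bins and normalized by the total count
  in that range. Sub-2-nm undocked vesicles count toward replacement-zone
  totals but are excluded from the histogram, per the figure captions.

## Trace analysis

- **dF/F**: `(F(t) - F0)/F0`, `F0` averaged over the ~300-ms window before
  the first stimulus. "~300 ms" is resolved deterministically as
  `floor(300 / frame_interval)` frames - 40 frames at 7.5 ms.
- **Peaks and PPR**: per-stimulus peak in `(stim, stim + window]`. How
  overlapping transients at 50-ms intervals were separated is not stated at
  the source; the declared choice here is to fit a single exponential to
  the inter-pulse decay segment and subtract its extrapolation before
  measuring the second peak (configurable off). On the noiseless synthetic
  two-pulse model this recovers the planted PPR exactly. The "failure"
  criterion replacing manual quality control is a peak at or below 3x the
  baseline dF/F SD, with every omission logged with a reason. PPR omission
  follows the printed rules: outside [0, 30] omitted; at 1-s intervals
  outside [0, 5].
- **FRAP**: one-phase association `M * (1 - exp(-t/tau))` fit to
  post-bleach fractional recovery, initialized from the half-recovery time
  and the final value. The optimizer is a bounded quasi-Newton least-squares
  core (on `M` and `log tau`) rather than Gauss-Newton `nls`, because `nls`
  stalls on zero-residual (noiseless) curves that the self-consistency
  tests require to be fit to 3-4 digits. A flat curve is reported as mobile
  fraction 0 with tau flagged unidentifiable.
- **CV**: the dispersion statistic is population variance divided by mean -
  the definition printed at the source, retained verbatim even though it is
  not the conventional SD/mean (available behind `conventional = TRUE`,
  never default). Values are normalized by the mean raw CV of the
  condition, which cannot change within-condition rank order.

## Train physiology

Amplitudes are normalized to the first response; the RRP ("nq", in units of
the first response) is the pulse-index-0 intercept of an ordinary
least-squares fit of cumulative normalized amplitude on pulse index over
the final 20 of 100 pulses. The regression domain (pulse index) and the
20-point tail are declared defaults - the source does not state which
points define the linear phase - with an R^2 >= 0.95 linearity warning.
The intercept is defined before the first pulse: that is the standard
back-extrapolation convention and the only choice making "pure steady
state gives intercept 0" exact. Recovery amplitudes are normalized to the
baseline first-pulse amplitude, with an optional single-exponential refill
fit.

## Synthetic data: the stated world

Each generator is a pure function of `(config, seed)` and attaches a truth
record carrying every quantity any analysis stage estimates.

- **STED scenes**: a 100-nm-wide scaffold bar (the reported mean Bassoon
  width) with an opposing postsynaptic bar, puncta at controlled signed
  midline offsets, isotropic Gaussian PSF of known FWHM (replacing the
  measured-PSF step so ground truth is exact), Poisson photon noise
  (`photon_scale = Inf` disables noise). Bars are rasterized with
  area-weighted pixel coverage so the rendered width is exact rather than
  quantized to whole pixels.
- **EM cohorts**: the membrane is a gently curved arc (radius 1.5 um)
  bulging into the terminal, sampled every 5 nm, with a 600-nm AZ
  sub-segment. Anchoring each vesicle on the outward radial ray of a
  membrane vertex makes its minimum distance to the polyline exactly
  radius + planted edge distance, so planted counts are recovered exactly.
  Docked/replacement vesicles are assigned randomized non-overlapping
  lateral slots along the AZ (plain rejection sampling jams well below
  capacity; slotting errors only when the drawn count truly exceeds AZ
  capacity, reported as infeasible packing). Reserve vesicles are placed by
  rejection sampling (1,000-retry cap) anywhere along the membrane.
  Distance laws default to uniform: replacement on (0.5, 20] nm - the lower
  bound clears the docking tolerance so planted docked/replacement labels
  are unambiguous - and reserve on (20, 120] nm. These laws are simple
  testable defaults, not claims about real synapses, whose empirical
  distance distributions are only published as histograms. Default means
  (docked 1.5, replacement 1.8 per profile) are in the range reported for
  hippocampal synaptic profiles while keeping the per-profile count below
  AZ slot capacity with overwhelming probability.
- **Traces**: 7.5-ms frames, 400 frames; instantaneous-rise exponential-
  decay transients whose peaks land on the first frame strictly after the
  stimulus, so noiseless analysis recovers amplitudes exactly; additive
  Gaussian noise.
- **FRAP**: 0.6-s frames, 100 frames, bleach after frame 3, recovery
  following the one-phase association in fractional-recovery units.
- **Trains**: depletion-replenishment model
  (`amp_i = p * pool_i`, `pool_{i+1} = pool_i (1 - p) + r`,
  `pool_1 = RRP`), 100 pulses at 20 Hz, multiplicative amplitude noise,
  single-exponential pool refill for recovery stimuli at 100-2,900 ms. The
  planted refill time constant (`recovery_tau_ms`, default 800 ms) is an
  addition to the configured fields: the recovery analysis needs a planted
  tau and none is specified upstream.
- **Axon profiles**: baseline plus Gaussian condensate bumps; the
  "dispersed" variant spreads each bump's integrated intensity uniformly,
  conserving the total - emulating aliphatic-alcohol dispersion.

What a green test does *not* establish: the generators do not emulate
photorealistic micrographs, 3-D structure, drift, bleaching, detector gain
variation, or biological variability between cultures; truth-recovery
results certify the estimators on the stated model, not performance on real
data.

## Statistics

`compare_groups()` provides two-sided Student's t, Mann-Whitney U and
Kruskal-Wallis with Dunn's post hoc (standard z approximation with rank-tie
correction, Bonferroni-adjusted over the prespecified pairs only, matching
the captions' restricted comparisons). The choice of test per metric is
explicit configuration, not inferred. SEM with n = 1 is reported as 0 and
flagged via the `n` column.

## Numerical and I/O choices

- No TIFF reader exists in the supported R stack, so images travel as one
  CSV matrix per channel plus a JSON metadata sidecar (pixel size, channel
  names); annotations and truth records are JSON; traces and trains CSV.
- All randomness flows from a single integer seed; per-stage child seeds
  stay below 2^31.
- The pipeline writes a manifest (config md5, seed, package version, per-
  file md5 digests); identical config + seed reproduces identical digests.

## Known limitations

- The blind deconvolution is a generic Richardson-Lucy scheme; outputs will
  differ in detail from any specific vendor implementation.
- Rolling-ball background subtraction is O(n r^2) and intended for the
  small radii used here (7 and 50 px), not for large-kernel batch work.
- `vz_cli()` provides single-process runs only; no workflow-engine
  integration or parallel guarantees.
- The 2 x SEM coverage acceptance check is intrinsically borderline (its
  nominal per-repeat probability is ~95.3% against a >= 95/100 criterion);
  it is evaluated at fixed a-priori seeds.
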