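---
title: "Measuring kinetochore DNA content with in-field phage standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring kinetochore DNA content with in-field phage standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinequant)
```

## The measurement problem

A vertebrate kinetochore assembles on a small stretch of centromeric
chromatin, but how much DNA that stretch contains is hard to read off an
image: fluorescence intensity is only proportional to DNA amount, with an
unknown, session-dependent constant. The solution implemented here is an
*internal standard*: bacteriophage particles of exactly known genome size
— λ (48 kb), P1 (90 kb) and T4 (168 kb) — are DAPI-stained and imaged in
the same field of view as the cells, so the proportionality constant can
be fitted per session and cancelled. Kinetochores are made measurable in
the first place by depleting condensin (SMC2), which lets them stretch
away from the bright chromosome mass ("excursions"); the GFP-tagged
kinetochore protein (CENP-A or CENP-H) then defines the region whose DAPI
content is converted to kilobases.

The chain is: detect and measure phage spots → fit the standard line →
segment each kinetochore's GFP envelope → measure its DAPI net intensity
→ invert the line. Every step is an explicit, tested operation.

## Intensity model and calibration

For an object carrying $m$ kb of DNA the expected integrated DAPI signal
is $I = \beta_1 m + \beta_0 + \varepsilon$. `fit_standard_curve()` fits
this by ordinary least squares with net intensity as the response,
matching the orientation in which such standard curves are plotted and
used; unknowns are then converted by **inverse prediction**,
$\hat m = (I - \beta_0)/\beta_1$, rather than by regressing kb on
intensity (the two are not equivalent under noise). The intercept is
estimated, not forced through the origin: shifted-ROI background
subtraction can leave a small common offset, and the data are allowed to
say so.

The 95% interval on $\hat m$ treats the unknown as a *single new
observation*: the delta method propagates the residual variance plus the
parameter covariance through the inverse transform, with a $t_{n-2}$
quantile. A Fieller interval is available (`interval = "fieller"`) for
weak or noisy calibrations, where the delta interval becomes optimistic;
with the bright standards simulated here the two agree to within a few
percent of the interval width, and Monte-Carlo calibration (1,000
replicate curves in the validation suite) puts empirical coverage at
~95–96%. Calibrations are keyed by imaging session: a fit carries its
session id, and the pipeline applies each field's own curve to that
field's kinetochores only.

## The measurement protocol, codified

`sum_intensity()` and `background_intensity()` transcribe the manual
Image-Pro protocol: sum the ROI, then translate *the same ROI* 5–10 px
away and call its sum the background. Because a hand operator chooses
where to put the background ROI and the protocol does not, the translated
ROI is evaluated in the 8 compass directions and the candidate
overlapping the fewest forbidden pixels (other detections, the chromatin
mass) wins; ties go to the lowest sum, then to a fixed direction order,
so the choice is deterministic. Negative nets are flagged, never clamped
— clamping would bias cohort statistics upward.

Two numerical choices deserve justification:

* **Default shift of 10 px** (the top of the protocol's 5–10 range).
  A detection ROI around a phage spot has radius ≈ 5–6 px; translated
  8 px, it still sits in the spot's own Gaussian tail and inherits ~4% of
  the spot's light as "background", biasing the calibration slope low.
  At 10 px the contamination drops to ~0.1%.
* **Detection threshold floor.** Spot detection thresholds at background
  median + 5·MAD, which degenerates to zero on noise-free synthetic
  planes; a floor of 2% of the background-corrected plane maximum keeps
  the component compact in that limit. Both constants are exposed as
  `detect_spots()` arguments.

### Projection policy

Kinetochores are measured on a **sum projection** of the planes holding
their signal, as in the original protocol; spot standards are, by
default, also measured on the sum projection rather than on their single
best-focus plane. The reason is flux consistency: with a finite-width PSF
(σ_z = 300 nm against a 200 nm step), a single plane captures only
~25% of a point source's light, and that fraction varies with the
object's sub-plane z-position — while the projected kinetochore
measurement captures essentially all of it. A calibration built from
single-plane nets therefore would not transfer to projected unknowns.
`measure_standards(measure_on = "focus-plane")` retains the literal
single-plane protocol, and `select_focus_plane()` is always recorded per
spot (ties break to the lower plane index).

### Envelope segmentation and the completeness correction

`segment_envelope()` crops a 31 × 31 px window (full z) around the seed,
thresholds the local GFP sum projection at 50% of the
background-corrected peak (half-max), keeps the connected component under
the seed, dilates by 1 px, and takes as z-range the contiguous planes
where the component's GFP exceeds the plane-wise local background.
Half-max is reproducible and robust, but for a Gaussian blob it captures
only ~64% of the light, and the blob's own tail contaminates a background
ROI translated merely 10 px away by a further ~8%. Both losses are pure
geometry, identical for the DAPI and GFP signals of the same kinetochore
— so `measure_kinetochore()` measures the *GFP* channel with exactly the
same envelope, z-range and background shift, divides by the local GFP
total (window photometry with a far ring for background), and uses that
fraction as the envelope **completeness factor** for the DAPI net. In the
noiseless limit the correction is exact; with shot noise it contributes
~1–2% to the error budget. `completeness = FALSE` reverts to the raw
protocol, which under these geometry defaults underestimates DNA content
by ~40% — the comparison is itself a test case.

## What the simulator emulates — and what it does not

`simulate_field()` produces the study's acquisition geometry:
1,024 × 1,024 px planes, 200 nm z-steps, 65 nm xy pixels (the
conventional value for this camera/objective class; the pixel pitch is
not stated in the protocol), two channels, 16-bit range with unit gain.
Objects are separable anisotropic Gaussians integrated over voxels, so
photon bookkeeping is exact by construction: a manifest records each
object's expected integrated DAPI ( `brightness_per_kb × true_kb ×
at_bias` ) and GFP photons before noise. Noise is Poisson on signal plus
background, then Gaussian read noise, then clipping and integer
quantisation.

Key defaults, all overridable in `sim_config()`:

| parameter | default | why |
|---|---|---|
| `psf_sigma` | 300/100 nm (z/xy) | compact as-if-deconvolved PSF; the study's stacks were deconvolved upstream |
| `kinetochore_sigma` | 300/250 nm | a stretched kinetochore blob, wider than the PSF |
| `brightness_per_kb` | 100 photons/kb | puts λ…T4 at 4,800–16,800 photons, shot-noise-limited at SNR ≫ 10 |
| `gfp_brightness` | 5 × 10⁴ photons | bright marker so envelope/completeness noise stays ~1% |
| `background_dapi` / `background_gfp` | 5 / 2 photons/voxel | realistic haze levels |
| `kinetochore_kb_range` | 28–147 kb | the observed spread of stretched-kinetochore DNA content |
| `at_bias` | 1.0 per class | DAPI's AT-rich preference, off by default |

The simulator deliberately does **not** model deconvolution itself,
vectorial PSFs, spectral bleed-through, photobleaching, or non-Gaussian
kinetochore shapes. Passing recovery tests on these fields therefore
demonstrates that the *measurement chain* is unbiased and correctly
calibrated under the stated optical model; it cannot certify real-data
effects such as deconvolution artefacts, chromatin adjacent to the
envelope, or dye-binding heterogeneity. The AT-bias knob makes one such
effect explicit: setting the kinetochore class factor to 0.8 (AT-poor
DNA relative to the phage standards) propagates to estimates biased low
by 20%, quantifying — not correcting — the caveat that a single
DNA-binding dye can only ever yield an estimate.

The optional chromatin mass is off by default: a Gaussian mass bright
enough to emulate the metaphase plate leaves, at realistic separations, a
shoulder under the kinetochore envelope that dwarfs the kinetochore's own
DAPI signal. It exists as an explicit option for demonstrating the
direction-aware background placement ("moved away from the metaphase
plate"), with the forbidden-mask machinery steering the background ROI.

## Validation problem sizes

The test-suite recovers ground truth at the following scales, chosen to
exercise the full acquisition geometry while keeping a complete run on
one CPU in a few minutes: noiseless end-to-end on one 21 × 1,024 × 1,024
field (9 standards + 5 kinetochores; every estimate within 2% of truth,
limited by rendering/aperture truncation); stochastic recovery over four
such fields (40 kinetochores with true kb uniform on 28–147; mean
absolute error ≈ 3.5%, standard-class assignment 100%); detection
recall/false positives over twenty 256-px fields; and 1,000-replicate
interval-coverage and 100-instance closed-form-OLS checks. Smaller 13- to
21-plane, 96- to 512-px fields back the unit tests of individual
operations. `scripts/acceptance.R` re-runs the headline computations from
scratch and writes their numbers as JSON.

## Known limitations

* The envelope is 2-D (on a sum projection), matching the measured
  quantity in the original protocol even though the underlying object is
  a volume; the z-range selection is the only 3-D element.
* The completeness correction assumes DAPI and GFP share one spatial
  profile per kinetochore; a kinetochore whose chromatin trails outside
  its protein envelope violates this, and the resulting spread is a
  biological signal the method cannot separate from measurement error.
* Phage aggregates and overlapping spots are handled only by area bounds
  and the cluster-ratio QC (means must match 48:90:168 within ±25%), not
  by deblending.
* Estimates inherit DAPI's sequence preference; the `at_bias` experiment
  bounds the effect but nothing in the pipeline corrects it.
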