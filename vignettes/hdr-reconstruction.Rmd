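---
title: "HDR reconstruction for laser scanning microscopy: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HDR reconstruction for laser scanning microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdrlsm)
```

## The problem

A photomultiplier tube (PMT) behind a laser scanning microscope delivers a
usable signal band of about three decades: below the dark-noise floor a
pixel's counts are indistinguishable from background, above the ADC's
clipping level they carry no information at all. Biological scenes —
heterogeneously expressing neurons, bead calibration mixtures spanning
0.3–100 % relative brightness, a dye bolus washing through vasculature —
exceed that band routinely. `hdrlsm` implements and validates the
multi-sensitivity remedy: several detectors view the same fluorescence
through different attenuations (neutral-density filters of optical density
0, 0.9 and 1.8, or a 90/10 beam-splitting pair), so that every scene
radiance falls inside at least one detector's usable band, and the
linearized channels are fused into one composite radiance map.

Because no public datasets exist for this acquisition geometry, the package
treats the *simulated microscope* as a first-class component: generators
produce ground-truth scenes with the statistical structure of the real
samples, the acquisition module reproduces the detection physics, and every
downstream claim is scored against the generator's truth.

## Detection model and its assumptions

For channel $i$ with optical density $od_i$, exposure/splitting fraction
$e_i$, gain $g_i$ (counts per detected photon), dark level
$(\mu_i, \sigma_i)$ and bit depth $b$:

$$\text{counts}_i = \mathrm{clip}\!\left(\mathrm{round}\left(
  g_i\,\mathrm{Pois}(\varphi\, e_i 10^{-od_i}) +
  \mathcal{N}(\mu_i, \sigma_i^2)\right),\, 0,\, 2^b - 1\right)$$

Assumptions, stated once:

* **Affine-linear response.** PMT analogue detection is linear below
  saturation; gain nonlinearity, afterpulsing and scan-timing artifacts are
  out of scope. The response-correction step therefore inverts an affine
  map, $x_i = (\text{counts}_i - \mu_i)/\alpha_i$ with
  $\alpha_i = e_i g_i 10^{-od_i}$.
* **Shared shot noise in simultaneous mode.** Beam splitting distributes
  the *same* photons across detectors, modelled as multinomial thinning of
  one Poisson draw; dark noise stays independent per channel. Sequential
  mode re-draws photons per exposure and supports rigid scene motion
  between exposures (the source of ghosting).
* **Monotone coupling.** Poisson draws go through the inverse CDF of a
  shared uniform stream, so for a fixed seed larger radiance never yields
  smaller counts — a property the tests exercise directly.
* **Rounding** is half-away-from-zero, a single stated convention.

Default channel parameters (gain 1, offset 100 counts, dark σ 10 counts,
12 bits) put a single channel's usable band at
$(0.98 \cdot 4095 - 100)/(3\sigma) \approx 130$:1 — about seven effective
bits, matching the "three decades, less after noise" regime the method is
designed around.

## Calibration

With declared filters (`calibration_from_config`) the sensitivities are
computed, not fitted: $\alpha_i = e_i g_i 10^{-od_i}$, normalized so the
reference channel has $\alpha = 1$; the raw reference sensitivity is kept
for truth-referred comparisons. With unknown filters (`estimate_alphas`)
each adjacent channel pair is fitted through the origin over pixels jointly
inside both usable bands. One deliberate deviation from the obvious
formulation: the fit regresses the *attenuated* channel on the brighter one
and inverts the slope. Regressing bright-on-dim puts the noisier variable
on the regressor side and attenuates the slope (the classical
errors-in-variables bias, ~1 % at realistic SNR — enough to miss the 1 %
recovery requirement the module sets itself); the inverted orientation
reduces that bias by two orders of magnitude. A single 3σ residual
rejection pass follows; estimation is deterministic and bounded.

## Fusion

Each channel is masked to its usable band — saturated at
$\ge 0.98\,(2^b{-}1)$ (not 1.0, to exclude near-clip nonlinearity), below
noise at $\le \mu + 3\sigma$ (the mean-noise ± 3σ convention used
throughout the package) — and the fused radiance is the weighted mean of
the valid linearized channels. Inverse-variance weights
$w_i = \alpha_i^2 / (g_i(\text{counts}_i-\mu_i)_+ + \sigma_i^2)$ are the
default (optimal for independent Gaussian-approximated channels); binary
weights are provided as the simpler reference mode. Known simplification:
in simultaneous mode the channels share shot noise and the weights ignore
that correlation; the correlation is negative (multinomial splitting), so
the fused variance is, if anything, slightly better than the independence
approximation predicts.

Pixels valid in no channel are resolved deterministically: saturated
everywhere → the best channel's saturation-equivalent radiance (a declared
floor — never NaN, so segmentation and display never see non-finite
values) with `all_saturated_mask` set; below noise everywhere → 0 with
`all_noise_mask` set. A third, mixed case is geometrically possible
(saturated in the sensitive channels, below noise in the attenuated ones)
when attenuation steps exceed a channel's band; with the default 0.9-OD
spacing the bands overlap and the case does not arise, but it is handled —
unweighted mean of all channels — rather than asserted away.

Sequential stacks can be registered to a reference channel by integer-pixel
phase correlation on offset-subtracted, noise-floor-zeroed data. Ties on a
flat correlation plateau resolve to the smallest-magnitude shift, rows
before columns; a peak below the confidence floor leaves the image
unshifted with a warning. Border pixels vacated by the corrective shift are
filled with the channel's dark level, which the fusion masks then treat as
missing data in that channel.

## Display remapping

The composite HDR image is linear radiance and is what all quantitative
operators consume. For display, `remap_global` applies
$y = \log(1 + \mu x')/\log(1 + \mu)$ on max-normalized radiance
(default $\mu = 1000$; log compression is the standard choice for
multi-decade microscopy data) or a gamma map, both strictly monotone;
`equalize_local` adds contrast-limited adaptive histogram equalization
(tile grid floored at 2×2 — the algorithm requires at least four contextual
regions). Negative fused values (noise about zero, preserved for unbiased
averaging) are clipped to zero *only* at this display stage. An optional
overlay paints all-saturated pixels red and all-noise pixels blue, the
conventional out-of-range coding.

## What the generators emulate — and what they do not

* `make_phantom`: non-adjacent uniform regions at stated relative
  concentrations (the 1:1 / 1:10 / 1:100 dilution series) over a
  zero-radiance background that doubles as the dark-noise reference. The
  exact layout of the physical phantom is not specified anywhere; a regular
  grid of discs is used, which fixes region geometry identically across
  levels so truth ratios are exact by construction.
* `make_beads`: hard discs with a 1-px cosine anti-aliased rim, uniform
  intra-population intensity (bead kits are highly homogeneous within a
  population), non-overlapping placement with a bounded retry budget.
* `make_neuron_scene`: bright hard-edged discs (somata) joined by dim
  quadratic-Bezier tubes (processes). Soma intensity may be a log-uniform
  range, emulating heterogeneous expression — the condition under which a
  single exposure must choose between losing dim cells and saturating
  bright ones.
* `make_kinetic_series`: piecewise-exponential bolus,
  $c_v(\tau) = A(1-e^{-k_{in}\tau})e^{-k_{out}\tau}$, with the tissue
  compartment integrating vascular signal at the extravasation rate in
  closed form (a 2 MDa probe is the $k_{ex}=0$ limit). Default rates
  (arrival 2 s, wash-in 1.5 s⁻¹, wash-out 0.05 s⁻¹, 0.5 s frames) give the
  fast-rise/slow-decay shape of an intravenous bolus at a 2 Hz frame rate.

Not modelled, by design: optical PSF and diffraction, tissue scattering,
photobleaching, elastic motion. Consequently, passing tests demonstrate the
*reconstruction's* correctness — linearity, range extension, SNR
dominance, registration, segmentation contrast — on scenes whose spatial
statistics resemble the real samples; they do not certify performance under
optical blur or non-rigid motion.

## Segmentation operators

The package ships the deterministic quantification pipelines used to show
that HDR improves downstream analysis:

* **Mitochondria-style**: rolling-ball background subtraction (grayscale
  opening with a disc element — the standard flat-element approximation),
  the zero-sum 5×5 sharpening kernel (centre 24, remainder −1), an
  FFT-based band-pass implemented as a difference of Gaussians passing
  structures of 3–40 px (an ImageJ-style convention; the cut-offs are
  recorded in the result), Kapur maximum-entropy thresholding (ties to the
  lowest bin), size filtering.
* **Cell bodies**: threshold at background mean + 3σ, per-slice binary
  erosion (laser-scanning z-sampling is anisotropic, so in-plane erosion is
  the appropriate default), exact 3-D Euclidean distance transform
  (separable lower-envelope algorithm, compiled), marker-based watershed
  flooding from distance-transform maxima (plateaus collapse to one marker;
  maxima closer than the minimum separation merge greedily, highest first),
  26-connected components, size filter. A trainable-classifier stage used
  in some published pipelines is deliberately replaced by this
  deterministic baseline: the claim under test is the *rendering's* effect
  on segmentation, which a fixed segmenter exposes without training
  variance.
* **Filaments**: Zhang–Suen thinning, branch points as skeleton pixels with
  ≥ 3 skeleton neighbours (8-connectivity), length as unit/√2 step sums.
  3-D input is maximum-projected first; volumetric skeletonization is out
  of scope, and the commercial filament tracer whose outputs motivated this
  statistic is proprietary and not replicated.

Detection scoring matches predicted to true centroids greedily,
closest-first, one-to-one, ties broken by (row, col). Cell detection has no
true negatives, so "specificity" is reported as precision and documented as
such; accuracy is tp/(tp+fp+fn).

## Numerical choices and degenerate inputs

* Coordinates are (row, col), 1-based, pixel centers at integers — R's
  native convention, applied everywhere including centroids and shifts.
* Truth radiance is arbitrary-linear with the brightest nominal object at
  1.0 (`peak` rescales); all contrasts are ratios.
* A constant image is an error for thresholding (no threshold exists), a
  no-op for equalization, and subtracts to zero under rolling-ball.
* Empty foreground in counting/filament operators returns zero counts, not
  errors.
* All-saturated fusion output is a finite declared floor; masks carry the
  truth.
* Generators, fusion, registration and segmentation are pure functions of
  their inputs and seeds; the test suite asserts bit-identical re-runs.

## Problem sizes

The validation experiments run at deliberately modest sizes — 192–320 px
scenes, 8–16 px uniform patches with 200 Monte-Carlo repeats, 10-seed
paired comparisons — chosen so the full suite completes in about a minute
while keeping every Monte-Carlo tolerance at 3 standard errors or better.
Scaling the same experiments up changes only precision, not structure.

## Known limitations

* Inverse-variance weights treat simultaneous channels as independent
  (second-order effect, see above).
* Registration is integer-pixel and rigid; subpixel or elastic motion
  leaves residual ghosting.
* The rolling-ball background uses a flat disc element rather than a
  spherical height profile.
* Per-slice erosion in the cell-body pipeline assumes z-anisotropic
  volumes; isotropic data would warrant a spherical element.
* The exact response-correction and fusion weighting of the original
  instrument are not published in accessible form; the affine model and
  inverse-variance weighting are this package's declared, tested choices,
  with binary weighting available for comparison.
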