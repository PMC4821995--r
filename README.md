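# hdrlsm — high dynamic range reconstruction for laser scanning microscopy

The photomultiplier tubes behind confocal and two-photon microscopes span
roughly three decades of signal. Biological scenes routinely span more: a
field of view with bright somata and dim processes, beads of 0.3 % and 100 %
relative brightness, or a dye bolus surging through a vessel will either
saturate the detector or drown in its dark noise within any single exposure.
`hdrlsm` implements the multi-detector remedy: acquire several low dynamic
range (LDR) images of one scene at different sensitivities — neutral-density
filters of optical density 0, 0.9 and 1.8 (or asymmetric 90/10 beam
splitting), simultaneously through beam splitters or sequentially —
linearize each channel with its response calibration, and fuse the usable
bands into one composite high dynamic range (HDR) radiance map.

The package is aimed at microscopists and image-analysis developers who want
to prototype, validate or teach HDR-LSM reconstruction without microscope
hardware: every stage of the real pipeline has a faithful simulated
counterpart, and every claim about the reconstruction can be scored against
ground truth.

## The model

Each detector channel *i* maps scene radiance φ to counts

```
counts_i = clip( round( gain_i · Pois(φ · e_i · 10^-od_i) + N(offset_i, σ_i²) ), 0, 2^bits - 1 )
```

so its sensitivity is `α_i = e_i · gain_i · 10^-od_i` (exposure/splitting
fraction × counts-per-photon × filter transmission). Only counts between the
noise floor `offset + k·σ` (k = 3 by default) and the saturation guard
`0.98 · (2^bits - 1)` quantize signal. Fusion linearizes each channel,
`x_i = (counts_i - offset_i)/α_i`, masks each channel to its usable band,
and per pixel forms the inverse-variance weighted mean

```
φ̂ = Σ w_i x_i / Σ w_i,    w_i = α_i² / (gain_i·(counts_i - offset_i)_+ + σ_i²)
```

which extends the estimable range by the largest attenuation factor
(63.1× for OD 1.8) and never falls below the best single channel's SNR.
For display, the linear HDR map is log- or gamma-compressed to 8 bits
(`remap_global`) with optional contrast-limited adaptive histogram
equalization (`equalize_local`); quantitative work stays on the linear map.

Downstream quantification operators used to benchmark HDR against single
exposures are included: rolling-ball background subtraction, the zero-sum
5×5 sharpening kernel (centre 24) with FFT band-pass, Kapur maximum-entropy
thresholding, watershed-based 3-D cell-body counting, skeleton filament
statistics, SNR/dynamic-range metrics, ROI time–intensity kinetics and
centroid detection scoring.

## Worked example

Simulate the three-population bead mixture (0.3 / 3 / 100 % relative
intensity), image it through the OD 0/0.9/1.8 bracket, fuse, and read back
the population means:

```r
library(hdrlsm)

beads    <- make_beads(c(0.3, 3, 100), n_per_pop = 20, seed = 7, peak = 1e5)
channels <- default_channels(c(0, 0.9, 1.8))
stack    <- acquire_stack(beads, channels, mode = "simultaneous", seed = 11)
calib    <- calibration_from_config(channels)
hdr      <- fuse(stack, calib, weighting = "inverse_variance")
hdr
#> hdr_image: 256 x 256 px, radiance [0, 109345], inverse_variance weights; 0.00% all-saturated, 87.85% all-noise

sapply(1:3, function(p) {
  ids <- beads$centroids$id[beads$centroids$pop == p]
  mean(hdr$radiance[beads$labels %in% ids])
})
#> [1]   255.8364  2557.9144 85082.9965
```

The population means sit in the ratio 0.301 : 3.01 : 100 — the dimmest
population, invisible in the unattenuated channel's noise and 300× below
the brightest, is recovered to within a percent of its true 0.3 % relative
intensity. (Absolute means are below `level × peak` because each bead's
mask includes its anti-aliased rim.) `remap_global(hdr, "log")` then yields
the 8-bit display image in which all three populations are visible at once.

A ready-made pipeline runner consumes a YAML config
(`run_pipeline("run.yaml")`), writing the LDR stack, calibration, HDR float
TIFF, masks, display image, region metrics CSV and a stage-timing log; a
thin CLI wrapper is installed at `inst/cli/hdrlsm`.

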