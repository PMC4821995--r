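#' Detector channel configuration
#'
#' Physics of one PMT detection channel. The channel's relative sensitivity
#' is `alpha = exposure * gain * 10^-od`: a neutral-density filter of optical
#' density `od` transmits a fraction `10^-od` of the fluorescence, the PMT
#' plus digitizer convert each detected photon into `gain` counts on top of a
#' dark level of mean `offset` and standard deviation `dark_sigma`, and the
#' ADC clips at `2^bit_depth - 1`. Defaults place a single 12-bit channel's
#' usable band at roughly three decades, the typical PMT dynamic range.
#'
#' @param od optical density of the attenuation filter (0 = none).
#' @param gain counts per detected photon (> 0).
#' @param offset dark-level mean in counts, in `[0, sat_level)`.
#' @param dark_sigma dark-noise standard deviation in counts (>= 0).
#' @param bit_depth ADC bit depth (>= 8); saturation at `2^bit_depth - 1`.
#' @param exposure relative dwell/illumination (or beam-splitting fraction)
#'   scale (> 0). A 90/10 beamsplitter pair is `exposure = 0.9` and `0.1`
#'   with `od = 0`.
#' @return an object of class `channel_config`.
#' @export
channel_config <- function(od = 0, gain = 1, offset = 100, dark_sigma = 10,
                           bit_depth = 12, exposure = 1) {
  stopifnot_scalar(od, "od"); stopifnot_scalar(gain, "gain", positive = TRUE)
  stopifnot_scalar(exposure, "exposure", positive = TRUE)
  if (od < 0) stop("'od' must be >= 0 (attenuation factor in (0, 1])")
  if (dark_sigma < 0) stop("'dark_sigma' must be >= 0")
  if (bit_depth < 8 || bit_depth != round(bit_depth))
    stop("'bit_depth' must be an integer >= 8")
  sat_level <- 2^bit_depth - 1
  if (offset < 0 || offset >= sat_level)
    stop("'offset' must lie in [0, sat_level)")
  structure(list(od = od, gain = gain, offset = offset,
                 dark_sigma = dark_sigma, bit_depth = bit_depth,
                 sat_level = sat_level, exposure = exposure),
            class = "channel_config")
}

# raw sensitivity (counts per unit radiance)
alpha_raw <- function(config) config$exposure * config$gain * 10^(-config$od)

#' @export
print.channel_config <- function(x, ...) {
  cat(sprintf(
    "channel_config: OD %.2f, gain %g, offset %g, dark sd %g, %d-bit (sat %d), exposure %g\n",
    x$od, x$gain, x$offset, x$dark_sigma, x$bit_depth, x$sat_level, x$exposure))
  invisible(x)
}

#' Default three-channel attenuation bracket
#'
#' The standard simultaneous configuration: three channels behind
#' neutral-density filters of optical density 0, 0.9 and 1.8.
#'
#' @param ods optical densities, one per channel.
#' @param ... passed to [channel_config] for every channel.
#' @return list of `channel_config`.
#' @export
default_channels <- function(ods = c(0, 0.9, 1.8), ...)
  lapply(ods, function(o) channel_config(od = o, ...))

new_ldr_image <- function(data, config, channel_index = 1L, acquired_at = 0) {
  structure(list(data = data, config = config,
                 channel_index = as.integer(channel_index),
                 acquired_at = acquired_at),
            class = "ldr_image")
}

#' @export
print.ldr_image <- function(x, ...) {
  cat(sprintf("ldr_image: channel %d, %s px, counts [%d, %d] of %d\n",
              x$channel_index, paste(dim(x$data), collapse = " x "),
              min(x$data), max(x$data), x$config$sat_level))
  invisible(x)
}

#' @export
print.ldr_stack <- function(x, ...) {
  cat(sprintf("ldr_stack: %d channel(s), %s px, %s mode\n",
              length(x$images), paste(dim(x$images[[1]]$data), collapse = " x "),
              x$mode))
  invisible(x)
}

# single-channel detection given a photon-rate map lambda (photons/pixel);
# returns integer counts. Poisson draws go through the inverse CDF so that,
# for a fixed seed, counts are monotone in radiance (coupled uniforms).
detect_counts <- function(lambda, config, photons = NULL) {
  n <- length(lambda)
  if (is.null(photons)) photons <- stats::qpois(runif(n), lambda)
  counts <- round_half_away(config$gain * photons +
                              rnorm(n, config$offset, config$dark_sigma))
  counts <- pmin(pmax(counts, 0), config$sat_level)
  matrix(as.integer(counts), nrow(lambda), ncol(lambda))
}

#' Acquire one LDR image of a scene
#'
#' Simulates the detection chain: expected photon count per pixel is
#' `radiance * exposure * 10^-od`, photon arrivals are Poisson, each photon
#' yields `gain` counts, Gaussian dark noise (mean `offset`, sd `dark_sigma`)
#' is added, and the result is rounded (half away from zero) and clipped to
#' `[0, sat_level]`. Dark noise limits detection from below; clipping
#' saturates from above — only the band between them quantizes signal.
#'
#' @param scene a [scene_truth] (or nonnegative radiance matrix).
#' @param config a [channel_config].
#' @param seed integer seed (NULL to draw from the current RNG stream).
#' @param shift (dy, dx) rigid scene translation before detection
#'   (sequential-mode motion).
#' @return an `ldr_image`.
#' @export
acquire_ldr <- function(scene, config, seed = NULL, shift = c(0, 0)) {
  radiance <- if (inherits(scene, "scene_truth")) scene$radiance else scene
  if (any(!is.finite(radiance)) || any(radiance < 0))
    stop("scene radiance must be finite and >= 0 (upstream bug)")
  if (any(shift != 0)) radiance <- shift_image(radiance, shift[1], shift[2])
  lambda <- radiance * config$exposure * 10^(-config$od)
  data <- with_seed(seed, detect_counts(lambda, config))
  new_ldr_image(data, config)
}

#' Acquire a multi-channel LDR stack
#'
#' In `"simultaneous"` mode all channels view the same photon stream: one
#' Poisson realization of the total detected photons is split across channels
#' by multinomial thinning in proportion to each channel's
#' `exposure * 10^-od` (physically, beam splitting), so shot noise is shared;
#' dark noise stays independent per channel. In `"sequential"` mode each
#' channel is an independent realization, optionally with a per-image rigid
#' scene shift emulating sample motion between frames (the source of
#' ghosting).
#'
#' @param scene a [scene_truth].
#' @param configs list of [channel_config].
#' @param mode `"simultaneous"` or `"sequential"`.
#' @param seed integer seed.
#' @param motion list of (dy, dx) shifts, sequential mode only; NULL = none.
#' @return an `ldr_stack` (fields `images`, `mode`, `motion`).
#' @export
acquire_stack <- function(scene, configs, mode = c("simultaneous", "sequential"),
                          seed = NULL, motion = NULL) {
  mode <- match.arg(mode)
  if (!length(configs)) stop("need at least one channel config")
  if (inherits(configs, "channel_config")) configs <- list(configs)
  nch <- length(configs)
  if (mode == "simultaneous" && !is.null(motion) &&
      any(unlist(motion) != 0))
    stop("motion cannot be supplied in simultaneous mode (channels share one frame)")
  if (is.null(motion)) motion <- rep(list(c(0, 0)), nch)
  if (length(motion) != nch) stop("'motion' must have one (dy, dx) per channel")
  radiance <- if (inherits(scene, "scene_truth")) scene$radiance else scene
  if (any(radiance < 0)) stop("scene radiance must be >= 0")
  images <- with_seed(seed, {
    if (mode == "simultaneous") {
      s <- vapply(configs, function(cf) cf$exposure * 10^(-cf$od), 0)
      total <- rpois(length(radiance), radiance * sum(s))
      rem <- total; srem <- sum(s)
      out <- vector("list", nch)
      for (i in seq_len(nch)) {
        ni <- if (i == nch) rem else rbinom(length(rem), rem, min(1, s[i] / srem))
        rem <- rem - ni; srem <- srem - s[i]
        ph <- matrix(ni, nrow(radiance), ncol(radiance))
        out[[i]] <- new_ldr_image(
          detect_counts(ph * 0, configs[[i]], photons = ni),
          configs[[i]], channel_index = i)
      }
      out
    } else {
      lapply(seq_len(nch), function(i) {
        sc <- shift_image(radiance, motion[[i]][1], motion[[i]][2])
        lambda <- sc * configs[[i]]$exposure * 10^(-configs[[i]]$od)
        new_ldr_image(detect_counts(lambda, configs[[i]]), configs[[i]],
                      channel_index = i, acquired_at = i - 1)
      })
    }
  })
  structure(list(images = images, mode = mode, motion = motion),
            class = "ldr_stack")
}

#' Average repeated acquisitions of one channel
#'
#' Pixelwise mean of `n` frames acquired with an identical configuration —
#' the conventional SNR remedy the HDR approach is benchmarked against.
#' Averaging narrows noise by `sqrt(n)` but cannot recover clipped pixels:
#' a saturated pixel averages to the saturation level.
#'
#' @param frames list of `ldr_image` with identical configs.
#' @return float matrix of pixelwise means.
#' @export
average_frames <- function(frames) {
  if (!length(frames)) stop("need at least one frame")
  cfg <- frames[[1]]$config
  for (f in frames)
    if (!identical(unclass(f$config), unclass(cfg)))
      stop("all frames must share one channel config")
  Reduce(`+`, lapply(frames, function(f) f$data)) / length(frames)
}
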