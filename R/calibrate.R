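#' Dark-frame statistics
#'
#' Estimates each channel's dark level and dark-noise standard deviation from
#' dark frames (acquisitions with no illumination).
#'
#' @param dark_frames for one channel: an `ldr_image`, matrix, or list of
#'   them (pooled); for several channels: a list with one such entry per
#'   channel.
#' @return for one channel a named vector `c(offset, dark_sigma)`; for a
#'   per-channel list, a matrix with one row per channel.
#' @export
estimate_dark <- function(dark_frames) {
  one <- function(x) {
    if (inherits(x, "ldr_image")) x <- list(x$data)
    if (is.matrix(x) || is.numeric(x)) x <- list(x)
    x <- lapply(x, function(f) if (inherits(f, "ldr_image")) f$data else f)
    if (!length(x) || !length(x[[1]])) stop("empty dark-frame input")
    v <- unlist(x)
    c(offset = mean(v), dark_sigma = if (length(v) > 1) sd(v) else 0)
  }
  if (is.list(dark_frames) && length(dark_frames) &&
      (is.list(dark_frames[[1]]) || inherits(dark_frames[[1]], "ldr_image") ||
       is.matrix(dark_frames[[1]]))) {
    t(vapply(dark_frames, one, c(offset = 0, dark_sigma = 0)))
  } else one(dark_frames)
}

new_calibration <- function(alphas, offsets, dark_sigmas, fit_rms = 0,
                            n_pixels_used = integer(0), reference = 1L,
                            ref_sensitivity = NA_real_) {
  if (any(alphas <= 0)) stop("alphas must be > 0")
  if (alphas[reference] != 1) stop("reference channel alpha must be 1")
  structure(list(alphas = alphas, offsets = offsets,
                 dark_sigmas = dark_sigmas, fit_rms = fit_rms,
                 n_pixels_used = n_pixels_used, reference = as.integer(reference),
                 ref_sensitivity = ref_sensitivity),
            class = "hdr_calibration")
}

#' @export
print.hdr_calibration <- function(x, ...) {
  cat("hdr_calibration\n  alphas:", signif(x$alphas, 5),
      "\n  offsets:", signif(x$offsets, 5),
      "\n  dark sigmas:", signif(x$dark_sigmas, 5),
      "\n  fit rms:", signif(x$fit_rms, 4), "\n")
  invisible(x)
}

#' Calibration from declared channel parameters (known-OD mode)
#'
#' When the attenuation filters and gains are trusted by construction, the
#' relative sensitivities need no fitting:
#' `alpha_i = exposure_i * gain_i * 10^-od_i`, normalized so the reference
#' channel has alpha exactly 1. The raw reference sensitivity (counts per
#' unit radiance) is kept so estimates can be converted to scene units.
#'
#' @param configs list of [channel_config] (or an `ldr_stack`).
#' @param reference index of the reference channel.
#' @return an `hdr_calibration`.
#' @export
calibration_from_config <- function(configs, reference = 1L) {
  if (inherits(configs, "ldr_stack"))
    configs <- lapply(configs$images, `[[`, "config")
  a_raw <- vapply(configs, alpha_raw, 0)
  new_calibration(alphas = a_raw / a_raw[reference],
                  offsets = vapply(configs, `[[`, 0, "offset"),
                  dark_sigmas = vapply(configs, `[[`, 0, "dark_sigma"),
                  fit_rms = 0,
                  n_pixels_used = integer(length(configs)),
                  reference = reference,
                  ref_sensitivity = a_raw[reference])
}

#' Estimate relative channel sensitivities from an acquired stack
#'
#' For each adjacent channel pair (ordered as given), the through-origin
#' slope between offset-subtracted counts is fitted over pixels jointly
#' inside both usable bands (below `sat_frac * sat_level`, above
#' `offset + noise_k * dark_sigma`). The fit uses the less-attenuated
#' (higher-SNR) channel as the regressor and inverts the slope, so shot
#' noise in the attenuated channel does not attenuate the estimate
#' (errors-in-variables). One pass of 3-sigma residual rejection follows
#' the initial fit. Pairwise slopes are chained to the reference channel.
#'
#' @param stack an `ldr_stack` with >= 2 channels.
#' @param offsets per-channel dark means; NULL uses the configs' values.
#' @param dark_sigmas per-channel dark sds; NULL uses the configs' values.
#' @param sat_frac saturation guard fraction of `sat_level` (default 0.98).
#' @param noise_k noise-floor multiple of `dark_sigma` (default 3).
#' @param reference index of the reference channel (alpha = 1).
#' @return an `hdr_calibration` with `fit_rms` (pooled relative residual
#'   rms) and `n_pixels_used` per adjacent pair.
#' @export
estimate_alphas <- function(stack, offsets = NULL, dark_sigmas = NULL,
                            sat_frac = 0.98, noise_k = 3, reference = 1L) {
  imgs <- stack$images
  nch <- length(imgs)
  if (nch < 2) stop("need >= 2 channels to estimate relative sensitivities")
  cfgs <- lapply(imgs, `[[`, "config")
  if (is.null(offsets)) offsets <- vapply(cfgs, `[[`, 0, "offset")
  if (is.null(dark_sigmas)) dark_sigmas <- vapply(cfgs, `[[`, 0, "dark_sigma")
  valid <- lapply(seq_len(nch), function(i) {
    d <- imgs[[i]]$data
    d < sat_frac * cfgs[[i]]$sat_level &
      d > offsets[i] + noise_k * dark_sigmas[i]
  })
  # pairwise slope of channel i (y) on channel i+1 (x): estimates alpha_i/alpha_{i+1}
  slopes <- numeric(nch - 1)
  n_used <- integer(nch - 1)
  res_ss <- 0; res_n <- 0
  for (i in seq_len(nch - 1)) {
    j <- i + 1L
    joint <- valid[[i]] & valid[[j]]
    if (sum(joint) < 2)
      stop(sprintf("no jointly valid pixels for channel pair (%d, %d)", i, j))
    y <- imgs[[i]]$data[joint] - offsets[i]
    x <- imgs[[j]]$data[joint] - offsets[j]
    # through-origin fit with the brighter (higher-SNR) channel as the
    # regressor: regress x on y and invert, so the attenuated channel's
    # shot noise does not bias the slope (errors-in-variables)
    b <- sum(y * y) / sum(x * y)
    r <- y - b * x
    keep <- abs(r) <= 3 * sd(r)
    if (sum(keep) >= 2) {
      y <- y[keep]; x <- x[keep]
      b <- sum(y * y) / sum(x * y)
      r <- y - b * x
    }
    slopes[i] <- b
    n_used[i] <- length(x)
    res_ss <- res_ss + sum((r / max(mean(y), 1e-12))^2)
    res_n <- res_n + length(r)
  }
  # chain to the reference: alpha_ref = 1
  log_rel <- c(0, cumsum(-log(slopes)))  # log alpha_i relative to channel 1
  alphas <- exp(log_rel - log_rel[reference])
  new_calibration(alphas = alphas, offsets = offsets,
                  dark_sigmas = dark_sigmas,
                  fit_rms = sqrt(res_ss / max(res_n, 1)),
                  n_pixels_used = n_used, reference = reference,
                  ref_sensitivity = alpha_raw(cfgs[[reference]]))
}

#' Linearize an LDR image with a calibration
#'
#' Inverts the affine detector response: `x = (counts - offset) / alpha`,
#' giving a radiance estimate in units of the reference channel. Negative
#' values (noise about zero) are preserved so downstream averaging stays
#' unbiased; saturated pixels simply map to `(sat_level - offset) / alpha` —
#' flagging them is the fusion stage's job.
#'
#' @param ldr an `ldr_image` (or counts matrix with `channel` given).
#' @param calib an `hdr_calibration`.
#' @param channel channel index into the calibration.
#' @return float matrix of linearized radiance estimates.
#' @export
correct_response <- function(ldr, calib, channel = NULL) {
  data <- if (inherits(ldr, "ldr_image")) ldr$data else ldr
  if (is.null(channel))
    channel <- if (inherits(ldr, "ldr_image")) ldr$channel_index else 1L
  if (channel < 1 || channel > length(calib$alphas))
    stop(sprintf("channel %d not present in calibration", channel))
  (data - calib$offsets[channel]) / calib$alphas[channel]
}
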