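#' Usable-band masks for one LDR image
#'
#' Partitions an LDR image into its three detector regimes: saturated
#' (counts at or above `sat_frac * sat_level`), below the noise floor
#' (counts at or below `offset + noise_k * dark_sigma`), and the valid
#' quantization band in between. The three masks partition the image.
#'
#' @param ldr an `ldr_image`.
#' @param calib an `hdr_calibration`.
#' @param sat_frac saturation guard fraction (default 0.98; strictly 1.0
#'   would admit near-clip nonlinearity).
#' @param noise_k noise-floor multiple of the dark sd (default 3).
#' @param channel channel index into the calibration.
#' @return list of logical matrices `valid`, `saturated`, `below_noise`.
#' @export
validity_masks <- function(ldr, calib, sat_frac = 0.98, noise_k = 3,
                           channel = NULL) {
  if (sat_frac <= 0 || sat_frac > 1) stop("'sat_frac' must be in (0, 1]")
  if (noise_k < 0) stop("'noise_k' must be >= 0")
  data <- ldr$data
  if (is.null(channel)) channel <- ldr$channel_index
  saturated <- data >= sat_frac * ldr$config$sat_level
  below <- data <= calib$offsets[channel] +
    noise_k * calib$dark_sigmas[channel] & !saturated
  list(valid = !saturated & !below, saturated = saturated,
       below_noise = below)
}

#' Fuse an LDR stack into a composite HDR radiance image
#'
#' The core reconstruction. Each channel is linearized
#' (`x_i = (counts_i - offset_i) / alpha_i`) and masked to its usable band;
#' per pixel the fused radiance is the weighted mean over valid channels.
#' `"inverse_variance"` weights each channel by the reciprocal of its
#' propagated noise variance,
#' `Var[x_i] = (gain_i * max(counts_i - offset_i, 0) + dark_sigma_i^2) / alpha_i^2`
#' (Poisson shot noise plus Gaussian dark noise); `"binary"` weights every
#' valid channel equally. Pixels valid in no channel: saturated in every
#' channel gets the best channel's saturation-equivalent radiance (a
#' declared floor, flagged in `all_saturated_mask`); below the noise floor in
#' every channel gets 0 (flagged in `all_noise_mask`); the rare mixed case
#' falls back to the unweighted mean of all channels.
#'
#' @param stack an `ldr_stack`.
#' @param calib an `hdr_calibration` covering all channels.
#' @param weighting `"inverse_variance"` or `"binary"`.
#' @param sat_frac,noise_k band thresholds, as in [validity_masks].
#' @return an `hdr_image`: fields `radiance`, `weight_sum`, `n_valid`,
#'   `all_saturated_mask`, `all_noise_mask`, plus the fusion parameters.
#' @export
fuse <- function(stack, calib, weighting = c("inverse_variance", "binary"),
                 sat_frac = 0.98, noise_k = 3) {
  weighting <- match.arg(weighting)
  imgs <- stack$images
  nch <- length(imgs)
  if (length(calib$alphas) != nch)
    stop("calibration covers a different number of channels than the stack")
  dims <- dim(imgs[[1]]$data)
  num <- den <- matrix(0, dims[1], dims[2])
  n_valid <- matrix(0L, dims[1], dims[2])
  all_sat <- all_noise <- matrix(TRUE, dims[1], dims[2])
  sat_equiv <- rep(-Inf, prod(dims))
  fallback_sum <- matrix(0, dims[1], dims[2])
  for (i in seq_len(nch)) {
    m <- validity_masks(imgs[[i]], calib, sat_frac, noise_k, channel = i)
    x <- correct_response(imgs[[i]], calib, channel = i)
    cfg <- imgs[[i]]$config
    w <- if (weighting == "inverse_variance") {
      v <- (cfg$gain * pmax(imgs[[i]]$data - calib$offsets[i], 0) +
              calib$dark_sigmas[i]^2) / calib$alphas[i]^2
      1 / pmax(v, .Machine$double.eps)
    } else matrix(1, dims[1], dims[2])
    num <- num + ifelse(m$valid, w * x, 0)
    den <- den + ifelse(m$valid, w, 0)
    n_valid <- n_valid + m$valid
    all_sat <- all_sat & m$saturated
    all_noise <- all_noise & m$below_noise
    sat_equiv <- pmax(sat_equiv,
                      (sat_frac * cfg$sat_level - calib$offsets[i]) /
                        calib$alphas[i])
    fallback_sum <- fallback_sum + x
  }
  radiance <- matrix(0, dims[1], dims[2])
  ok <- n_valid > 0
  radiance[ok] <- num[ok] / den[ok]
  radiance[all_sat] <- max(sat_equiv)
  mixed <- !ok & !all_sat & !all_noise
  radiance[mixed] <- fallback_sum[mixed] / nch
  structure(list(radiance = radiance, weight_sum = den, n_valid = n_valid,
                 all_saturated_mask = all_sat, all_noise_mask = all_noise,
                 weighting = weighting, sat_frac = sat_frac,
                 noise_k = noise_k, calib = calib),
            class = "hdr_image")
}

#' @export
print.hdr_image <- function(x, ...) {
  cat(sprintf(
    "hdr_image: %s px, radiance [%g, %g], %s weights; %.2f%% all-saturated, %.2f%% all-noise\n",
    paste(dim(x$radiance), collapse = " x "), min(x$radiance), max(x$radiance),
    x$weighting, 100 * mean(x$all_saturated_mask), 100 * mean(x$all_noise_mask)))
  invisible(x)
}

# integer-pixel phase correlation between two images (FFT cross-power
# spectrum); returns list(shift = c(dy, dx), confidence)
phase_correlate <- function(ref, mov) {
  Fa <- stats::fft(ref); Fb <- stats::fft(mov)
  cp <- Fa * Conj(Fb)
  denom <- pmax(Mod(cp), .Machine$double.eps)
  r <- Re(stats::fft(cp / denom, inverse = TRUE)) / length(ref)
  peak <- max(r)
  cand <- which(r >= peak - 1e-12, arr.ind = TRUE)
  nr <- nrow(ref); nc <- ncol(ref)
  dy <- cand[, 1] - 1; dx <- cand[, 2] - 1
  dy <- ifelse(dy > nr / 2, dy - nr, dy)
  dx <- ifelse(dx > nc / 2, dx - nc, dx)
  # flat-plateau tie-break: smallest magnitude, rows before columns
  ord <- order(abs(dy) + abs(dx), abs(dy), abs(dx), dy, dx)
  list(shift = unname(c(dy[ord[1]], dx[ord[1]])), confidence = peak)
}

#' Register a sequentially acquired stack to a reference channel
#'
#' Sequential bracketing of a moving sample misaligns the exposures and
#' produces ghosting in the fused image. Each non-reference image is rigidly
#' translated (integer pixels) to the phase-correlation optimum against the
#' reference, computed on offset-subtracted data with noise-band pixels
#' zeroed. If the correlation peak is below `min_confidence` the image is
#' left unshifted with a warning.
#'
#' @param stack a sequential `ldr_stack` with >= 2 channels.
#' @param calib an `hdr_calibration`.
#' @param reference index of the reference channel.
#' @param noise_k noise floor used to down-weight background pixels.
#' @param min_confidence phase-correlation peak floor.
#' @return the aligned `ldr_stack`; `$registration` holds the applied
#'   (dy, dx) per channel.
#' @export
register_sequential <- function(stack, calib, reference = 1L, noise_k = 3,
                                min_confidence = 0.03) {
  if (stack$mode != "sequential")
    stop("registration applies to sequential stacks")
  imgs <- stack$images
  if (length(imgs) < 2) stop("need >= 2 channels to register")
  prep <- function(i) {
    d <- imgs[[i]]$data - calib$offsets[i]
    d[d < noise_k * calib$dark_sigmas[i]] <- 0
    d / max(d, 1)
  }
  ref <- prep(reference)
  applied <- rep(list(c(0, 0)), length(imgs))
  for (i in seq_along(imgs)) {
    if (i == reference) next
    pc <- phase_correlate(ref, prep(i))
    if (pc$confidence < min_confidence) {
      warning(sprintf(
        "channel %d: correlation peak %.3f below confidence floor; left unshifted",
        i, pc$confidence))
      next
    }
    applied[[i]] <- pc$shift
    imgs[[i]]$data <- shift_image(imgs[[i]]$data, pc$shift[1], pc$shift[2],
                                  fill = round(calib$offsets[i]))
    storage.mode(imgs[[i]]$data) <- "integer"
  }
  stack$images <- imgs
  stack$registration <- applied
  stack
}
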