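#' SNR versus intensity for single-channel, averaged and fused imaging
#'
#' Monte-Carlo SNR curves over an intensity grid. For each intensity a
#' uniform patch is imaged `n_repeats` times; the patch estimate is the mean
#' linearized value over the patch (single channels and frame averages) or
#' the mean fused radiance (HDR), and SNR is the across-repeat mean/sd of
#' that estimate. A channel is marked unusable at intensities where its
#' patch-mean counts sit outside the usable band (clipped estimates make
#' mean/sd meaningless); unusable entries carry `usable = FALSE`.
#'
#' @param configs list of [channel_config] (channels of the HDR bracket).
#' @param intensities radiance grid (reference-channel photon units).
#' @param n_repeats Monte-Carlo repeats (>= 2).
#' @param patch patch side in pixels.
#' @param n_average frames for the averaging baseline (0 = skip).
#' @param seed integer seed.
#' @param sat_frac,noise_k usable-band thresholds.
#' @return data.frame with columns `intensity`, `method`, `snr`, `mean`,
#'   `sd`, `usable`.
#' @export
snr_curve <- function(configs, intensities = 10^(0:5), n_repeats = 200,
                      patch = 16, n_average = 16, seed = 1,
                      sat_frac = 0.98, noise_k = 3) {
  if (n_repeats < 2) stop("'n_repeats' must be >= 2")
  calib <- calibration_from_config(configs)
  nch <- length(configs)
  rows <- list()
  with_seed(seed, {
    for (I in intensities) {
      scene <- matrix(I, patch, patch)
      est <- matrix(NA_real_, n_repeats, nch + 2)
      mean_counts <- matrix(0, n_repeats, nch)
      for (r in seq_len(n_repeats)) {
        st <- acquire_stack(scene, configs, mode = "simultaneous")
        for (i in seq_len(nch)) {
          est[r, i] <- mean(correct_response(st$images[[i]], calib, channel = i))
          mean_counts[r, i] <- mean(st$images[[i]]$data)
        }
        est[r, nch + 1] <- mean(fuse(st, calib, sat_frac = sat_frac,
                                     noise_k = noise_k)$radiance)
        if (n_average > 0) {
          fr <- lapply(seq_len(n_average), function(k)
            acquire_ldr(scene, configs[[1]]))
          est[r, nch + 2] <- mean((average_frames(fr) - calib$offsets[1]) /
                                    calib$alphas[1])
        }
      }
      meth <- c(paste0("channel", seq_len(nch)), "hdr",
                if (n_average > 0) sprintf("average%d", n_average))
      for (k in seq_along(meth)) {
        v <- est[, k]
        usable <- if (k <= nch) {
          mc <- mean(mean_counts[, k])
          mc < sat_frac * configs[[k]]$sat_level &&
            mc > configs[[k]]$offset + noise_k * configs[[k]]$dark_sigma
        } else TRUE
        rows[[length(rows) + 1]] <- data.frame(
          intensity = I, method = meth[k], snr = mean(v) / sd(v),
          mean = mean(v), sd = sd(v), usable = usable)
      }
    }
  })
  do.call(rbind, rows)
}

#' Effective dynamic range of a channel set
#'
#' Ratio of the largest radiance estimable before every channel saturates to
#' the smallest radiance above the noise floor of the most sensitive
#' channel, and its base-2 logarithm (effective bits). Dark noise and
#' saturation shrink a detector's nominal bit depth to this effective value;
#' attenuation-bracketed channels extend the top end by the largest
#' attenuation factor.
#'
#' @param configs list of [channel_config].
#' @param sat_frac,noise_k usable-band thresholds.
#' @return list `dr_ratio`, `effective_bits`, `max_estimable`, `noise_floor`
#'   (radiance in reference-channel units: counts / reference sensitivity).
#' @export
effective_dynamic_range <- function(configs, sat_frac = 0.98, noise_k = 3) {
  if (inherits(configs, "channel_config")) configs <- list(configs)
  a <- vapply(configs, alpha_raw, 0)
  tops <- vapply(seq_along(configs), function(i)
    (sat_frac * configs[[i]]$sat_level - configs[[i]]$offset) / a[i], 0)
  floors <- vapply(seq_along(configs), function(i)
    noise_k * configs[[i]]$dark_sigma / a[i], 0)
  if (any(tops <= 0) || min(floors) >= max(tops))
    stop("degenerate configuration: noise floor at or above saturation")
  dr <- max(tops) / min(floors)
  list(dr_ratio = dr, effective_bits = log2(dr),
       max_estimable = max(tops), noise_floor = min(floors))
}

#' Intensity profile along a line segment
#'
#' Bilinearly interpolated samples along the segment from `p0` to `p1`
#' ((row, col) coordinates), one sample per pixel of path length, averaged
#' across `width` parallel offsets perpendicular to the path.
#'
#' @param image numeric matrix (HDR radiance or any 2-D image).
#' @param p0,p1 endpoints, `c(row, col)`, inside the image.
#' @param width perpendicular averaging width in pixels (>= 1).
#' @return data.frame with `distance` (px along path) and `value`.
#' @export
line_profile <- function(image, p0, p1, width = 1) {
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length profile path")
  inside <- function(p) all(p >= 1) && p[1] <= nrow(image) && p[2] <= ncol(image)
  if (!inside(p0) || !inside(p1)) stop("profile endpoints must lie inside the image")
  n <- ceiling(len) + 1
  t <- seq(0, 1, length.out = n)
  dir <- (p1 - p0) / len
  perp <- c(-dir[2], dir[1])
  offs <- if (width > 1) seq(-(width - 1) / 2, (width - 1) / 2, length.out = width)
  else 0
  bilin <- function(r, c) {
    r <- pmin(pmax(r, 1), nrow(image)); c <- pmin(pmax(c, 1), ncol(image))
    r0 <- pmin(floor(r), nrow(image) - 1); c0 <- pmin(floor(c), ncol(image) - 1)
    fr <- r - r0; fc <- c - c0
    image[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      image[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      image[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      image[cbind(r0 + 1, c0 + 1)] * fr * fc
  }
  vals <- rowMeans(vapply(offs, function(o) {
    bilin(p0[1] + t * (p1[1] - p0[1]) + o * perp[1],
          p0[2] + t * (p1[2] - p0[2]) + o * perp[2])
  }, numeric(n)))
  data.frame(distance = t * len, value = vals)
}

#' ROI time-intensity curve
#'
#' Mean signal inside a region of interest as a function of frame time —
#' the standard readout of tracer kinetics. For LDR input frames the
#' per-frame fraction of saturated ROI pixels is reported alongside, since a
#' clipped sequence plateaus where the true kinetics peak.
#'
#' @param frames list of `hdr_image`, `ldr_image`, [scene_truth] or
#'   matrices, all of one shape.
#' @param roi_mask logical matrix, nonempty.
#' @param times frame times; defaults to 0, 1, 2, ...
#' @return data.frame with `t`, `mean`, and `saturated_frac` (NA for
#'   non-LDR input).
#' @export
roi_time_intensity <- function(frames, roi_mask, times = NULL) {
  if (!any(roi_mask)) stop("empty ROI")
  if (is.null(times)) times <- seq_along(frames) - 1
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    if (inherits(f, "hdr_image")) {
      data.frame(t = times[i], mean = mean(f$radiance[roi_mask]),
                 saturated_frac = NA_real_)
    } else if (inherits(f, "ldr_image")) {
      data.frame(t = times[i], mean = mean(f$data[roi_mask]),
                 saturated_frac = mean(f$data[roi_mask] >= f$config$sat_level))
    } else {
      img <- if (inherits(f, "scene_truth")) f$radiance else f
      data.frame(t = times[i], mean = mean(img[roi_mask]),
                 saturated_frac = NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' Score detected centroids against ground truth
#'
#' Greedy one-to-one nearest-neighbour matching within `match_radius`
#' (closest pairs first; ties broken by (row, col) order). With no true
#' negatives in a detection task, "specificity" is reported as precision.
#'
#' @param pred data.frame (or matrix) of predicted centroids with
#'   `row`, `col` columns.
#' @param truth ground-truth centroids, same layout.
#' @param match_radius maximum matching distance in pixels (> 0).
#' @return a `detection_score`: counts `tp`, `fp`, `fn` and rates
#'   `sensitivity`, `precision`, `accuracy` (`tp / (tp + fp + fn)`).
#' @export
detection_score <- function(pred, truth, match_radius = 5) {
  if (match_radius <= 0) stop("'match_radius' must be > 0")
  as_mat <- function(x) {
    if (is.data.frame(x)) cbind(x$row, x$col)
    else if (is.null(x) || !length(x)) matrix(0, 0, 2)
    else as.matrix(x)
  }
  p <- as_mat(pred); g <- as_mat(truth)
  np <- nrow(p); ng <- nrow(g)
  tp <- 0L
  if (np > 0 && ng > 0) {
    d <- sqrt(outer(p[, 1], g[, 1], `-`)^2 + outer(p[, 2], g[, 2], `-`)^2)
    cand <- which(d <= match_radius, arr.ind = TRUE)
    if (nrow(cand)) {
      dv <- d[cand]
      ord <- order(dv, p[cand[, 1], 1], p[cand[, 1], 2])
      used_p <- logical(np); used_g <- logical(ng)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_p[i] && !used_g[j]) {
          used_p[i] <- used_g[j] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- np - tp; fn <- ng - tp
  structure(list(tp = tp, fp = fp, fn = fn, match_radius = match_radius,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 accuracy = if (tp + fp + fn > 0) tp / (tp + fp + fn)
                 else NA_real_),
            class = "detection_score")
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf(
    "detection_score: tp %d, fp %d, fn %d | sensitivity %.3f, precision %.3f, accuracy %.3f\n",
    x$tp, x$fp, x$fn, x$sensitivity, x$precision, x$accuracy))
  invisible(x)
}
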