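test_that("single-pixel SNR matches the shot-plus-dark-noise closed form", {
  cfg <- channel_config()
  tab <- snr_curve(list(cfg), intensities = c(20, 200), n_repeats = 2000,
                   patch = 1, n_average = 0, seed = 1)
  for (lam in c(20, 200)) {
    got <- tab$snr[tab$intensity == lam & tab$method == "channel1"]
    expect_equal(got, lam / sqrt(lam + 100), tolerance = 0.1)
  }
})

test_that("16-frame averaging multiplies SNR by 4 within 10%", {
  cfg <- channel_config()
  tab <- snr_curve(list(cfg), intensities = 50, n_repeats = 1500,
                   patch = 1, n_average = 16, seed = 2)
  r <- tab$snr[tab$method == "average16"] / tab$snr[tab$method == "channel1"]
  expect_equal(r, 4, tolerance = 0.1)
})

test_that("snr_curve is reproducible and positive where signal exists", {
  cfgs <- bracket3()
  a <- snr_curve(cfgs, intensities = c(100, 1000), n_repeats = 50, seed = 3,
                 n_average = 0)
  b <- snr_curve(cfgs, intensities = c(100, 1000), n_repeats = 50, seed = 3,
                 n_average = 0)
  expect_identical(a, b)
  expect_true(all(a$snr[a$mean > 0] > 0))
})

test_that("effective dynamic range follows the closed-form band limits", {
  one <- effective_dynamic_range(list(channel_config()))
  expect_equal(one$dr_ratio, (0.98 * 4095 - 100) / 30, tolerance = 1e-12)
  expect_equal(one$effective_bits, log2((0.98 * 4095 - 100) / 30),
               tolerance = 1e-12)
  # an OD 1.8 channel multiplies the top of the range by 10^1.8
  multi <- effective_dynamic_range(list(channel_config(),
                                        channel_config(od = 1.8)))
  expect_equal(multi$dr_ratio / one$dr_ratio, 10^1.8, tolerance = 1e-12)
  # a duplicate channel adds nothing
  dup <- effective_dynamic_range(list(channel_config(), channel_config()))
  expect_equal(dup$dr_ratio, one$dr_ratio)
  expect_error(effective_dynamic_range(list(channel_config(dark_sigma = 1e6))),
               "degenerate")
})

test_that("line profiles interpolate correctly", {
  flat <- matrix(3, 32, 32)
  pr <- line_profile(flat, c(5, 5), c(5, 25))
  expect_true(all(pr$value == 3))
  expect_equal(nrow(pr), ceiling(20) + 1)
  ramp <- matrix(rep(1:32, each = 32), 32, 32)  # value = column index
  pr2 <- line_profile(ramp, c(10, 4), c(10, 28))
  expect_equal(pr2$value, seq(4, 28, length.out = nrow(pr2)), tolerance = 1e-9)
  expect_error(line_profile(flat, c(5, 5), c(5, 5)), "zero-length")
  expect_error(line_profile(flat, c(0, 5), c(5, 25)), "inside")
})

test_that("ROI kinetics recover the generator's bolus curve", {
  p <- kinetic_params(t0 = 2, amplitude = 800, k_in = 2, k_out = 0.08,
                      k_ex = 0, dt = 0.5, n_frames = 24)
  frames <- make_kinetic_series(p, size = 96, seed = 5)
  vmask <- frames[[1]]$labels == 1
  cfgs <- list(channel_config(exposure = 0.9), channel_config(exposure = 0.1))
  cal <- calibration_from_config(cfgs)
  t <- sapply(frames, function(f) f$meta$t)
  hdr_frames <- lapply(seq_along(frames), function(i)
    fuse(acquire_stack(frames[[i]], cfgs, seed = 100 + i), cal))
  curve <- roi_time_intensity(hdr_frames, vmask, times = t)
  truth <- vascular_curve(p, t) * 0.9  # reference-channel units
  rmse <- sqrt(mean((curve$mean - truth)^2))
  expect_lt(rmse, 0.05 * max(truth))
  # tissue ROI (non-leaking probe) before arrival reads zero within noise
  bg <- roi_time_intensity(hdr_frames[1:4], frames[[1]]$labels == 2,
                           times = t[1:4])
  expect_lt(max(abs(bg$mean)), 1)
  expect_error(roi_time_intensity(hdr_frames, vmask & FALSE), "empty")
})

test_that("a clipped LDR kinetic curve plateaus where the HDR curve peaks", {
  p <- kinetic_params(t0 = 1, amplitude = 2e4, k_in = 2, k_out = 0.05,
                      dt = 0.5, n_frames = 16)
  frames <- make_kinetic_series(p, size = 64, seed = 6)
  vmask <- frames[[1]]$labels == 1
  cfgs <- bracket3()
  cal <- calibration_from_config(cfgs)
  ldr_frames <- lapply(seq_along(frames), function(i)
    acquire_ldr(frames[[i]], cfgs[[1]], seed = i))
  hdr_frames <- lapply(seq_along(frames), function(i)
    fuse(acquire_stack(frames[[i]], cfgs, seed = 200 + i), cal))
  lcurve <- roi_time_intensity(ldr_frames, vmask)
  hcurve <- roi_time_intensity(hdr_frames, vmask)
  expect_gt(max(lcurve$saturated_frac), 0.9)       # the LDR clips at the peak
  expect_lt(max(lcurve$mean), cfgs[[1]]$sat_level + 1)
  expect_gt(max(hcurve$mean), 2 * cfgs[[1]]$sat_level)  # HDR sails past it
})

test_that("detection scoring arithmetic is exact on constructed cases", {
  truth <- data.frame(row = rep(1:10, 10) * 10, col = rep(1:10, each = 10) * 10)
  pred <- truth[1:90, ]                       # 90 matched, 10 missed
  pred <- rbind(pred, data.frame(row = 500 + 1:5, col = 500 + 1:5))  # 5 spurious
  s <- detection_score(pred, truth, match_radius = 3)
  expect_equal(s$tp, 90L); expect_equal(s$fn, 10L); expect_equal(s$fp, 5L)
  expect_equal(s$sensitivity, 0.9)
  expect_equal(s$precision, 18 / 19)
  expect_equal(s$accuracy, 90 / 105)

  perfect <- detection_score(truth, truth, 2)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fp + perfect$fn, 0L)

  none <- detection_score(truth[0, ], truth, 2)
  expect_equal(none$tp, 0L)
  expect_equal(none$fn, 100L)
  expect_true(is.na(none$precision))
})

test_that("detection scoring is symmetric with sensitivity/precision swapped", {
  set.seed(11)
  truth <- data.frame(row = runif(30, 0, 100), col = runif(30, 0, 100))
  pred <- data.frame(row = runif(25, 0, 100), col = runif(25, 0, 100))
  a <- detection_score(pred, truth, 8)
  b <- detection_score(truth, pred, 8)
  expect_equal(a$tp, b$tp)
  expect_equal(a$sensitivity, b$precision)
  expect_equal(a$precision, b$sensitivity)
  expect_error(detection_score(pred, truth, 0), "> 0")
})
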