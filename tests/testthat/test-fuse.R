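test_that("the three validity masks partition every image", {
  cfg <- channel_config()
  cal <- calibration_from_config(list(cfg))
  sc <- make_phantom(c(1, 0.1, 0.01), peak = 5000)
  ldr <- acquire_ldr(sc, cfg, seed = 1)
  m <- validity_masks(ldr, cal, channel = 1)
  expect_true(all(m$valid + m$saturated + m$below_noise == 1))
  # noise-free dark frame is entirely below the noise floor
  dark <- synthetic_ldr(matrix(0, 8, 8), 1, channel_config(dark_sigma = 0))
  md <- validity_masks(dark, calibration_from_config(list(dark$config)),
                       channel = 1)
  expect_true(all(md$below_noise))
  # an all-clipped frame is entirely saturated
  sat <- synthetic_ldr(matrix(1e6, 8, 8), 1, cfg)
  ms <- validity_masks(sat, cal, channel = 1)
  expect_true(all(ms$saturated))
})

test_that("fused values match an independent per-pixel weighted-mean oracle", {
  sc <- make_phantom(c(1, 0.1, 0.01), peak = 1e5, size = 96)
  cfgs <- bracket3()
  st <- acquire_stack(sc, cfgs, mode = "simultaneous", seed = 21)
  cal <- calibration_from_config(cfgs)
  for (wmode in c("inverse_variance", "binary")) {
    h <- fuse(st, cal, weighting = wmode)
    set.seed(17)
    px <- sample(length(sc$radiance), 1000)
    # independently coded scalar oracle over the same masking rules
    for (p in px) {
      num <- 0; den <- 0; nv <- 0
      all_sat <- TRUE; all_noi <- TRUE
      for (i in 1:3) {
        cts <- st$images[[i]]$data[p]
        cfg <- cfgs[[i]]
        is_sat <- cts >= 0.98 * cfg$sat_level
        is_noi <- !is_sat && cts <= cal$offsets[i] + 3 * cal$dark_sigmas[i]
        all_sat <- all_sat && is_sat
        all_noi <- all_noi && is_noi
        if (!is_sat && !is_noi) {
          x <- (cts - cal$offsets[i]) / cal$alphas[i]
          w <- if (wmode == "inverse_variance")
            cal$alphas[i]^2 / (cfg$gain * max(cts - cal$offsets[i], 0) +
                                 cal$dark_sigmas[i]^2)
          else 1
          num <- num + w * x; den <- den + w; nv <- nv + 1
        }
      }
      expected <- if (nv > 0) num / den
      else if (all_sat) max((0.98 * 4095 - cal$offsets) / cal$alphas)
      else if (all_noi) 0
      else mean(sapply(1:3, function(i)
        (st$images[[i]]$data[p] - cal$offsets[i]) / cal$alphas[i]))
      expect_equal(h$radiance[p], expected, tolerance = 1e-10)
      expect_equal(h$n_valid[p], nv)
    }
  }
})

test_that("two identical channels fuse to the mean of their corrections", {
  cfg <- channel_config()
  a <- acquire_ldr(matrix(800, 32, 32), cfg, seed = 1)
  b <- acquire_ldr(matrix(800, 32, 32), cfg, seed = 2)
  st <- as_stack(list(a, b))
  cal <- calibration_from_config(list(cfg, cfg))
  h <- fuse(st, cal, weighting = "binary")
  both <- h$n_valid == 2
  expect_gt(mean(both), 0.99)
  expect_equal(h$radiance[both],
               ((a$data[both] - 100) + (b$data[both] - 100)) / 2)
})

test_that("single-channel fusion degenerates to response correction", {
  cfg <- channel_config()
  ldr <- acquire_ldr(matrix(600, 24, 24), cfg, seed = 4)
  cal <- calibration_from_config(list(cfg))
  h <- fuse(as_stack(list(ldr)), cal)
  v <- h$n_valid == 1
  expect_identical(h$radiance[v], correct_response(ldr, cal)[v])
})

test_that("the phantom fuses to its true 1 : 0.1 : 0.01 concentration ratios", {
  sc <- make_phantom(c(1, 0.1, 0.01), peak = 1e5, size = 192)
  st <- acquire_stack(sc, bracket3(), mode = "simultaneous", seed = 8)
  cal <- calibration_from_config(bracket3())
  h <- fuse(st, cal)
  means <- sapply(1:3, function(i) mean(h$radiance[sc$labels == i]))
  expect_true(all(table(sc$labels[sc$labels > 0]) >= 1e3))
  expect_equal(means / means[1], c(1, 0.1, 0.01), tolerance = 0.05)
  # fused region means are unbiased within 3 standard errors
  n3 <- sum(sc$labels == 3)
  se3 <- sqrt((1e3 + 100) / n3) / 1e3
  expect_equal(means[3], 1e3, tolerance = 3 * se3)
})

test_that("attenuation bracketing extends the estimable range by 10^1.8", {
  single <- effective_dynamic_range(list(channel_config()))
  multi <- effective_dynamic_range(bracket3())
  expect_equal(multi$dr_ratio / single$dr_ratio, 10^1.8, tolerance = 0.01)
})

test_that("all-saturated and all-noise pixels carry their declared floors", {
  cfgs <- bracket3()
  cal <- calibration_from_config(cfgs)
  sat_stack <- as_stack(lapply(cfgs, function(cf)
    synthetic_ldr(matrix(1e9, 4, 4), hdrlsm:::alpha_raw(cf), cf)))
  h <- fuse(sat_stack, cal)
  expect_true(all(h$all_saturated_mask))
  expect_equal(h$radiance[1, 1], max((0.98 * 4095 - 100) / cal$alphas))
  dark_stack <- as_stack(lapply(cfgs, function(cf)
    synthetic_ldr(matrix(0, 4, 4), 1, channel_config(od = cf$od,
                                                     dark_sigma = 0))))
  hd <- fuse(dark_stack, cal)
  expect_true(all(hd$all_noise_mask))
  expect_true(all(hd$radiance == 0))
  expect_true(all(hd$n_valid[hd$all_noise_mask | hd$all_saturated_mask] == 0))
})

test_that("registration undoes a known sequential shift and a zero shift is identity", {
  sc <- make_beads(c(100), 15, seed = 3, peak = 2000)
  cfgs <- bracket3()[1:2]
  cal <- calibration_from_config(cfgs)
  still <- acquire_stack(sc, cfgs, mode = "sequential", seed = 1)
  r0 <- register_sequential(still, cal)
  expect_equal(r0$registration, list(c(0, 0), c(0, 0)))
  moved <- acquire_stack(sc, cfgs, mode = "sequential", seed = 2,
                         motion = list(c(0, 0), c(5, -3)))
  r1 <- register_sequential(moved, cal)
  expect_equal(r1$registration[[2]], c(-5, 3))
})

test_that("fusing a registered stack beats the unregistered one against truth", {
  sc <- make_beads(c(100, 10), 12, seed = 6, peak = 3000)
  cfgs <- bracket3()
  cal <- calibration_from_config(cfgs)
  moved <- acquire_stack(sc, cfgs, mode = "sequential", seed = 7,
                         motion = list(c(0, 0), c(6, 0), c(0, 0)))
  truth <- sc$radiance
  rmse_of <- function(stack) {
    h <- fuse(stack, cal)
    sqrt(mean((h$radiance - truth)^2))
  }
  un <- rmse_of(moved)
  reg <- rmse_of(register_sequential(moved, cal))
  expect_lt(reg, un / 2)
})

test_that("fusion rejects a stack/calibration channel mismatch", {
  sc <- make_phantom(c(1))
  st <- acquire_stack(sc, bracket3(), seed = 1)
  expect_error(fuse(st, calibration_from_config(bracket3()[1:2])), "channels")
})
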