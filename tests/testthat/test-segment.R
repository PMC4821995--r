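test_that("rolling-ball subtraction removes flat background and keeps small peaks", {
  flat <- matrix(17, 64, 64)
  expect_true(all(rolling_ball(flat, 10) == 0))
  # a small bright disc on flat background survives nearly intact
  sc <- stamp <- matrix(5, 96, 96)
  sc[45:51, 45:51] <- 105
  out <- rolling_ball(sc, 20)
  expect_gt(out[48, 48], 0.95 * 100)
  expect_true(all(out >= 0))
  expect_error(rolling_ball(flat, 0.5), ">= 1")
  expect_error(rolling_ball(matrix(1, 10, 10), 6), "smaller")
})

test_that("the enhancement kernel is the zero-sum 5x5 sharpener", {
  k <- hdrlsm:::mito_kernel()
  expect_equal(k[3, 3], 24)
  expect_true(all(k[-13] == -1))
  expect_equal(sum(k), 0)
  # zero-sum kernel: constant image maps to (numerically) zero
  out <- mito_enhance(matrix(9, 32, 32), bandpass = FALSE)
  expect_lt(max(abs(out)), 1e-9)
  # impulse response reproduces the kernel
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  resp <- mito_enhance(imp, bandpass = FALSE)
  expect_equal(resp[9:13, 9:13], k, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(mito_enhance(matrix(1, 3, 3)), "5 x 5")
})

test_that("the maximum-entropy threshold matches a brute-force scan exactly", {
  # independent oracle: direct double-loop evaluation of the Kapur criterion
  kapur_brute <- function(v, n_bins = 256) {
    breaks <- seq(min(v), max(v), length.out = n_bins + 1)
    h <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                       n_bins), n_bins)
    p <- h / sum(h)
    best <- -Inf; best_s <- NA
    for (s in 1:(n_bins - 1)) {
      p1 <- p[1:s]; p2 <- p[(s + 1):n_bins]
      P1 <- sum(p1); P2 <- sum(p2)
      if (P1 <= 0 || P2 <= 0) next
      H1 <- -sum(ifelse(p1 > 0, p1 / P1 * log(p1 / P1), 0))
      H2 <- -sum(ifelse(p2 > 0, p2 / P2 * log(p2 / P2), 0))
      if (H1 + H2 > best + 1e-12) { best <- H1 + H2; best_s <- s }
    }
    breaks[best_s + 1]
  }
  set.seed(13)
  for (rep in 1:50) {
    v <- c(rnorm(300, 10, 2), rnorm(200, 40, 6), runif(50, 0, 60))
    expect_identical(max_entropy_threshold(v, 64), kapur_brute(v, 64))
  }
})

test_that("the threshold separates a two-level image and survives affine rescaling", {
  v <- c(rep(2, 400), rep(30, 100))
  thr <- max_entropy_threshold(v)
  expect_gt(thr, 2); expect_lt(thr, 30)
  img <- decade_image(32, 2, seed = 3)
  t0 <- max_entropy_threshold(img, 128)
  t1 <- max_entropy_threshold(5 * img + 7, 128)
  bin_width <- diff(range(img)) / 128
  expect_equal((t1 - 7) / 5, t0, tolerance = 2 * bin_width)
  expect_error(max_entropy_threshold(matrix(3, 4, 4)), "constant")
})

test_that("size filtering drops small objects and never adds any", {
  m <- matrix(FALSE, 32, 32)
  m[2:4, 2:4] <- TRUE        # size 9
  m[20:29, 20:29] <- TRUE    # size 100
  expect_equal(nrow(size_filter(m, 1)$objects), 2)
  r <- size_filter(m, 10)
  expect_equal(nrow(r$objects), 1)
  expect_equal(sort(unique(as.vector(r$labels))), c(0L, 1L))
  expect_equal(nrow(size_filter(m, 101)$objects), 0)
  set.seed(21)
  noise <- matrix(runif(64 * 64) > 0.7, 64, 64)
  n_before <- nrow(size_filter(noise, 1)$objects)
  for (ms in c(2, 4, 8))
    expect_lte(nrow(size_filter(noise, ms)$objects), n_before)
})

test_that("the mitochondria pipeline recovers curvilinear blobs at high SNR", {
  set.seed(31)
  img <- matrix(rnorm(128 * 128, 20, 2), 128, 128)
  truth <- data.frame(row = numeric(), col = numeric())
  centres <- expand.grid(row = c(28, 64, 100), col = c(28, 64, 100))
  for (b in seq_len(nrow(centres))) {
    r0 <- centres$row[b] + runif(1, -5, 5)
    c0 <- centres$col[b] + runif(1, -5, 5)
    ang <- runif(1, 0, pi)
    for (t in seq(-6, 6, by = 0.5)) {
      rr <- round(r0 + t * sin(ang) + (-1:1))
      cc <- round(c0 + t * cos(ang) + (-1:1))
      img[rr, cc] <- 220
    }
    truth <- rbind(truth, data.frame(row = r0, col = c0))
  }
  res <- segment_mitochondria(img, ball_radius = 20, min_size = 12)
  sc <- detection_score(res$objects, truth, match_radius = 6)
  expect_gte(sc$sensitivity, 0.9)
  res2 <- segment_mitochondria(img, ball_radius = 20, min_size = 12)
  expect_identical(res$labels, res2$labels)
  # blank field segments to nothing
  blank <- segment_mitochondria(matrix(4, 64, 64))
  expect_equal(nrow(blank$objects), 0)
})

test_that("well-separated somata count as distinct cell bodies", {
  vol <- array(0, c(64, 64, 5))
  for (ctr in list(c(16, 16), c(48, 48))) {
    for (z in 2:4) {
      d <- sqrt(outer((1:64 - ctr[1])^2, (1:64 - ctr[2])^2, `+`))
      vol[, , z][d <= 7] <- 100
    }
  }
  out <- count_cell_bodies_3d(vol, bg_mean = 0, bg_sd = 1, erosion_radius = 2,
                              min_size = 20)
  expect_equal(out$count, 2L)
  # counting is invariant to intensity scaling above the threshold
  out2 <- count_cell_bodies_3d(vol * 50, bg_mean = 0, bg_sd = 50,
                               erosion_radius = 2, min_size = 20)
  expect_equal(out2$count, 2L)
  # empty foreground is count 0, not an error
  expect_equal(count_cell_bodies_3d(array(0, c(16, 16, 2)), bg_mean = 0,
                                    bg_sd = 1)$count, 0L)
})

test_that("watershed splits touching somata that a bright bridge fuses", {
  # two somata joined by a thin bright bridge (the saturation-induced
  # proximity-fusion artifact): watershed on the distance transform
  # separates them
  img <- matrix(0, 64, 64)
  for (ctr in list(c(32, 20), c(32, 44))) {
    d <- sqrt(outer((1:64 - ctr[1])^2, (1:64 - ctr[2])^2, `+`))
    img[d <= 8] <- 100
  }
  img[31:33, 20:44] <- 100  # bridge
  out <- count_cell_bodies_3d(img, bg_mean = 0, bg_sd = 1,
                              erosion_radius = 2, min_size = 20,
                              min_separation = 10)
  expect_equal(out$count, 2L)
  # the same truth rendered through a clipped low-range acquisition, where
  # clipping flattens somata and bridge to one level, still merges without
  # enough erosion: one object at erosion 0 demonstrates the artifact
  clipped <- pmin(img, 60)
  merged <- count_cell_bodies_3d(clipped, bg_mean = 0, bg_sd = 1,
                                 erosion_radius = 0, min_size = 20,
                                 min_separation = 30)
  expect_equal(merged$count, 1L)
})

test_that("skeleton statistics are exact on constructed geometries", {
  line <- matrix(FALSE, 32, 120)
  line[16, 11:110] <- TRUE
  fs <- filament_stats(line * 1, threshold = 0.5)
  expect_equal(fs$n_branch_points, 0L)
  expect_equal(fs$total_length, 99)
  expect_equal(fs$n_components, 1L)
  # symmetric Y: three arms, one branch point
  y <- matrix(FALSE, 120, 120)
  y[60:109, 60] <- TRUE                     # down
  for (t in 0:49) {
    y[60 - t, 60 - t] <- TRUE               # up-left diagonal
    y[60 - t, 60 + t] <- TRUE               # up-right diagonal
  }
  fy <- filament_stats(y * 1, threshold = 0.5)
  expect_equal(fy$n_branch_points, 1L)
  expect_equal(fy$n_components, 1L)
  # empty foreground
  f0 <- filament_stats(matrix(0, 16, 16), threshold = 0.5)
  expect_equal(f0$total_length, 0)
  expect_equal(f0$n_branch_points, 0L)
})

test_that("3-D primitives agree with direct definitions on small cases", {
  # distance transform: single background voxel in a filled volume
  m <- array(TRUE, c(9, 9, 3)); m[5, 5, 2] <- FALSE
  d <- distance_transform(m)
  expect_equal(d[5, 5, 2], 0)
  expect_equal(d[5, 7, 2], 2)
  expect_equal(d[4, 4, 1], sqrt(3))
  # connectivity: diagonal touch joins under 26, splits under 6
  v <- array(FALSE, c(4, 4, 2))
  v[1, 1, 1] <- TRUE; v[2, 2, 2] <- TRUE
  expect_equal(max(label_components(v, 26)), 1L)
  expect_equal(max(label_components(v, 6)), 2L)
})
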