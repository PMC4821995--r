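#' Segmentation result container
#'
#' @param labels integer label map (2-D or 3-D), background 0, ids
#'   contiguous from 1.
#' @param params list of the parameters that produced it.
#' @return a `segmentation_result` with an `objects` table
#'   (id, size, centroid).
#' @export
segmentation_result <- function(labels, params = list()) {
  ids <- seq_len(max(0L, max(labels)))
  objects <- if (length(ids)) {
    dims <- dim(as_volume(labels))
    idx <- which(labels > 0)
    lab <- labels[idx]
    z <- (idx - 1) %/% (dims[1] * dims[2])
    rem <- (idx - 1) %% (dims[1] * dims[2])
    data.frame(
      id = ids,
      size = as.integer(tabulate(lab, length(ids))),
      row = as.numeric(tapply(rem %% dims[1] + 1, lab, mean)),
      col = as.numeric(tapply(rem %/% dims[1] + 1, lab, mean)),
      slice = as.numeric(tapply(z + 1, lab, mean)))
  } else data.frame(id = integer(), size = integer(), row = numeric(),
                    col = numeric(), slice = numeric())
  structure(list(labels = labels, objects = objects, params = params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %d object(s), %s px\n",
              nrow(x$objects), paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Connected-component labelling (2-D or 3-D)
#'
#' 8-connectivity in 2-D, 26-connectivity in 3-D (6/4 available).
#'
#' @param mask logical matrix or array.
#' @param connectivity 26 (8 in 2-D) or 6 (4 in 2-D).
#' @return integer label map of the same shape.
#' @export
label_components <- function(mask, connectivity = 26) {
  v <- as_volume(mask)
  conn <- if (connectivity %in% c(8, 26)) 26L else 6L
  lab <- .label3d(as.logical(v), dim(v), conn)
  if (is.matrix(mask)) dim(lab) <- dim(mask)
  lab
}

#' Euclidean distance transform (2-D or 3-D)
#'
#' Exact distance from every foreground pixel/voxel to the nearest
#' background one (separable lower-envelope algorithm).
#'
#' @param mask logical matrix or array.
#' @return numeric map of distances, same shape.
#' @export
distance_transform <- function(mask) {
  v <- as_volume(mask)
  d <- .edt3d(as.logical(v), dim(v))
  if (is.matrix(mask)) dim(d) <- dim(mask)
  d
}

#' Rolling-ball background subtraction
#'
#' Estimates a slowly varying background as the grayscale morphological
#' opening with a disc structuring element of the given radius — the
#' standard first stage before thresholding unevenly lit fluorescence
#' images — and subtracts it, clipping at zero. Peaks much smaller than the
#' ball survive almost untouched; broad background is removed.
#'
#' @param image numeric matrix.
#' @param radius ball radius in pixels (>= 1, smaller than the image).
#' @return background-subtracted image, >= 0 everywhere.
#' @export
rolling_ball <- function(image, radius = 25) {
  if (radius < 1) stop("'radius' must be >= 1")
  if (2 * radius + 1 >= min(dim(image)))
    stop("ball diameter must be smaller than the image")
  mx <- max(image, 1e-12)
  bg <- EBImage::opening(image / mx, EBImage::makeBrush(2 * round(radius) + 1,
                                                        "disc")) * mx
  pmax(image - bg, 0)
}

# the mitochondrial enhancement kernel: 5x5, centre 24, rest -1 (zero sum)
mito_kernel <- function() {
  k <- matrix(-1, 5, 5)
  k[3, 3] <- 24
  k
}

#' High-pass convolution plus FFT band-pass for tubular structures
#'
#' Sharpens with the zero-sum 5x5 kernel (centre 24, remaining elements -1),
#' reflect-padded, then applies an FFT-based band-pass (difference of
#' Gaussians) keeping structures between `small` and `large` pixels —
#' the enhancement used before maximum-entropy thresholding of
#' mitochondria-like textures.
#'
#' @param image numeric matrix (>= 5x5).
#' @param small,large band-pass cut-offs in pixels.
#' @param bandpass apply the band-pass stage (FALSE returns the plain
#'   kernel response).
#' @return filtered image (may contain negative values).
#' @export
mito_enhance <- function(image, small = 3, large = 40, bandpass = TRUE) {
  if (any(dim(image) < 5)) stop("image must be at least 5 x 5")
  pad <- 2
  padded <- reflect_pad(image, pad)
  conv <- EBImage::filter2(padded, mito_kernel(), boundary = "circular")
  conv <- conv[(pad + 1):(pad + nrow(image)), (pad + 1):(pad + ncol(image))]
  if (!bandpass) return(conv)
  blur <- function(x, sigma) {
    if (sigma <= 0) return(x)
    sz <- 2 * ceiling(3 * sigma) + 1
    cap <- 2 * floor((min(dim(x)) - 1) / 2) + 1  # filter must fit the image
    EBImage::filter2(x, EBImage::makeBrush(min(sz, cap), "gaussian",
                                           sigma = sigma),
                     boundary = "replicate")
  }
  blur(conv, small / 2) - blur(conv, large / 2)
}

reflect_pad <- function(img, p) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rev(seq_len(p) + 1), seq_len(nr), nr - seq_len(p))
  ci <- c(rev(seq_len(p) + 1), seq_len(nc), nc - seq_len(p))
  img[ri, ci]
}

#' Maximum-entropy (Kapur) threshold
#'
#' Chooses the threshold maximizing the sum of Shannon entropies of the
#' sub- and supra-threshold histogram classes over an `n_bins` histogram.
#' Ties resolve to the lowest threshold; a constant image has no threshold
#' and is an error.
#'
#' @param image numeric matrix or vector with >= 2 distinct values.
#' @param n_bins histogram bins (default 256).
#' @return the threshold value (a bin edge); pixels strictly above it are
#'   foreground.
#' @export
max_entropy_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0) stop("constant image: no threshold exists")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins),
                n_bins)
  p <- h / sum(h)
  plogp <- ifelse(p > 0, -p * log(p), 0)
  c1 <- cumsum(p)
  e1 <- cumsum(plogp)
  s <- seq_len(n_bins - 1)
  P1 <- c1[s]; P2 <- 1 - P1
  H1 <- ifelse(P1 > 0, e1[s] / P1 + log(P1), 0)
  H2 <- ifelse(P2 > 0, (e1[n_bins] - e1[s]) / P2 + log(P2), 0)
  crit <- ifelse(P1 > 0 & P2 > 0, H1 + H2, -Inf)
  breaks[which.max(crit) + 1]
}

#' Remove small objects from a label map
#'
#' Drops connected components below `min_size` pixels/voxels and relabels
#' the survivors contiguously (order preserved).
#'
#' @param labels integer label map, or logical mask (labelled first).
#' @param min_size minimum object size (>= 1).
#' @param connectivity used only when `labels` is a mask.
#' @return a [segmentation_result].
#' @export
size_filter <- function(labels, min_size = 1, connectivity = 26) {
  if (min_size < 1) stop("'min_size' must be >= 1")
  if (is.logical(labels)) labels <- label_components(labels, connectivity)
  nmax <- max(0L, max(labels))
  sizes <- tabulate(labels[labels > 0], nmax)
  keep <- which(sizes >= min_size)
  remap <- integer(nmax)
  remap[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- remap[labels[labels > 0]]
  segmentation_result(out, params = list(min_size = min_size))
}

#' Mitochondria-style segmentation pipeline
#'
#' Rolling-ball background subtraction, kernel + band-pass enhancement,
#' maximum-entropy threshold, connected components, size filter — in that
#' order, with every parameter recorded in the result.
#'
#' @param image numeric matrix.
#' @param ball_radius rolling-ball radius (px).
#' @param small,large band-pass cut-offs (px).
#' @param n_bins threshold histogram bins.
#' @param min_size minimum object size (px).
#' @return a [segmentation_result].
#' @export
segment_mitochondria <- function(image, ball_radius = 25, small = 3,
                                 large = 40, n_bins = 256, min_size = 9) {
  params <- list(ball_radius = ball_radius, small = small, large = large,
                 n_bins = n_bins, min_size = min_size)
  bs <- rolling_ball(image, ball_radius)
  enh <- mito_enhance(bs, small = small, large = large)
  if (diff(range(enh)) == 0)  # blank field: nothing to segment
    return(segmentation_result(matrix(0L, nrow(image), ncol(image)),
                               params = params))
  thr <- max_entropy_threshold(enh, n_bins)
  res <- size_filter(enh > thr, min_size, connectivity = 8)
  res$params <- c(params, list(threshold = thr))
  res
}

# local maxima of a height map within a mask; plateaus collapse to one
# marker; maxima closer than min_sep merge (greedy, highest first)
find_markers <- function(height, mask, min_sep = 3) {
  v <- as_volume(height)
  m <- as_volume(mask)
  dims <- dim(v)
  is_max <- m
  for (dz in -1:1) for (dc in -1:1) for (dr in -1:1) {
    if (dr == 0 && dc == 0 && dz == 0) next
    if (dims[3] == 1 && dz != 0) next
    shifted <- array(-Inf, dims)
    r_src <- max(1, 1 - dr):min(dims[1], dims[1] - dr)
    c_src <- max(1, 1 - dc):min(dims[2], dims[2] - dc)
    z_src <- max(1, 1 - dz):min(dims[3], dims[3] - dz)
    shifted[r_src + dr, c_src + dc, z_src + dz] <- v[r_src, c_src, z_src]
    is_max <- is_max & (v >= shifted)
  }
  plat <- .label3d(as.logical(is_max & m), dims, 26L)
  np <- max(0L, max(plat))
  if (np == 0) return(NULL)
  idx1 <- vapply(seq_len(np), function(i) which(plat == i)[1], 0L)
  pos <- cbind((idx1 - 1) %% dims[1] + 1,
               ((idx1 - 1) %/% dims[1]) %% dims[2] + 1,
               (idx1 - 1) %/% (dims[1] * dims[2]) + 1)
  hts <- v[idx1]
  ord <- order(-hts, pos[, 1], pos[, 2], pos[, 3])
  kept <- integer(0)
  for (k in ord) {
    if (!length(kept) ||
        min(sqrt(rowSums(sweep(pos[kept, , drop = FALSE], 2,
                               pos[k, ])^2))) >= min_sep)
      kept <- c(kept, k)
  }
  list(pos = pos[kept, , drop = FALSE], idx = idx1[kept])
}

#' Count cell bodies in a volume
#'
#' The cell-body pipeline: foreground by intensity threshold at
#' `background mean + k * sigma` (the mean-noise +/- 3 sigma convention),
#' binary erosion, Euclidean distance transform, marker-based watershed to
#' split touching somata, connected components and size filtering. A 2-D
#' image is treated as a single-slice volume.
#'
#' @param volume numeric 3-D array (or 2-D matrix).
#' @param k threshold multiple of the background sd (default 3).
#' @param erosion_radius binary erosion radius in pixels.
#' @param min_size minimum object volume after watershed (voxels).
#' @param bg_mean,bg_sd background statistics; NULL estimates them robustly
#'   (median and MAD of the volume).
#' @param min_separation minimum marker separation (default
#'   `erosion_radius`).
#' @return list with `count` and the [segmentation_result].
#' @export
count_cell_bodies_3d <- function(volume, k = 3, erosion_radius = 3,
                                 min_size = 20, bg_mean = NULL, bg_sd = NULL,
                                 min_separation = NULL) {
  v <- as_volume(volume)
  if (is.null(bg_mean)) bg_mean <- median(v)
  if (is.null(bg_sd)) bg_sd <- mad(v)
  if (is.null(min_separation)) min_separation <- max(erosion_radius, 2)
  thr <- bg_mean + k * bg_sd
  mask <- v > thr
  params <- list(k = k, threshold = thr, erosion_radius = erosion_radius,
                 min_size = min_size, min_separation = min_separation)
  empty <- function() list(count = 0L,
                           segmentation = segmentation_result(
                             array(0L, dim(volume)), params = params))
  if (!any(mask)) return(empty())
  if (erosion_radius >= 1) {
    brush <- EBImage::makeBrush(2 * round(erosion_radius) + 1, "disc")
    mask <- EBImage::erode(mask * 1, brush) > 0  # per-slice (LSM z-anisotropy)
    mask <- array(as.logical(mask), dim(v))
  }
  if (!any(mask)) return(empty())
  edt <- .edt3d(as.logical(mask), dim(v))
  mk <- find_markers(edt, mask, min_sep = min_separation)
  if (is.null(mk)) return(empty())
  markers <- array(0L, dim(v))
  markers[mk$idx] <- seq_along(mk$idx)
  ws <- .watershed3d(-edt, markers, as.logical(mask), dim(v), 26L)
  res <- size_filter(ws, min_size)
  res$params <- params
  if (is.matrix(volume)) res$labels <- matrix(res$labels, nrow(volume))
  list(count = nrow(res$objects), segmentation = res)
}

# Zhang-Suen thinning; mask: logical matrix -> 1-px skeleton
skeletonize <- function(mask) {
  m <- mask * 1L
  nbr <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    rs <- max(1, 1 - dr):min(nrow(m), nrow(m) - dr)
    cs <- max(1, 1 - dc):min(ncol(m), ncol(m) - dc)
    out[rs + dr, cs + dc] <- m[rs, cs]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- nbr(m, 1, 0); p3 <- nbr(m, 1, -1); p4 <- nbr(m, 0, -1)
      p5 <- nbr(m, -1, -1); p6 <- nbr(m, -1, 0); p7 <- nbr(m, -1, 1)
      p8 <- nbr(m, 0, 1); p9 <- nbr(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- Reduce(`+`, lapply(1:8, function(i)
        (seqs[[i]] == 0) & (seqs[[i + 1]] == 1)))
      if (step == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1
}

#' Skeleton statistics of a filamentous structure
#'
#' Thresholds the image (at `bg_mean + k * bg_sd` unless a threshold is
#' given), skeletonizes the foreground (Zhang-Suen thinning) and reports
#' the number of branch points (skeleton pixels with >= 3 skeleton
#' neighbours, 8-connectivity) and the total skeleton length (unit steps
#' count 1, diagonal steps sqrt(2)). A 3-D input is maximum-projected to
#' 2-D first. Noise-fragmented renderings skeletonize into short
#' disconnected pieces, so summed length drops with SNR.
#'
#' @param image numeric matrix (or 3-D array; max-projected).
#' @param threshold explicit foreground threshold; NULL derives it.
#' @param k threshold multiple of the background sd.
#' @param bg_mean,bg_sd background statistics; NULL estimates them (median
#'   and MAD).
#' @param min_size discard skeleton fragments from components smaller than
#'   this many foreground pixels (0 keeps all).
#' @return list `n_branch_points`, `total_length`, `n_components`,
#'   `skeleton` (logical matrix).
#' @export
filament_stats <- function(image, threshold = NULL, k = 3, bg_mean = NULL,
                           bg_sd = NULL, min_size = 0) {
  if (length(dim(image)) == 3) image <- apply(image, c(1, 2), max)
  if (is.null(threshold)) {
    if (is.null(bg_mean)) bg_mean <- median(image)
    if (is.null(bg_sd)) bg_sd <- mad(image)
    threshold <- bg_mean + k * bg_sd
  }
  mask <- image > threshold
  if (min_size > 0 && any(mask))
    mask <- size_filter(mask, min_size, connectivity = 8)$labels > 0
  if (!any(mask))
    return(list(n_branch_points = 0L, total_length = 0,
                n_components = 0L, skeleton = mask))
  sk <- skeletonize(mask)
  s <- sk * 1L
  nb <- function(dr, dc) {
    out <- matrix(0L, nrow(s), ncol(s))
    rs <- max(1, 1 - dr):min(nrow(s), nrow(s) - dr)
    cs <- max(1, 1 - dc):min(ncol(s), ncol(s) - dc)
    out[rs + dr, cs + dc] <- s[rs, cs]
    out
  }
  ncount <- nb(1, 0) + nb(-1, 0) + nb(0, 1) + nb(0, -1) +
    nb(1, 1) + nb(1, -1) + nb(-1, 1) + nb(-1, -1)
  branch <- sum(sk & ncount >= 3)
  straight <- sum(s[-nrow(s), ] & s[-1, ]) + sum(s[, -ncol(s)] & s[, -1])
  diag1 <- sum(s[-nrow(s), -ncol(s)] & s[-1, -1]) +
    sum(s[-1, -ncol(s)] & s[-nrow(s), -1])
  list(n_branch_points = as.integer(branch),
       total_length = straight + sqrt(2) * diag1,
       n_components = max(label_components(sk, 8)),
       skeleton = sk)
}
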