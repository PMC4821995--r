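#' Ground-truth scenes for HDR microscopy simulation
#'
#' A `scene_truth` object holds a noiseless radiance map in arbitrary linear
#' units together with the object-level ground truth needed to score every
#' downstream stage: an integer label map aligned with the radiance, a
#' centroid table, and the generation parameters. Generators are pure
#' functions of their parameters and seed: the same call is bit-identical.
#'
#' Conventions: images are (row, col) matrices, pixel centers at integer
#' coordinates, 1-based as native in R; origin at the top-left. The brightest
#' nominal object is at radiance 1.0 by default (`peak` rescales); all
#' contrasts are ratios, matching how relative intensity is reported for
#' fluorescence work.
#'
#' @param radiance nonnegative numeric matrix (or 3-D array).
#' @param labels integer matrix of object ids (0 = background), same shape.
#' @param centroids data.frame with at least columns `id`, `row`, `col`.
#' @param meta list of generation parameters (kind, seed, ...).
#' @return an object of class `scene_truth`.
#' @export
scene_truth <- function(radiance, labels, centroids, meta = list()) {
  if (any(radiance < 0)) stop("radiance must be >= 0 everywhere")
  if (!identical(dim(radiance), dim(labels)))
    stop("radiance and labels must have identical dimensions")
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (!setequal(ids, centroids$id) || anyDuplicated(centroids$id))
    stop("every positive label must appear in centroids exactly once")
  structure(list(radiance = radiance, labels = labels,
                 centroids = centroids, meta = meta),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  d <- dim(x$radiance)
  cat(sprintf("scene_truth '%s': %s px, %d objects, radiance [%g, %g]\n",
              x$meta$kind %||% "custom", paste(d, collapse = " x "),
              nrow(x$centroids), min(x$radiance), max(x$radiance)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stamp a hard (aa = FALSE) or cosine-edged (aa = TRUE, 1 px ramp) disc into
# `img` at (r0, c0); returns list(img, mask) where mask is the disc support
stamp_disc <- function(img, r0, c0, radius, level, aa = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- max(1L, floor(r0 - radius - 1)):min(nr, ceiling(r0 + radius + 1))
  cc <- max(1L, floor(c0 - radius - 1)):min(nc, ceiling(c0 + radius + 1))
  d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
  if (aa) {
    w <- ifelse(d <= radius - 0.5, 1,
                ifelse(d >= radius + 0.5, 0,
                       0.5 * (1 + cos(pi * (d - radius + 0.5)))))
  } else {
    w <- (d <= radius) * 1
  }
  img[rr, cc] <- pmax(img[rr, cc], level * w)
  mask <- matrix(FALSE, nr, nc)
  mask[rr, cc] <- w > 0
  list(img = img, mask = mask)
}

#' Multi-region fluorescence phantom
#'
#' Builds the validation phantom: non-adjacent uniform regions at the
#' requested relative concentrations over a zero-radiance background (the
#' background doubles as the dark-noise reference region). A dilution series
#' of 1:1, 1:10 and 1:100 corresponds to `levels = c(1, 0.1, 0.01)`.
#'
#' @param levels nonnegative relative concentrations, at least one > 0.
#' @param geometry `"disc"` or `"block"` regions on a regular grid.
#' @param size image side in pixels.
#' @param peak radiance of a level-1 region (arbitrary linear units).
#' @return a [scene_truth]; labels 1..length(levels) identify the regions.
#' @export
make_phantom <- function(levels, geometry = c("disc", "block"), size = 192,
                         peak = 1) {
  geometry <- match.arg(geometry)
  if (length(levels) == 0) stop("'levels' must not be empty")
  if (any(levels < 0) || !any(levels > 0))
    stop("'levels' must be nonnegative with at least one > 0")
  n <- length(levels)
  g <- ceiling(sqrt(n))
  cell <- size / g
  radius <- floor(cell * 0.3)
  if (radius < 2)
    stop(sprintf("size %d too small to place %d non-adjacent regions", size, n))
  img <- matrix(0, size, size)
  lab <- matrix(0L, size, size)
  cent <- data.frame(id = integer(), row = numeric(), col = numeric(),
                     level = numeric())
  for (i in seq_len(n)) {
    gr <- (i - 1) %/% g; gc <- (i - 1) %% g
    r0 <- (gr + 0.5) * cell; c0 <- (gc + 0.5) * cell
    if (geometry == "disc") {
      s <- stamp_disc(img, r0, c0, radius, peak * levels[i], aa = FALSE)
      img <- s$img; lab[s$mask] <- i
    } else {
      rr <- round(r0 + (-radius:radius)); cc <- round(c0 + (-radius:radius))
      img[rr, cc] <- peak * levels[i]
      lab[rr, cc] <- i
    }
    cent <- rbind(cent, data.frame(id = i, row = r0, col = c0,
                                   level = levels[i]))
  }
  scene_truth(img, lab, cent,
              meta = list(kind = "phantom", levels = levels, size = size,
                          geometry = geometry, peak = peak))
}

#' Mixed bead populations
#'
#' Emulates a slide of fluorescent microsphere populations with discrete
#' relative brightness (e.g. 0.3, 3 and 100 percent), homogeneous within a
#' population. Beads are hard discs with a 1-px cosine anti-aliased edge,
#' placed uniformly at random without overlap (bounded retries).
#'
#' @param pop_intensities relative intensities (> 0), typically in percent.
#' @param n_per_pop beads per population.
#' @param radius bead radius in pixels.
#' @param size image side in pixels.
#' @param seed integer seed.
#' @param peak radiance of the brightest population.
#' @param max_tries placement retries per bead before giving up.
#' @return a [scene_truth]; `centroids$pop` records the population index.
#' @export
make_beads <- function(pop_intensities, n_per_pop, radius = 6, size = 256,
                       seed = 1, peak = 1, max_tries = 200) {
  if (any(pop_intensities <= 0)) stop("'pop_intensities' must be > 0")
  if (n_per_pop < 0) stop("'n_per_pop' must be >= 0")
  levels <- pop_intensities / max(pop_intensities) * peak
  npop <- length(levels)
  img <- matrix(0, size, size)
  lab <- matrix(0L, size, size)
  n_total <- npop * n_per_pop
  cent <- NULL
  if (n_total > 0) with_seed(seed, {
    placed_r <- placed_c <- numeric(0)
    id <- 0L
    rows <- vector("list", n_total)
    for (p in seq_len(npop)) for (k in seq_len(n_per_pop)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- runif(1, radius + 1, size - radius)
        c0 <- runif(1, radius + 1, size - radius)
        if (!length(placed_r) ||
            min((placed_r - r0)^2 + (placed_c - c0)^2) >= (2 * radius + 1)^2) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf("could not place bead %d of %d within %d retries (placed %d)",
                     id + 1L, n_total, max_tries, id))
      id <- id + 1L
      placed_r <- c(placed_r, r0); placed_c <- c(placed_c, c0)
      s <- stamp_disc(img, r0, c0, radius, levels[p], aa = TRUE)
      img <- s$img
      lab[s$mask & lab == 0] <- id
      rows[[id]] <- data.frame(id = id, row = r0, col = c0, pop = p,
                               level = levels[p])
    }
    cent <- do.call(rbind, rows)
  })
  if (is.null(cent))
    cent <- data.frame(id = integer(), row = numeric(), col = numeric(),
                       pop = integer(), level = numeric())
  scene_truth(img, lab, cent,
              meta = list(kind = "beads", pop_intensities = pop_intensities,
                          n_per_pop = n_per_pop, radius = radius, size = size,
                          seed = seed, peak = peak))
}

#' Neuron-like scene: bright somata, dim processes
#'
#' Cell bodies are discs, much brighter than the thin curvilinear processes
#' (quadratic Bezier tubes) that connect them — the structure that makes a
#' single exposure lose either the somata (saturation) or the processes
#' (noise floor). Soma intensity may be a scalar or a (min, max) range, in
#' which case each soma draws a log-uniform intensity, emulating
#' heterogeneous expression levels.
#'
#' @param n_somata number of cell bodies.
#' @param soma_radius disc radius in pixels.
#' @param soma_intensity scalar, or length-2 range for log-uniform draws.
#' @param n_processes number of connecting tubes.
#' @param process_width tube width in pixels.
#' @param process_intensity tube radiance (<= min soma intensity).
#' @param size image side in pixels.
#' @param seed integer seed.
#' @param peak overall radiance scale.
#' @return a [scene_truth]; `centroids$type` is `"soma"` or `"process"`;
#'   `meta$process_length` and `meta$branch_points` hold the truth
#'   skeleton statistics (anchor junctions; each process joins two anchors).
#' @export
make_neuron_scene <- function(n_somata = 8, soma_radius = 8,
                              soma_intensity = 1, n_processes = 6,
                              process_width = 3, process_intensity = 0.01,
                              size = 256, seed = 1, peak = 1) {
  if (min(soma_intensity) < process_intensity || process_intensity < 0)
    stop("need soma intensity >= process intensity >= 0")
  img <- matrix(0, size, size)
  lab <- matrix(0L, size, size)
  cent <- NULL
  total_len <- 0
  with_seed(seed, {
    # somata: random placement with min separation
    pr <- pc <- numeric(0)
    for (i in seq_len(n_somata)) {
      for (try in seq_len(500)) {
        r0 <- runif(1, soma_radius + 2, size - soma_radius - 1)
        c0 <- runif(1, soma_radius + 2, size - soma_radius - 1)
        if (!length(pr) ||
            min((pr - r0)^2 + (pc - c0)^2) >= (3 * soma_radius)^2) break
        if (try == 500) stop("could not place somata; reduce n_somata or radius")
      }
      pr <- c(pr, r0); pc <- c(pc, c0)
    }
    si <- if (length(soma_intensity) == 2)
      exp(runif(n_somata, log(soma_intensity[1]), log(soma_intensity[2])))
    else rep(soma_intensity[1], n_somata)
    # processes: Bezier tubes between random soma pairs (or soma to edge)
    proc_rows <- list()
    for (j in seq_len(n_processes)) {
      a <- sample.int(max(n_somata, 1L), 1)
      if (n_somata >= 2) {
        b <- sample(setdiff(seq_len(n_somata), a), 1)
        p0 <- c(pr[a], pc[a]); p1 <- c(pr[b], pc[b])
      } else {
        p0 <- if (n_somata) c(pr[a], pc[a]) else runif(2, 2, size - 1)
        p1 <- runif(2, 2, size - 1)
      }
      ctrl <- (p0 + p1) / 2 + runif(2, -size / 6, size / 6)
      tt <- seq(0, 1, length.out = max(2, ceiling(4 * sqrt(sum((p1 - p0)^2)))))
      bez <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), ctrl) +
        outer(tt^2, p1)
      bez[, 1] <- pmin(pmax(bez[, 1], 2), size - 1)
      bez[, 2] <- pmin(pmax(bez[, 2], 2), size - 1)
      seg_len <- sum(sqrt(rowSums(diff(bez)^2)))
      total_len <- total_len + seg_len
      pid <- n_somata + j
      for (k in seq_len(nrow(bez))) {
        s <- stamp_disc(img, bez[k, 1], bez[k, 2], process_width / 2,
                        peak * process_intensity, aa = FALSE)
        img <- s$img
        lab[s$mask & lab == 0] <- pid
      }
      proc_rows[[j]] <- data.frame(id = pid, row = mean(bez[, 1]),
                                   col = mean(bez[, 2]), type = "process",
                                   level = process_intensity)
    }
    # somata stamped last so their labels win over crossing processes; hard
    # edges keep the truth's max/min positive radiance at the stated ratio
    soma_rows <- list()
    for (i in seq_len(n_somata)) {
      s <- stamp_disc(img, pr[i], pc[i], soma_radius, peak * si[i], aa = FALSE)
      img <- s$img
      lab[s$mask] <- i
      soma_rows[[i]] <- data.frame(id = i, row = pr[i], col = pc[i],
                                   type = "soma", level = si[i])
    }
    cent <- do.call(rbind, c(soma_rows, proc_rows))
  })
  if (is.null(cent))
    cent <- data.frame(id = integer(), row = numeric(), col = numeric(),
                       type = character(), level = numeric())
  scene_truth(img, lab, cent,
              meta = list(kind = "neurons", n_somata = n_somata,
                          soma_radius = soma_radius,
                          soma_intensity = soma_intensity,
                          n_processes = n_processes,
                          process_width = process_width,
                          process_intensity = process_intensity,
                          size = size, seed = seed, peak = peak,
                          process_length = total_len,
                          branch_points = if (n_processes > 0 && n_somata > 0)
                            2L * n_processes else 0L))
}

#' Bolus kinetics parameters
#'
#' Piecewise-exponential model of an intravenous bolus: the vascular
#' concentration rises as `1 - exp(-k_in * tau)` and decays as
#' `exp(-k_out * tau)` after the arrival time; the extravascular compartment
#' integrates vascular signal at the extravasation rate `k_ex` (0 for a
#' high-molecular-weight probe that stays intravascular).
#'
#' @param t0 bolus arrival time (s).
#' @param amplitude peak-scale vascular amplitude (radiance units).
#' @param k_in,k_out wash-in / wash-out rate constants (1/s).
#' @param k_ex extravasation rate (1/s).
#' @param dt frame interval (s), > 0.
#' @param n_frames number of frames, >= 1.
#' @return an object of class `kinetic_params`.
#' @export
kinetic_params <- function(t0 = 2, amplitude = 1, k_in = 1.5, k_out = 0.05,
                           k_ex = 0, dt = 0.5, n_frames = 40) {
  if (dt <= 0) stop("frame interval 'dt' must be > 0")
  if (n_frames < 1) stop("'n_frames' must be >= 1")
  if (any(c(t0, amplitude, k_in, k_out, k_ex) < 0))
    stop("rates, amplitude and t0 must be >= 0")
  structure(list(t0 = t0, amplitude = amplitude, k_in = k_in, k_out = k_out,
                 k_ex = k_ex, dt = dt, n_frames = n_frames),
            class = "kinetic_params")
}

#' Closed-form compartment curves
#'
#' @param params a [kinetic_params].
#' @param t times (s).
#' @return vascular (or tissue) radiance at the given times.
#' @export
vascular_curve <- function(params, t) {
  tau <- pmax(t - params$t0, 0)
  params$amplitude * (1 - exp(-params$k_in * tau)) * exp(-params$k_out * tau)
}

#' @rdname vascular_curve
#' @export
tissue_curve <- function(params, t) {
  tau <- pmax(t - params$t0, 0)
  a <- params$k_in; b <- params$k_out
  int_exp <- function(rate, tau)  # integral of exp(-rate s) from 0 to tau
    ifelse(rep(rate, length(tau)) > 0, (1 - exp(-rate * tau)) / max(rate, 1e-300), tau)
  params$k_ex * params$amplitude * (int_exp(b, tau) - int_exp(a + b, tau))
}

#' Time series of perfusion/extravasation scenes
#'
#' Generates one [scene_truth] per frame: a vessel compartment following the
#' vascular bolus curve and a tissue compartment accumulating leaked probe.
#' Frames before arrival are background only.
#'
#' @param params a [kinetic_params].
#' @param vessel_mask,tissue_mask logical matrices; defaults build a curved
#'   vessel band across the frame with tissue as its complement margin.
#' @param size image side (used only when masks are NULL).
#' @param seed integer seed (vessel geometry).
#' @return list of `scene_truth`, one per frame; each `meta$t` is its time.
#' @export
make_kinetic_series <- function(params, vessel_mask = NULL, tissue_mask = NULL,
                                size = 128, seed = 1) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(vessel_mask)) {
    m <- with_seed(seed, {
      cc <- matrix(rep(seq_len(size), each = size), size, size)
      rr <- matrix(seq_len(size), size, size)
      mid <- size / 2 + size / 8 * sin(2 * pi * cc / size + runif(1, 0, 2 * pi))
      abs(rr - mid) <= size / 16
    })
    vessel_mask <- m
  }
  if (is.null(tissue_mask)) tissue_mask <- !vessel_mask
  t <- (seq_len(params$n_frames) - 1) * params$dt
  cv <- vascular_curve(params, t)
  ct <- tissue_curve(params, t)
  lab <- matrix(0L, nrow(vessel_mask), ncol(vessel_mask))
  lab[vessel_mask] <- 1L; lab[tissue_mask & !vessel_mask] <- 2L
  cent <- data.frame(
    id = c(1L, 2L),
    row = c(mean(which(vessel_mask, arr.ind = TRUE)[, 1]),
            mean(which(tissue_mask & !vessel_mask, arr.ind = TRUE)[, 1])),
    col = c(mean(which(vessel_mask, arr.ind = TRUE)[, 2]),
            mean(which(tissue_mask & !vessel_mask, arr.ind = TRUE)[, 2])),
    type = c("vessel", "tissue"))
  lapply(seq_along(t), function(i) {
    img <- matrix(0, nrow(vessel_mask), ncol(vessel_mask))
    img[vessel_mask] <- cv[i]
    img[tissue_mask & !vessel_mask] <- ct[i]
    scene_truth(img, lab, cent,
                meta = list(kind = "kinetics", t = t[i], frame = i,
                            params = unclass(params), seed = seed,
                            c_vascular = cv[i], c_tissue = ct[i]))
  })
}
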