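#' Write / read an LDR stack as multi-page TIFF plus sidecar metadata
#'
#' One 16-bit TIFF page per channel, with the channel physics (od, gain,
#' offset, dark_sigma, bit_depth, exposure) and acquisition mode in a YAML
#' sidecar (`<path>.meta.yaml`). The integer round-trip is lossless.
#'
#' @param stack an `ldr_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(stack$images, function(im) im$data / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    type = "ldr_stack", mode = stack$mode,
    motion = lapply(stack$motion, as.numeric),
    channels = lapply(stack$images, function(im)
      list(od = im$config$od, gain = im$config$gain,
           offset = im$config$offset, dark_sigma = im$config$dark_sigma,
           bit_depth = im$config$bit_depth, exposure = im$config$exposure)))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' @rdname write_stack
#' @param required_fields channel metadata fields that must be present.
#' @export
read_stack <- function(path,
                       required_fields = c("od", "gain", "offset",
                                           "dark_sigma", "bit_depth",
                                           "exposure")) {
  if (!file.exists(sidecar_path(path)))
    stop("missing sidecar metadata file: ", sidecar_path(path))
  meta <- yaml::read_yaml(sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$channels))
    stop("TIFF page count does not match sidecar channel count")
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1) stop("TIFF pages have mismatched shapes")
  images <- lapply(seq_along(pages), function(i) {
    ch <- meta$channels[[i]]
    missing_f <- setdiff(required_fields, names(ch))
    if (length(missing_f))
      stop("sidecar channel ", i, " missing required fields: ",
           paste(missing_f, collapse = ", "))
    cfg <- channel_config(od = ch$od, gain = ch$gain, offset = ch$offset,
                          dark_sigma = ch$dark_sigma,
                          bit_depth = ch$bit_depth, exposure = ch$exposure)
    d <- matrix(as.integer(round(pages[[i]] * 65535)),
                nrow(pages[[i]]), ncol(pages[[i]]))
    if (max(d) > cfg$sat_level)
      stop("channel ", i, " counts exceed its declared bit depth")
    new_ldr_image(d, cfg, channel_index = i)
  })
  motion <- if (is.null(meta$motion)) rep(list(c(0, 0)), length(images))
  else lapply(meta$motion, as.numeric)
  structure(list(images = images, mode = meta$mode, motion = motion),
            class = "ldr_stack")
}

#' Write an HDR radiance image (32-bit float TIFF) with mask pages
#'
#' The radiance plane is stored as 32-bit float — never re-quantized; the
#' validity masks go to a companion 8-bit TIFF (`<path>.masks.tif`) with
#' pages all-saturated, all-noise, n_valid.
#'
#' @param hdr an `hdr_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_hdr <- function(hdr, path) {
  tiff::writeTIFF(hdr$radiance / max(hdr$radiance, 1),
                  path, bits.per.sample = 32L, reduce = FALSE)
  # store scale so radiance is recoverable from the normalized plane
  yaml::write_yaml(list(type = "hdr_image", scale = max(hdr$radiance, 1),
                        weighting = hdr$weighting, sat_frac = hdr$sat_frac,
                        noise_k = hdr$noise_k),
                   sidecar_path(path))
  tiff::writeTIFF(list(hdr$all_saturated_mask * 1,
                       hdr$all_noise_mask * 1,
                       pmin(hdr$n_valid, 255) / 255),
                  paste0(path, ".masks.tif"), bits.per.sample = 8L)
  invisible(path)
}

#' Write a ground-truth scene (float TIFF + labels + sidecar)
#'
#' @param scene a [scene_truth].
#' @param path output TIFF path; labels go to `<path>.labels.tif`.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  tiff::writeTIFF(scene$radiance / max(scene$radiance, 1), path,
                  bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(scene$labels / 65535, paste0(path, ".labels.tif"),
                  bits.per.sample = 16L)
  meta <- scene$meta
  meta$scale <- max(scene$radiance, 1)
  yaml::write_yaml(list(type = "scene_truth",
                        meta = meta[!vapply(meta, is.null, TRUE)]),
                   sidecar_path(path))
  invisible(path)
}

#' Serialize / restore a calibration as plain text
#'
#' @param calib an `hdr_calibration`.
#' @param path key/value text file path.
#' @return `path` (write) or the calibration (read).
#' @export
write_calibration <- function(calib, path) {
  yaml::write_yaml(unclass(calib), path, precision = 12L)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- yaml::read_yaml(path)
  new_calibration(alphas = as.numeric(x$alphas),
                  offsets = as.numeric(x$offsets),
                  dark_sigmas = as.numeric(x$dark_sigmas),
                  fit_rms = x$fit_rms,
                  n_pixels_used = as.integer(x$n_pixels_used),
                  reference = x$reference,
                  ref_sensitivity = x$ref_sensitivity)
}

run_config_fields <- c("scene", "channels", "mode", "calibration",
                       "weighting", "tonemap", "register", "segment",
                       "seed", "out_dir")

#' Read and validate a pipeline run configuration
#'
#' YAML with keys: `scene` (kind + generator parameters), `channels` (list
#' of channel physics), `mode`, `calibration` (`known_od` or `estimated`),
#' `weighting`, `tonemap` (method/param/clahe), `register` (logical),
#' `seed`, `out_dir`. Unknown keys are rejected by name; the file
#' round-trips losslessly.
#'
#' @param path YAML config path (or a list already in memory).
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_fields)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg$mode <- cfg$mode %||% "simultaneous"
  cfg$calibration <- cfg$calibration %||% "known_od"
  cfg$weighting <- cfg$weighting %||% "inverse_variance"
  cfg$seed <- cfg$seed %||% 1L
  cfg$out_dir <- cfg$out_dir %||% "hdrlsm_out"
  cfg$register <- isTRUE(cfg$register)
  cfg
}

build_scene_from_config <- function(sc, seed) {
  kind <- sc$kind %||% "phantom"
  sc$kind <- NULL
  switch(kind,
         phantom = do.call(make_phantom, sc),
         beads = do.call(make_beads, c(sc, list(seed = sc$seed %||% seed))),
         neurons = do.call(make_neuron_scene,
                           c(sc, list(seed = sc$seed %||% seed))),
         stop("unknown scene kind: ", kind))
}

#' Run the full simulate-calibrate-fuse-remap pipeline
#'
#' Executes the stages in order — simulate (or load) the scene, acquire the
#' LDR stack, calibrate (declared ODs or estimated from the data), register
#' if sequential and requested, fuse, tone-map — and writes every artifact
#' (LDR stack, calibration, HDR radiance + masks, rHDR PNG, region metrics
#' CSV, run log) under the configured output directory. Outputs are a pure
#' function of config + seed.
#'
#' @param config path to a YAML run config, or an equivalent list.
#' @return (invisibly) list with the in-memory `stack`, `calib`, `hdr`,
#'   `rhdr`, `scene` and the output directory.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat(sprintf("hdrlsm run, seed %d\n", as.integer(cfg$seed)), file = logf)
  t_start <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_line("stage %-10s %.2fs", name, proc.time()[["elapsed"]] - t0)
    r
  }
  scene <- stage("simulate", build_scene_from_config(cfg$scene, cfg$seed))
  configs <- lapply(cfg$channels, function(ch) do.call(channel_config, ch))
  if (length(configs) < 2)
    warning("single-channel configuration: no dynamic-range extension possible")
  if (cfg$mode == "sequential" && !cfg$register)
    warning("sequential acquisition without registration risks ghosting artifacts")
  stack <- stage("acquire",
                 acquire_stack(scene, configs, mode = cfg$mode,
                               seed = cfg$seed))
  calib <- stage("calibrate", {
    if (cfg$calibration == "known_od") calibration_from_config(configs)
    else estimate_alphas(stack)
  })
  if (cfg$mode == "sequential" && cfg$register)
    stack <- stage("register", register_sequential(stack, calib))
  hdr <- stage("fuse", fuse(stack, calib, weighting = cfg$weighting))
  tm <- cfg$tonemap %||% list()
  rhdr <- stage("tonemap", {
    r <- remap_global(hdr, method = tm$method %||% "log", param = tm$param)
    if (isTRUE(tm$clahe)) r <- equalize_local(r) else r
  })
  stage("write", {
    write_scene(scene, file.path(cfg$out_dir, "scene.tif"))
    write_stack(stack, file.path(cfg$out_dir, "ldr_stack.tif"))
    write_calibration(calib, file.path(cfg$out_dir, "calibration.yaml"))
    write_hdr(hdr, file.path(cfg$out_dir, "hdr.tif"))
    tiff::writeTIFF(rhdr$data / 255, file.path(cfg$out_dir, "rhdr.tif"),
                    bits.per.sample = 8L)
    regions <- scene$centroids
    if (nrow(regions)) {
      means <- vapply(regions$id, function(i)
        mean(hdr$radiance[scene$labels == i]), 0)
      truth <- vapply(regions$id, function(i)
        mean(scene$radiance[scene$labels == i]), 0)
      write.csv(cbind(regions, fused_mean = means, true_mean = truth),
                file.path(cfg$out_dir, "region_metrics.csv"),
                row.names = FALSE)
    }
  })
  log_line("total %.2fs", proc.time()[["elapsed"]] - t_start)
  invisible(list(scene = scene, stack = stack, calib = calib, hdr = hdr,
                 rhdr = rhdr, out_dir = cfg$out_dir))
}
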