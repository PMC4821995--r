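# shared fixtures: all built in code, nothing on disk

# default three-channel bracket used throughout (OD 0 / 0.9 / 1.8, 12-bit)
bracket3 <- function(...) default_channels(c(0, 0.9, 1.8), ...)

# a noise-free LDR image with counts = offset + alpha * x (rounded, clipped)
synthetic_ldr <- function(x, alpha, config) {
  counts <- pmin(pmax(round(config$offset + alpha * x), 0), config$sat_level)
  img <- list(data = matrix(as.integer(counts), nrow(x), ncol(x)),
              config = config, channel_index = 1L, acquired_at = 0)
  class(img) <- "ldr_image"
  img
}

# assemble an ldr_stack from bare images
as_stack <- function(images, mode = "simultaneous") {
  for (i in seq_along(images)) images[[i]]$channel_index <- i
  structure(list(images = images, mode = mode,
                 motion = rep(list(c(0, 0)), length(images))),
            class = "ldr_stack")
}

# deterministic multi-decade test image (log-uniform values)
decade_image <- function(n = 64, decades = 4, seed = 42) {
  set.seed(seed)
  matrix(10^runif(n * n, 0, decades), n, n)
}
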