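#' Global tone mapping of an HDR radiance image
#'
#' Compresses the multi-decade fused radiance into an 8-bit display image
#' with a global nonlinear map. `"log"` uses `y = log(1 + mu * x') /
#' log(1 + mu)` on the max-normalized radiance `x'` (negatives clipped to 0
#' for display); `"gamma"` uses `y = x'^gamma`. Both are strictly monotone on
#' the positive range, so pixel ordering survives up to 8-bit rounding.
#' Quantitative analysis belongs on the linear HDR image, never on the
#' remapped one; the input is not modified.
#'
#' @param hdr an `hdr_image` (or nonnegative matrix).
#' @param method `"log"` or `"gamma"`.
#' @param param `mu` (> 0, default 1000) for log; `gamma` (> 0) for gamma.
#' @return an `rhdr_image`: integer matrix `data` in 0..255 plus the mapping
#'   parameters.
#' @export
remap_global <- function(hdr, method = c("log", "gamma"), param = NULL) {
  method <- match.arg(method)
  x <- if (inherits(hdr, "hdr_image")) hdr$radiance else hdr
  x <- pmax(x, 0)
  if (is.null(param)) param <- if (method == "log") 1000 else 0.5
  if (param <= 0) stop("tone-mapping parameter must be > 0")
  mx <- max(x)
  xn <- if (mx > 0) x / mx else x
  y <- if (method == "log") log1p(param * xn) / log1p(param) else xn^param
  structure(list(data = matrix(as.integer(round_half_away(255 * y)),
                               nrow(x), ncol(x)),
                 method = method, param = param, max_radiance = mx,
                 equalized = FALSE),
            class = "rhdr_image")
}

#' @export
print.rhdr_image <- function(x, ...) {
  cat(sprintf("rhdr_image: %s px, %s map (param %g)%s\n",
              paste(dim(x$data), collapse = " x "), x$method, x$param,
              if (isTRUE(x$equalized)) ", locally equalized" else ""))
  invisible(x)
}

#' Local contrast enhancement (CLAHE)
#'
#' Contrast-limited adaptive histogram equalization over a tile grid,
#' applied to a display-referred 8-bit image when the global map leaves too
#' little local contrast. Deterministic in its inputs.
#'
#' @param rhdr an `rhdr_image` (or integer matrix in 0..255).
#' @param clip_limit contrast clip limit (larger = closer to plain
#'   equalization).
#' @param tile_grid number of tiles per axis, `c(nx, ny)` or scalar; floored
#'   at 2 per axis (the algorithm needs at least 4 contextual regions, so a
#'   coarse 2x2 grid with a large clip limit is the closest analogue of
#'   global equalization).
#' @return an `rhdr_image` with `equalized = TRUE`.
#' @export
equalize_local <- function(rhdr, clip_limit = 4, tile_grid = c(8, 8)) {
  obj <- if (inherits(rhdr, "rhdr_image")) rhdr
  else structure(list(data = rhdr, method = "none", param = NA,
                      max_radiance = NA, equalized = FALSE),
                 class = "rhdr_image")
  d <- obj$data
  if (min(d) < 0 || max(d) > 255) stop("input must be 8-bit (0..255)")
  if (length(tile_grid) == 1) tile_grid <- rep(tile_grid, 2)
  tile_grid <- pmax(tile_grid, 2)  # CLAHE needs >= 2 contextual regions/axis
  if (any(dim(d) < tile_grid))
    stop("tile grid finer than the image (tiles larger than image extent)")
  if (diff(range(d)) == 0) {  # constant image: equalization is a no-op
    obj$equalized <- TRUE
    obj$clahe <- list(clip_limit = clip_limit, tile_grid = tile_grid)
    return(obj)
  }
  eq <- EBImage::clahe(d / 255, nx = tile_grid[1], ny = tile_grid[2],
                       limit = clip_limit, keep.range = TRUE)
  obj$data <- matrix(as.integer(pmin(pmax(round_half_away(255 * eq), 0), 255)),
                     nrow(d), ncol(d))
  obj$equalized <- TRUE
  obj$clahe <- list(clip_limit = clip_limit, tile_grid = tile_grid)
  obj
}

#' Saturation / noise overlay for display
#'
#' Renders an rHDR image to RGB with the all-saturated mask painted red and
#' the all-noise mask painted blue, the conventional display coding for
#' out-of-range pixels.
#'
#' @param rhdr an `rhdr_image`.
#' @param hdr the `hdr_image` carrying the masks.
#' @return numeric array (rows x cols x 3) in 0..1.
#' @export
overlay_masks <- function(rhdr, hdr) {
  g <- rhdr$data / 255
  rgb <- array(rep(g, 3), c(dim(g), 3))
  sat <- hdr$all_saturated_mask; noi <- hdr$all_noise_mask
  r <- rgb[, , 1]; gg <- rgb[, , 2]; b <- rgb[, , 3]
  r[sat] <- 1; gg[sat] <- 0; b[sat] <- 0
  r[noi] <- 0; gg[noi] <- 0; b[noi] <- 1
  rgb[, , 1] <- r; rgb[, , 2] <- gg; rgb[, , 3] <- b
  rgb
}
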