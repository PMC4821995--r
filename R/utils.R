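#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the RNG seeded at \code{seed}, restoring the caller's
#' RNG state afterwards so library calls never perturb user randomness.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Round half away from zero (fixed quantization convention; R's round() is
# half-to-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Rigid integer/subpixel translation of an image
#'
#' Shifts by (dy, dx) in (row, col) order; vacated pixels are filled with
#' \code{fill}. Non-integer shifts use bilinear interpolation.
#'
#' @param img numeric matrix.
#' @param dy,dx shift in rows/columns; positive moves content down/right.
#' @param fill value for pixels shifted in from outside the frame.
#' @return shifted matrix of the same dimensions.
#' @export
shift_image <- function(img, dy, dx, fill = 0) {
  if (dy == 0 && dx == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  if (dy == round(dy) && dx == round(dx)) {
    out <- matrix(fill, nr, nc)
    sr <- seq_len(nr) - dy; sc <- seq_len(nc) - dx
    ok_r <- sr >= 1 & sr <= nr; ok_c <- sc >= 1 & sc <= nc
    out[ok_r, ok_c] <- img[sr[ok_r], sc[ok_c]]
    return(out)
  }
  # bilinear for subpixel shifts
  r <- matrix(seq_len(nr) - dy, nr, nc)
  c <- matrix(rep(seq_len(nc) - dx, each = nr), nr, nc)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  gv <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- matrix(fill, nr, nc)
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * gv(r0, c0) + (1 - fr) * fc * gv(r0, c0 + 1) +
    fr * (1 - fc) * gv(r0 + 1, c0) + fr * fc * gv(r0 + 1, c0 + 1)
}

# internal: coerce 2-D/3-D input to 3-D array (single-slice volumes allowed)
as_volume <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else if (length(dim(x)) == 3L) x
  else stop("expected a 2-D matrix or 3-D array")
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
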