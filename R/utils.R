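# Internal helpers shared across modules.

# Classed error so callers can condition on failure modes.
abort <- function(message, class) {
  stop(structure(
    class = c(class, "cequant_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Otsu threshold of an intensity sample
#'
#' Maximum between-class-variance threshold computed on a 256-bin histogram
#' (delegates to [EBImage::otsu()] after rescaling to `[0, 1]`). Returns the
#' threshold on the original intensity scale; pixels strictly above it are
#' foreground.
#'
#' @param x numeric vector or matrix of intensities.
#' @param levels number of histogram levels.
#' @return scalar threshold.
#' @export
threshold_otsu <- function(x, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) abort("no finite intensities to threshold", "cequant_error_degenerate")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) abort("constant-intensity input: Otsu threshold undefined", "cequant_error_degenerate")
  img <- EBImage::Image((v - lo) / (hi - lo))
  t01 <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  lo + t01 * (hi - lo)
}

# Pixel-center coordinates (micrometres) of a [ny, nx] grid.
# Row i (y) and column j (x) map to ((i - 0.5) * px, (j - 0.5) * px).
pixel_centers <- function(ny, nx, pixel_size) {
  list(
    y = (seq_len(ny) - 0.5) * pixel_size,
    x = (seq_len(nx) - 0.5) * pixel_size
  )
}

# Rasterize a (possibly rotated) ellipse: TRUE where the pixel center falls
# inside. center/semiaxes in um; angle in radians (long axis vs x).
ellipse_mask <- function(ny, nx, pixel_size, center, a, b, angle = 0) {
  pc <- pixel_centers(ny, nx, pixel_size)
  X <- matrix(pc$x, ny, nx, byrow = TRUE) - center[1]
  Y <- matrix(pc$y, ny, nx, byrow = FALSE) - center[2]
  u <- X * cos(angle) + Y * sin(angle)
  v <- -X * sin(angle) + Y * cos(angle)
  (u / a)^2 + (v / b)^2 <= 1
}

# Elliptical radial coordinate rho of points (x, y) relative to an ellipse;
# rho = 1 on the boundary, < 1 inside.
elliptical_rho <- function(x, y, center, a, b, angle = 0) {
  dx <- x - center[1]; dy <- y - center[2]
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  sqrt((u / a)^2 + (v / b)^2)
}
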