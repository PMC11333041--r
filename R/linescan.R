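# Two-channel line-scan profiles and subpixel pre/postsynaptic peak-offset
# measurement.

#' Extract an intensity profile along a line
#'
#' Samples each channel by bilinear interpolation at uniform steps along the
#' segment `p0 -> p1`, averaging over `width` perpendicular to the line.
#'
#' @param images named list of 2D matrices (or a single matrix).
#' @param p0,p1 line endpoints `c(x, y)` in um.
#' @param pixel_size um/px.
#' @param width perpendicular averaging width, um (0 = single line).
#' @param step sampling step along the line, um; default half a pixel.
#' @return list of class `line_profile`: `position` (um from `p0`),
#'   `intensity` (named list of numeric vectors), `p0`, `p1`, `width`.
#' @export
extract_profile <- function(images, p0, p1, pixel_size, width = 0,
                            step = pixel_size / 2) {
  if (is.matrix(images)) images <- list(ch1 = images)
  ny <- nrow(images[[1]]); nx <- ncol(images[[1]])
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) abort("zero-length line", "cequant_error_line")
  lim_x <- c(0, nx * pixel_size); lim_y <- c(0, ny * pixel_size)
  for (p in list(p0, p1))
    if (p[1] < lim_x[1] || p[1] > lim_x[2] || p[2] < lim_y[1] || p[2] > lim_y[2])
      abort("line endpoints outside image", "cequant_error_line")
  dirv <- (p1 - p0) / len
  perp <- c(-dirv[2], dirv[1])
  pos <- seq(0, len, by = step)
  offs <- if (width > 0) seq(-width / 2, width / 2, by = pixel_size / 2) else 0

  bilinear <- function(img, x, y) {
    fx <- x / pixel_size + 0.5; fy <- y / pixel_size + 0.5
    j0 <- pmin(pmax(floor(fx), 1), nx - 1L); i0 <- pmin(pmax(floor(fy), 1), ny - 1L)
    wx <- pmin(pmax(fx - j0, 0), 1); wy <- pmin(pmax(fy - i0, 0), 1)
    img[cbind(i0, j0)] * (1 - wx) * (1 - wy) +
      img[cbind(i0, j0 + 1L)] * wx * (1 - wy) +
      img[cbind(i0 + 1L, j0)] * (1 - wx) * wy +
      img[cbind(i0 + 1L, j0 + 1L)] * wx * wy
  }
  intensity <- lapply(images, function(img) {
    acc <- numeric(length(pos)); nacc <- 0L
    for (o in offs) {
      xs <- p0[1] + pos * dirv[1] + o * perp[1]
      ys <- p0[2] + pos * dirv[2] + o * perp[2]
      inside <- xs >= lim_x[1] & xs <= lim_x[2] & ys >= lim_y[1] & ys <= lim_y[2]
      if (!all(inside)) next
      acc <- acc + bilinear(img, xs, ys); nacc <- nacc + 1L
    }
    if (nacc == 0L) abort("averaging band falls outside image", "cequant_error_line")
    acc / nacc
  })
  structure(list(position = pos, intensity = intensity,
                 p0 = p0, p1 = p1, width = width),
            class = "line_profile")
}

#' Subpixel peak localization on a profile
#'
#' Gaussian fit (`b + A exp(-(x - mu)^2 / (2 s^2))`, Levenberg-Marquardt)
#' to the samples within `window` of the discrete maximum; falls back to
#' three-point parabolic interpolation when the fit fails. A maximum at the
#' profile boundary is flagged (`boundary = TRUE`) and should be excluded
#' from statistics.
#'
#' @param position,intensity numeric vectors (one channel).
#' @param window half-width of the fitting window, um.
#' @return list: `position` (um), `method` ("gaussian" or "parabolic"),
#'   `boundary` flag, `fit_rmse` (NA for parabolic fallback).
#' @export
locate_peak <- function(position, intensity, window = 0.3) {
  stopifnot(length(position) == length(intensity), length(position) >= 3L)
  i_max <- which.max(intensity)
  if (i_max == 1L || i_max == length(intensity))
    return(list(position = position[i_max], method = "boundary",
                boundary = TRUE, fit_rmse = NA_real_))
  sel <- abs(position - position[i_max]) <= window
  x <- position[sel]; y <- intensity[sel]
  parabolic <- function() {
    i <- i_max
    y0 <- intensity[i - 1L]; y1 <- intensity[i]; y2 <- intensity[i + 1L]
    den <- y0 - 2 * y1 + y2
    d <- if (abs(den) < 1e-300) 0 else 0.5 * (y0 - y2) / den
    d <- max(min(d, 0.5), -0.5)
    position[i] + d * (position[i + 1L] - position[i])
  }
  fit <- NULL
  if (sum(sel) >= 5L) {
    st <- list(A = max(y) - min(y), mu = position[i_max],
               s = max(window / 3, diff(range(x)) / 6), b = min(y))
    fit <- try(minpack.lm::nlsLM(
      y ~ b + A * exp(-(x - mu)^2 / (2 * s^2)),
      start = st,
      lower = c(A = 0, mu = min(x), s = 1e-4, b = -Inf),
      upper = c(A = Inf, mu = max(x), s = Inf, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (!is.null(fit) && !inherits(fit, "try-error")) {
    cf <- stats::coef(fit)
    list(position = unname(cf["mu"]), method = "gaussian", boundary = FALSE,
         fit_rmse = sqrt(mean(stats::resid(fit)^2)))
  } else {
    list(position = parabolic(), method = "parabolic", boundary = FALSE,
         fit_rmse = NA_real_)
  }
}

#' Peak-to-peak offset between two channels of a profile
#'
#' `d = position(B) - position(A)` along the line; positive means the B peak
#' lies farther from the line start. Boundary peaks propagate an exclusion
#' flag.
#'
#' @param profile a `line_profile` with >= 2 channels.
#' @param channels length-2 character (default: first two channels).
#' @param window peak-fit window, um.
#' @return list of class `peak_offset`: `offset` (signed, um),
#'   `position_a`, `position_b`, `excluded`, per-channel `method`.
#' @export
peak_offset <- function(profile, channels = NULL, window = 0.3) {
  stopifnot(inherits(profile, "line_profile"))
  channels <- channels %||% names(profile$intensity)[1:2]
  pa <- locate_peak(profile$position, profile$intensity[[channels[1]]], window)
  pb <- locate_peak(profile$position, profile$intensity[[channels[2]]], window)
  structure(list(offset = pb$position - pa$position,
                 position_a = pa$position, position_b = pb$position,
                 excluded = pa$boundary || pb$boundary,
                 method = c(a = pa$method, b = pb$method)),
            class = "peak_offset")
}

#' Group statistics of peak offsets
#'
#' Per-group mean and SEM of the offset magnitudes, one-way ANOVA across
#' groups, and Tukey HSD pairwise comparisons — the statistics used to
#' compare connexin-connexin, connexin-ZO1 and fluorophore-swapped offsets.
#'
#' @param offsets named list of numeric vectors (offset magnitudes, um), one
#'   per condition; each n >= 2.
#' @return list with `table` (per-group mean/SEM/n), `anova_F`, `anova_p`,
#'   `tukey` (matrix from [stats::TukeyHSD()]).
#' @export
offset_stats <- function(offsets) {
  if (length(offsets) < 2L) abort("need >= 2 groups", "cequant_error_input")
  if (any(vapply(offsets, length, 0L) < 2L))
    abort("each group needs n >= 2", "cequant_error_input")
  grp <- factor(rep(names(offsets), vapply(offsets, length, 0L)),
                levels = names(offsets))
  val <- unlist(offsets, use.names = FALSE)
  fit <- stats::aov(val ~ grp)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$grp
  tab <- data.frame(
    group = names(offsets),
    mean = vapply(offsets, mean, 0),
    sem = vapply(offsets, function(v) stats::sd(v) / sqrt(length(v)), 0),
    n = vapply(offsets, length, 0L))
  list(table = result_table(tab, units = c(group = "", mean = "um",
                                           sem = "um", n = "count")),
       anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       tukey = tk)
}

#' End-to-end offset measurement on rendered side-view puncta
#'
#' Convenience wrapper: render `n` flat side-view puncta at a given true
#' normal offset, line-scan each through the punctum, fit both peaks and
#' return the signed offsets (boundary-peak profiles excluded).
#'
#' @param n number of puncta.
#' @param offset_um true offset (um).
#' @param model an [imaging_model()].
#' @param channel_names length-2 character; order defines the offset sign.
#' @param window peak-fit window, um.
#' @return numeric vector of signed offsets (length <= n).
#' @export
measure_sideview_offsets <- function(n, offset_um, model = imaging_model(),
                                     channel_names = c("Cx35.5", "ZO1"),
                                     window = 0.3) {
  out <- numeric(0)
  for (i in seq_len(n)) {
    sim <- render_linescan_punctum(model, offset_um = offset_um,
                                   channel_names = channel_names)
    prof <- extract_profile(sim$stack$channels |> lapply(function(a) a[, , 1]),
                            sim$p0, sim$p1, model$pixel_size_xy,
                            width = sim$width)
    po <- peak_offset(prof, channels = channel_names, window = window)
    if (!po$excluded) out <- c(out, po$offset)
  }
  out
}
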