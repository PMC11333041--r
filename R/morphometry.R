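# Contact-outline morphometry: oval fit, diameters, areas, expansion
# factors and short/long-ratio isotropy statistics.

#' Fit the oval contact outline of a single channel
#'
#' Thresholds the image (Otsu by default), keeps the largest connected
#' component, closes it morphologically, and fits an ellipse by second
#' moments: the long/short diameters are the major/minor axis lengths of the
#' ellipse with the same second moments as the mask (`4 * sqrt(eigenvalue)`),
#' the area is the mask pixel count times the pixel area.
#'
#' @param image 2D numeric matrix (one channel, typically a max projection).
#' @param pixel_size um/px.
#' @param threshold absolute intensity threshold; `NULL` for Otsu.
#' @param close_radius_um radius of the morphological closing brush. The
#'   default (0.6 um) bridges the gaps between neighbouring gap-junction
#'   puncta so a punctate connexin channel yields one contact outline;
#'   holes are filled after closing.
#' @param view `"en-face"` or `"lateral"` (recorded, not inferred).
#' @param channel recorded source-channel name.
#' @return list with `mask` (a [roi_mask()]) and `measure` (class
#'   `contact_measure`: `L`, `S`, `area` in um / um^2, `sl_ratio`, `center`
#'   um, `angle` rad, `border_touch` flag).
#' @export
fit_contact_outline <- function(image, pixel_size, threshold = NULL,
                                close_radius_um = 0.6,
                                view = c("en-face", "lateral"),
                                channel = "") {
  view <- match.arg(view)
  if (is.null(threshold)) threshold <- threshold_otsu(image)
  fg <- image > threshold
  if (!any(fg))
    abort("no component above threshold", "cequant_error_no_component")
  brush_px <- max(1L, round(close_radius_um / pixel_size))
  kern <- EBImage::makeBrush(2L * brush_px + 1L, shape = "disc")
  # pad before closing so the brush never interacts with the image border
  pad <- brush_px + 1L
  padded <- matrix(FALSE, nrow(fg) + 2L * pad, ncol(fg) + 2L * pad)
  padded[pad + seq_len(nrow(fg)), pad + seq_len(ncol(fg))] <- fg
  closed <- EBImage::closing(padded, kern) > 0
  closed <- closed[pad + seq_len(nrow(fg)), pad + seq_len(ncol(fg))]
  lab <- EBImage::bwlabel(closed)
  tab <- tabulate(lab[lab > 0])
  biggest <- which.max(tab)
  mask <- EBImage::fillHull(lab == biggest) > 0
  border_touch <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])

  idx <- which(mask, arr.ind = TRUE)
  ybar <- mean(idx[, 1]); xbar <- mean(idx[, 2])
  dy <- idx[, 1] - ybar; dx <- idx[, 2] - xbar
  cxx <- mean(dx^2); cyy <- mean(dy^2); cxy <- mean(dx * dy)
  tr <- cxx + cyy; det <- cxx * cyy - cxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  L <- 4 * sqrt(l1) * pixel_size
  S <- 4 * sqrt(l2) * pixel_size
  angle <- 0.5 * atan2(2 * cxy, cxx - cyy)
  area <- nrow(idx) * pixel_size^2
  measure <- structure(
    list(L = L, S = S, area = area, sl_ratio = S / L,
         center = c((xbar - 0.5) * pixel_size, (ybar - 0.5) * pixel_size),
         angle = angle, view = view, channel = channel,
         border_touch = border_touch, pixel_size = pixel_size),
    class = "contact_measure")
  list(mask = roi_mask(mask, "contact-outline"), measure = measure)
}

#' Expansion factors from group means
#'
#' Linear factor = ratio of mean long diameters; areal factor = ratio of
#' mean contact areas.
#'
#' @param mean_L_expanded,mean_L_nonexpanded mean long diameters, um.
#' @param mean_A_expanded,mean_A_nonexpanded mean contact areas, um^2.
#' @return list with `linear` and `areal`.
#' @export
expansion_factor <- function(mean_L_expanded, mean_L_nonexpanded,
                             mean_A_expanded, mean_A_nonexpanded) {
  vals <- c(mean_L_expanded, mean_L_nonexpanded, mean_A_expanded, mean_A_nonexpanded)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("all inputs must be positive", "cequant_error_input")
  list(linear = mean_L_expanded / mean_L_nonexpanded,
       areal = mean_A_expanded / mean_A_nonexpanded)
}

#' Two-group comparison with normal fits
#'
#' Two-sided two-sample Student's t-test (pooled variance) plus per-group
#' maximum-likelihood normal fits (sd with denominator n) for distribution
#' plotting, mirroring the S/L-ratio isotropy analysis.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list of class `group_comparison`: per-group `mean`, `sem`, `n`,
#'   `fit` (mean, sd), plus `t`, `df`, `p_value`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    abort("each group needs n >= 2", "cequant_error_input")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    # identical constant groups carry no evidence of a difference; constant
    # groups with different means make the statistic undefined
    if (isTRUE(all.equal(mean(values_a), mean(values_b))))
      tt <- list(statistic = c(t = 0),
                 parameter = c(df = length(values_a) + length(values_b) - 2),
                 p.value = 1)
    else
      abort("zero variance in both groups: t-test undefined",
            "cequant_error_degenerate")
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  }
  grp <- function(v) list(
    mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v),
    fit = c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2))))
  structure(list(a = grp(values_a), b = grp(values_b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "group_comparison")
}
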