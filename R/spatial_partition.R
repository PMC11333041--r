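# Center/periphery partition of the contact, corrected total fluorescence
# (CTCF), normalized center-vs-periphery comparison, and labeling occupancy.

#' Partition the contact into center and periphery
#'
#' The center is the similar ellipse with both semi-axes scaled by
#' `sqrt(3/4)` (same center and orientation as the fitted contact), so its
#' continuous area is exactly 3/4 of the contact's; the periphery is the
#' remaining quarter-area annulus. On the raster, center = scaled ellipse
#' intersect contact mask and periphery = contact minus center, so the two
#' masks partition the contact exactly.
#'
#' @param mask contact [roi_mask()] (logical matrix).
#' @param measure `contact_measure` from [fit_contact_outline()].
#' @param center_fraction area fraction of the central ellipse (default 3/4).
#' @return list of class `partition_rois`: `center`, `periphery` (masks),
#'   `measure`.
#' @export
partition_center_periphery <- function(mask, measure, center_fraction = 0.75) {
  stopifnot(inherits(measure, "contact_measure"))
  if (measure$view == "lateral")
    abort("center/periphery partition requires an 'en face' contact",
          "cequant_error_lateral_view")
  mask <- mask > 0
  s <- sqrt(center_fraction)
  ell <- ellipse_mask(nrow(mask), ncol(mask), measure$pixel_size,
                      measure$center, s * measure$L / 2, s * measure$S / 2,
                      measure$angle)
  center <- mask & ell
  periphery <- mask & !center
  structure(list(center = roi_mask(center, "center"),
                 periphery = roi_mask(periphery, "periphery"),
                 measure = measure),
            class = "partition_rois")
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated density - ROI area x background mean`, the standard
#' background-corrected integrated intensity. Negative values are permitted
#' and flagged.
#'
#' @param image 2D numeric matrix.
#' @param roi logical mask to integrate over.
#' @param background_roi logical mask of a background region (disjoint from
#'   `roi`).
#' @return list of class `ctcf_value`: `integrated_density`, `area_px`,
#'   `background_mean`, `ctcf`, `negative` flag.
#' @export
ctcf <- function(image, roi, background_roi) {
  roi <- roi > 0; background_roi <- background_roi > 0
  if (!any(roi)) abort("empty ROI", "cequant_error_empty_roi")
  if (!any(background_roi)) abort("empty background ROI", "cequant_error_empty_roi")
  idens <- sum(image[roi])
  area <- sum(roi)
  bmean <- mean(image[background_roi])
  val <- idens - area * bmean
  structure(list(integrated_density = idens, area_px = area,
                 background_mean = bmean, ctcf = val, negative = val < 0),
            class = "ctcf_value")
}

#' Pick a default background ROI outside the contact
#'
#' Pixels outside the dilated contact whose intensity falls in the modal
#' decile of the out-of-contact intensity distribution.
#'
#' @param image 2D numeric matrix.
#' @param contact_mask logical contact mask.
#' @param dilate_px dilation margin around the contact, px.
#' @return a [roi_mask()] with provenance `"background"`.
#' @export
default_background_roi <- function(image, contact_mask, dilate_px = 5L) {
  kern <- EBImage::makeBrush(2L * dilate_px + 1L, "disc")
  outside <- !(EBImage::dilate(contact_mask > 0, kern) > 0)
  if (!any(outside)) abort("no out-of-contact pixels", "cequant_error_empty_roi")
  v <- image[outside]
  qs <- stats::quantile(v, seq(0, 1, 0.1))
  counts <- table(cut(v, unique(qs), include.lowest = TRUE))
  modal <- names(counts)[which.max(counts)]
  sel <- cut(v, unique(qs), include.lowest = TRUE) == modal
  m <- matrix(FALSE, nrow(image), ncol(image))
  m[outside][sel] <- TRUE
  roi_mask(m, "background")
}

#' Center-versus-periphery fluorescence comparison of two channels
#'
#' Per ROI (center, periphery) and channel, CTCF divided by the ROI pixel
#' area, then normalized to the highest channel x ROI value of the contact.
#' Across contacts, a Student's t-test compares the two channels within each
#' ROI.
#'
#' @param contacts list, one element per contact:
#'   `list(chA, chB, partition, background_roi)` where `chA`/`chB` are 2D
#'   matrices and `partition` a [partition_center_periphery()] result.
#' @param channel_names length-2 character.
#' @return list with `table` (per-contact normalized fluorescence-per-area)
#'   and `tests` (per-ROI `group_comparison`, NULL when < 2 contacts).
#' @export
center_periphery_analysis <- function(contacts, channel_names = c("Cx35.5", "GluR2")) {
  rows <- lapply(seq_along(contacts), function(i) {
    ct <- contacts[[i]]
    p <- ct$partition
    vals <- c(
      A_center = ctcf(ct$chA, p$center, ct$background_roi)$ctcf / sum(p$center),
      B_center = ctcf(ct$chB, p$center, ct$background_roi)$ctcf / sum(p$center),
      A_periphery = ctcf(ct$chA, p$periphery, ct$background_roi)$ctcf / sum(p$periphery),
      B_periphery = ctcf(ct$chB, p$periphery, ct$background_roi)$ctcf / sum(p$periphery))
    vals <- vals / max(vals)
    data.frame(contact = i, t(vals))
  })
  df <- do.call(rbind, rows)
  tests <- NULL
  if (nrow(df) >= 2L)
    tests <- list(
      center = compare_groups(df$A_center, df$B_center),
      periphery = compare_groups(df$A_periphery, df$B_periphery))
  names(df)[2:5] <- c(paste0(channel_names[1], "_center"),
                      paste0(channel_names[2], "_center"),
                      paste0(channel_names[1], "_periphery"),
                      paste0(channel_names[2], "_periphery"))
  units <- setNames(rep("", ncol(df)), names(df))
  list(table = result_table(df, units = units), tests = tests)
}

#' Labeling occupancy within an ROI
#'
#' Per channel, the labeled area fraction of the ROI (pixels above that
#' channel's threshold). With `exclusive = TRUE` every labeled pixel is
#' assigned to the single channel with the largest threshold-normalized
#' intensity (`I / t`), so the per-channel fractions plus the unlabeled
#' fraction sum to exactly 1.
#'
#' @param images named list of 2D matrices (one per channel).
#' @param roi logical mask.
#' @param thresholds named numeric, absolute per-channel thresholds; `NULL`
#'   for per-channel Otsu within the ROI.
#' @param exclusive logical, exclusive pixel assignment (default TRUE).
#' @return list of class `occupancy_result`: `fractions` (named, per
#'   channel), `unlabeled`, `thresholds`, `exclusive`, `n_roi_px`.
#' @export
occupancy <- function(images, roi, thresholds = NULL, exclusive = TRUE) {
  roi <- roi > 0
  if (!any(roi)) abort("empty ROI", "cequant_error_empty_roi")
  nms <- names(images)
  if (is.null(thresholds))
    thresholds <- vapply(images, function(im) threshold_otsu(im[roi]), 0)
  thresholds <- thresholds[nms]
  n_roi <- sum(roi)
  above <- lapply(nms, function(nm) images[[nm]][roi] > thresholds[[nm]])
  names(above) <- nms
  if (exclusive) {
    score <- vapply(nms, function(nm)
      ifelse(above[[nm]], images[[nm]][roi] / thresholds[[nm]], -Inf), numeric(n_roi))
    score <- matrix(score, nrow = n_roi)
    any_above <- Reduce(`|`, above)
    winner <- max.col(score, ties.method = "first")
    fractions <- vapply(seq_along(nms), function(j)
      sum(any_above & winner == j) / n_roi, 0)
  } else {
    fractions <- vapply(nms, function(nm) sum(above[[nm]]) / n_roi, 0)
    any_above <- Reduce(`|`, above)
  }
  names(fractions) <- nms
  structure(list(fractions = fractions,
                 unlabeled = sum(!any_above) / n_roi,
                 thresholds = unlist(thresholds), exclusive = exclusive,
                 n_roi_px = n_roi),
            class = "occupancy_result")
}
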