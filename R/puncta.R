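# Gap-junction puncta: segmentation inside the contact ROI, per-punctum
# morphometry, connexon-number estimation, and Sturges-rule histograms.

#' Segment gap-junction puncta within an ROI
#'
#' Connected components above an in-ROI threshold (Otsu by default),
#' filtered by a minimum area; optionally split touching puncta by
#' distance-map watershed. Deterministic given its inputs.
#'
#' @param image 2D numeric matrix.
#' @param roi logical mask (the contact outline).
#' @param pixel_size um/px.
#' @param threshold absolute threshold; `NULL` for Otsu computed within the ROI.
#' @param min_area_um2 minimum punctum area retained; default 0.05 um^2,
#'   just under the smallest plaque the method is expected to report.
#' @param split_touching logical; enable watershed splitting.
#' @return integer label matrix (0 = background); labels are 1..N.
#' @export
segment_puncta <- function(image, roi, pixel_size, threshold = NULL,
                           min_area_um2 = 0.05, split_touching = FALSE) {
  roi <- roi > 0
  if (!any(roi)) abort("empty ROI", "cequant_error_empty_roi")
  if (is.null(threshold)) threshold <- threshold_otsu(image[roi])
  fg <- (image > threshold) & roi
  if (!any(fg)) return(matrix(0L, nrow(image), ncol(image)))
  if (split_touching) {
    dm <- EBImage::distmap(fg)
    lab <- EBImage::watershed(dm, tolerance = 1)
  } else {
    lab <- EBImage::bwlabel(fg)
  }
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  min_px <- min_area_um2 / pixel_size^2
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  # relabel compactly, ordered by (row, col) of each component's first pixel
  out <- matrix(0L, nrow(image), ncol(image))
  if (length(keep)) {
    first <- vapply(keep, function(k) which(lab == k)[1], 0L)
    keep <- keep[order(first)]
    for (i in seq_along(keep)) out[lab == keep[i]] <- i
  }
  out
}

#' Measure segmented puncta
#'
#' Image-scale area from the pixel count, biological area by dividing out
#' the areal expansion factor, and connexon number assuming crystalline
#' packing at `connexon_density` hemichannels per square micrometre.
#'
#' @param labels integer label matrix from [segment_puncta()].
#' @param pixel_size um/px.
#' @param areal_expansion_factor unitless (> 0); image area / biological area.
#' @param connexon_density connexons per um^2 of biological plaque area.
#' @return data.frame (`punctum_record`s): `label`, `area_um2`,
#'   `centroid_x_um`, `centroid_y_um`, `biological_area_um2`, `connexons`.
#' @export
measure_puncta <- function(labels, pixel_size, areal_expansion_factor,
                           connexon_density = 12000) {
  if (areal_expansion_factor <= 0 || connexon_density <= 0)
    abort("expansion factor and connexon density must be positive",
          "cequant_error_input")
  n <- max(0L, max(labels))
  if (n == 0L)
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      biological_area_um2 = numeric(0), connexons = integer(0)))
  rows <- lapply(seq_len(n), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    area <- nrow(idx) * pixel_size^2
    bio <- area / areal_expansion_factor
    data.frame(label = k, area_um2 = area,
               centroid_x_um = (mean(idx[, 2]) - 0.5) * pixel_size,
               centroid_y_um = (mean(idx[, 1]) - 0.5) * pixel_size,
               biological_area_um2 = bio,
               connexons = as.integer(round(bio * connexon_density)))
  })
  do.call(rbind, rows)
}

#' Sturges-rule histogram
#'
#' Equal-width bins spanning `[min, max]` with bin count
#' `k = ceiling(1 + log2(n))`; counts conserve `n`.
#'
#' @param areas numeric vector (n >= 1), e.g. punctum areas in um^2.
#' @return list with `breaks`, `counts`, `k`.
#' @export
area_histogram <- function(areas) {
  n <- length(areas)
  if (n == 0L) abort("empty input", "cequant_error_input")
  k <- max(1L, as.integer(ceiling(1 + log2(n))))
  lo <- min(areas); hi <- max(areas)
  if (hi <= lo) hi <- lo + max(1e-9, abs(lo) * 1e-9)
  breaks <- seq(lo, hi, length.out = k + 1L)
  counts <- as.integer(table(cut(areas, breaks, include.lowest = TRUE)))
  list(breaks = breaks, counts = counts, k = k)
}

#' Per-contact puncta summary
#'
#' @param records data.frame from [measure_puncta()].
#' @return list of class `contact_puncta_summary`: `n`, `total_area_um2`,
#'   `total_connexons`, `histogram` (NULL when empty).
#' @export
contact_summary <- function(records) {
  n <- nrow(records)
  structure(list(
    n = n,
    total_area_um2 = if (n) sum(records$area_um2) else 0,
    total_connexons = if (n) sum(records$connexons) else 0,
    histogram = if (n) area_histogram(records$area_um2) else NULL
  ), class = "contact_puncta_summary")
}
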