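# Thresholded Manders colocalization between two channels within an ROI.

#' Per-channel threshold selection
#'
#' Independent thresholds for the two channels within the ROI. `"otsu"`
#' maximises between-class variance per channel; `"manual"` passes the user
#' values through; `"costes"` runs the Costes regression search: thresholds
#' walk down the orthogonal-regression line `B = a + b A` until the Pearson
#' correlation of the pixels below both thresholds is <= 0.
#'
#' @param imgA,imgB 2D numeric matrices, same shape.
#' @param roi logical mask.
#' @param method `"otsu"`, `"manual"` or `"costes"`.
#' @param manual numeric length-2 `c(tA, tB)` when `method = "manual"`.
#' @return numeric `c(tA, tB)`.
#' @export
select_thresholds <- function(imgA, imgB, roi, method = c("otsu", "manual", "costes"),
                              manual = NULL) {
  method <- match.arg(method)
  roi <- roi > 0
  if (!any(roi)) abort("empty ROI", "cequant_error_empty_roi")
  a <- imgA[roi]; b <- imgB[roi]
  if (method == "manual") {
    if (is.null(manual) || length(manual) != 2L)
      abort("manual method needs c(tA, tB)", "cequant_error_input")
    return(as.numeric(manual))
  }
  if (max(a) <= min(a) || max(b) <= min(b))
    abort("constant-intensity channel: thresholds undefined", "cequant_error_degenerate")
  if (method == "otsu")
    return(c(threshold_otsu(a), threshold_otsu(b)))
  # costes: total-least-squares line via principal axis of standardized data
  sda <- stats::sd(a); sdb <- stats::sd(b)
  r_ab <- stats::cor(a, b)
  slope <- sign(r_ab + 1e-300) * sdb / sda
  inter <- mean(b) - slope * mean(a)
  for (tA in sort(unique(a), decreasing = TRUE)) {
    tB <- inter + slope * tA
    below <- a <= tA & b <= tB
    if (sum(below) > 2L && stats::sd(a[below]) > 0 && stats::sd(b[below]) > 0) {
      if (stats::cor(a[below], b[below]) <= 0) return(c(tA, tB))
    }
  }
  c(min(a), inter + slope * min(a))
}

#' Thresholded Manders coefficients
#'
#' With `A'_i = A_i` when `A_i > tA` (else 0) and likewise `B'`:
#' `M1 = sum(A'_i over pixels where B'_i > 0) / sum(A'_i)` and symmetrically
#' `M2` for channel B over A, both restricted to the ROI. A zero denominator
#' flags the corresponding coefficient as undefined (`NA` + `undefined`
#' flag) rather than reporting 0.
#'
#' @param imgA,imgB 2D numeric matrices of identical shape.
#' @param roi logical mask.
#' @param tA,tB per-channel thresholds.
#' @return list of class `manders_result`: `M1`, `M2`, `tA`, `tB`,
#'   `n_roi_px`, `undefined` (logical length 2).
#' @export
manders <- function(imgA, imgB, roi, tA, tB) {
  if (!all(dim(imgA) == dim(imgB)) || !all(dim(imgA) == dim(roi)))
    abort("image/ROI shape mismatch", "cequant_error_shape")
  roi <- roi > 0
  if (!any(roi)) abort("empty ROI", "cequant_error_empty_roi")
  a <- imgA[roi]; b <- imgB[roi]
  ap <- ifelse(a > tA, a, 0)
  bp <- ifelse(b > tB, b, 0)
  sa <- sum(ap); sb <- sum(bp)
  undefined <- c(M1 = sa == 0, M2 = sb == 0)
  M1 <- if (sa > 0) sum(ap[bp > 0]) / sa else NA_real_
  M2 <- if (sb > 0) sum(bp[ap > 0]) / sb else NA_real_
  structure(list(M1 = M1, M2 = M2, tA = tA, tB = tB,
                 n_roi_px = sum(roi), undefined = undefined),
            class = "manders_result")
}

#' Batch Manders over a set of contacts
#'
#' One thresholded Manders pair per contact; undefined coefficients are
#' excluded from the appended means (with a warning).
#'
#' @param pairs list of `list(imgA, imgB, roi)` per contact.
#' @param method threshold method, see [select_thresholds()].
#' @param manual optional manual thresholds applied to every contact.
#' @return list with `table` (a [result_table()]: one row per contact) and
#'   `summary` (mean and SEM of M1 and M2).
#' @export
coloc_batch <- function(pairs, method = "otsu", manual = NULL) {
  if (length(pairs) < 1L) abort("need >= 1 contact", "cequant_error_input")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    th <- select_thresholds(p$imgA, p$imgB, p$roi, method = method, manual = manual)
    m <- manders(p$imgA, p$imgB, p$roi, th[1], th[2])
    if (any(m$undefined))
      warning(sprintf("contact %d: undefined Manders coefficient excluded from means", i))
    data.frame(contact = i, M1 = m$M1, M2 = m$M2, tA = m$tA, tB = m$tB,
               n_roi_px = m$n_roi_px)
  })
  df <- do.call(rbind, rows)
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  summary <- list(
    mean_M1 = mean(df$M1, na.rm = TRUE), sem_M1 = sem(stats::na.omit(df$M1)),
    mean_M2 = mean(df$M2, na.rm = TRUE), sem_M2 = sem(stats::na.omit(df$M2)))
  list(table = result_table(df, units = c(contact = "", M1 = "", M2 = "",
                                          tA = "au", tB = "au", n_roi_px = "px")),
       summary = summary)
}
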