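# Calibrated image containers, TIFF I/O, projections, ROI masks and result
# tables. Everything downstream consumes these.

#' Calibrated multi-channel z-stack
#'
#' Container for a multi-channel 3D intensity grid with physical pixel
#' calibration. Each channel is a numeric `[y, x, z]` array; all channels
#' share dimensions. Intensities are finite and non-negative; calibration is
#' carried in micrometres.
#'
#' @param channels named list of 3D numeric arrays `[y, x, z]` (a 2D matrix is
#'   promoted to a single-slice array).
#' @param pixel_size_xy lateral pixel size, um/px (> 0).
#' @param z_step axial step, um (> 0).
#' @param expansion_state `"non-expanded"` or `"expanded"`.
#' @param metadata free-form named list.
#' @return object of class `calibrated_stack`.
#' @export
calibrated_stack <- function(channels, pixel_size_xy, z_step,
                             expansion_state = c("expanded", "non-expanded"),
                             metadata = list()) {
  expansion_state <- match.arg(expansion_state)
  if (is.null(names(channels)) || any(names(channels) == ""))
    names(channels) <- paste0("ch", seq_along(channels))
  channels <- lapply(channels, function(ch) {
    if (length(dim(ch)) == 2L) ch <- array(ch, c(dim(ch), 1L))
    ch
  })
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    abort("all channels must share identical dimensions", "cequant_error_shape")
  if (!is.numeric(pixel_size_xy) || pixel_size_xy <= 0 ||
      !is.numeric(z_step) || z_step <= 0)
    abort("pixel_size_xy and z_step must be positive", "cequant_error_calibration")
  for (ch in channels)
    if (any(!is.finite(ch)) || any(ch < 0))
      abort("intensities must be finite and non-negative", "cequant_error_intensity")
  structure(
    list(channels = channels, pixel_size_xy = pixel_size_xy, z_step = z_step,
         expansion_state = expansion_state, metadata = metadata),
    class = "calibrated_stack"
  )
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "calibrated_stack: %d channel(s) [%s], %d x %d x %d (y,x,z), %.4g um/px, z-step %.4g um, %s\n",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    d[1], d[2], d[3], x$pixel_size_xy, x$z_step, x$expansion_state))
  invisible(x)
}

stack_dim <- function(stack) dim(stack$channels[[1]])

#' Write a calibrated stack to TIFF with a JSON sidecar
#'
#' Pages are written channel-major (all z of channel 1, then channel 2, ...)
#' as 32-bit samples scaled into `[0, 1]`; the scale factor, calibration,
#' channel names and page layout go to a `<path>.json` sidecar so a read-back
#' reproduces the stack.
#'
#' @param stack a [calibrated_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d <- stack_dim(stack)
  mx <- max(1e-12, vapply(stack$channels, max, 0))
  pages <- list()
  for (ch in stack$channels)
    for (k in seq_len(d[3]))
      pages[[length(pages) + 1L]] <- ch[, , k] / mx
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    abort(sprintf("cannot write TIFF at '%s'", path), "cequant_error_unwritable")
  sidecar <- list(
    pixel_size_xy = stack$pixel_size_xy, z_step = stack$z_step,
    expansion_state = stack$expansion_state,
    channel_names = names(stack$channels), n_z = d[3],
    intensity_scale = mx, metadata = stack$metadata
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated stack from TIFF
#'
#' Calibration precedence: explicit `calibration_override`, then the JSON
#' sidecar written by [write_stack()], then TIFF resolution tags (assumed
#' px-per-um as written by common microscopy exporters), else a classed
#' error. Without layout metadata all pages are treated as z-slices of one
#' channel.
#'
#' @param path TIFF file path.
#' @param calibration_override optional list with any of `pixel_size_xy`,
#'   `z_step`, `channel_names`, `n_channels`, `expansion_state`.
#' @return a [calibrated_stack()].
#' @export
read_stack <- function(path, calibration_override = NULL) {
  if (!file.exists(path))
    abort(sprintf("no such file: '%s'", path), "cequant_error_missing_file")
  pages <- try(tiff::readTIFF(path, all = TRUE, info = TRUE), silent = TRUE)
  if (inherits(pages, "try-error"))
    abort(sprintf("unreadable TIFF: '%s'", path), "cequant_error_unreadable")
  if (!is.list(pages)) pages <- list(pages)
  # collapse RGB pages to first plane (we only deal in single-sample pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)

  sidecar <- NULL
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path))
    sidecar <- jsonlite::read_json(sc_path, simplifyVector = TRUE)

  ov <- calibration_override %||% list()
  pixel_size_xy <- ov$pixel_size_xy %||% sidecar$pixel_size_xy
  if (is.null(pixel_size_xy)) {
    xres <- attr(pages[[1]], "x.resolution")
    if (!is.null(xres) && is.finite(xres) && xres > 0) pixel_size_xy <- 1 / xres
  }
  if (is.null(pixel_size_xy))
    abort("no pixel calibration in file and no calibration_override given",
          "cequant_error_missing_calibration")
  z_step <- ov$z_step %||% sidecar$z_step %||% 1

  scale <- sidecar$intensity_scale %||% 1
  n_pages <- length(pages)
  channel_names <- ov$channel_names %||% sidecar$channel_names
  n_channels <- ov$n_channels %||% length(channel_names %||% "ch1")
  if (n_pages %% n_channels != 0L)
    abort("page count not divisible by channel count", "cequant_error_unreadable")
  n_z <- n_pages %/% n_channels
  d <- dim(pages[[1]])
  channels <- vector("list", n_channels)
  for (c_i in seq_len(n_channels)) {
    arr <- array(0, c(d, n_z))
    for (k in seq_len(n_z)) arr[, , k] <- pages[[(c_i - 1L) * n_z + k]] * scale
    channels[[c_i]] <- arr
  }
  names(channels) <- channel_names %||% paste0("ch", seq_len(n_channels))
  calibrated_stack(
    channels, pixel_size_xy, z_step,
    expansion_state = ov$expansion_state %||% sidecar$expansion_state %||% "expanded",
    metadata = sidecar$metadata %||% list()
  )
}

#' Maximum-intensity projection
#'
#' Per pixel and per channel, the maximum over the selected z slices.
#' Calibration propagates to the returned `projected_image` (a named list of
#' 2D matrices plus `pixel_size_xy`).
#'
#' @param stack a [calibrated_stack()].
#' @param z_range inclusive `c(from, to)` slice interval; default all slices.
#' @return object of class `projected_image`.
#' @export
max_project <- function(stack, z_range = NULL) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d <- stack_dim(stack)
  z_range <- z_range %||% c(1L, d[3])
  z_range <- as.integer(z_range)
  if (length(z_range) != 2L || z_range[1] > z_range[2] ||
      z_range[1] < 1L || z_range[2] > d[3])
    abort("z_range empty or out of bounds", "cequant_error_zrange")
  zs <- z_range[1]:z_range[2]
  channels <- lapply(stack$channels, function(ch) {
    if (length(zs) == 1L) ch[, , zs] else apply(ch[, , zs, drop = FALSE], c(1, 2), max)
  })
  structure(
    list(channels = channels, pixel_size_xy = stack$pixel_size_xy,
         expansion_state = stack$expansion_state),
    class = "projected_image"
  )
}

#' Sum-intensity projection
#'
#' Per pixel and per channel, the sum over the selected z slices (the
#' "integrated density" along z). For punctum segmentation and occupancy
#' this is preferable to a maximum projection: it is insensitive to where a
#' structure sits relative to the slice grid, so faint small puncta are not
#' attenuated.
#'
#' @inheritParams max_project
#' @return object of class `projected_image`.
#' @export
sum_project <- function(stack, z_range = NULL) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d <- stack_dim(stack)
  z_range <- z_range %||% c(1L, d[3])
  z_range <- as.integer(z_range)
  if (length(z_range) != 2L || z_range[1] > z_range[2] ||
      z_range[1] < 1L || z_range[2] > d[3])
    abort("z_range empty or out of bounds", "cequant_error_zrange")
  zs <- z_range[1]:z_range[2]
  channels <- lapply(stack$channels, function(ch) {
    if (length(zs) == 1L) ch[, , zs] else apply(ch[, , zs, drop = FALSE], c(1, 2), sum)
  })
  structure(
    list(channels = channels, pixel_size_xy = stack$pixel_size_xy,
         expansion_state = stack$expansion_state),
    class = "projected_image"
  )
}

#' ROI mask
#'
#' A logical 2D mask tagged with its provenance.
#'
#' @param mask logical matrix.
#' @param provenance one of `"contact-outline"`, `"center"`, `"periphery"`,
#'   `"background"`, `"punctum"`, `"manual"`.
#' @export
roi_mask <- function(mask, provenance = "manual") {
  provenance <- match.arg(provenance, c("contact-outline", "center", "periphery",
                                        "background", "punctum", "manual"))
  mask <- mask > 0
  if (!any(mask)) abort("ROI mask is empty", "cequant_error_empty_roi")
  structure(mask, provenance = provenance, class = c("roi_mask", "matrix", "array"))
}

#' Result table with unit annotations
#'
#' A thin wrapper around `data.frame` that records a unit per column and
#' writes/reads CSV with unit-suffixed headers (`name.unit`), so values
#' round-trip at full precision.
#'
#' @param df data.frame, one row per measured object.
#' @param units named character vector, unit per numeric column ("" allowed).
#' @export
result_table <- function(df, units = NULL) {
  stopifnot(is.data.frame(df))
  units <- units %||% setNames(rep("", ncol(df)), names(df))
  missing <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], names(units))
  if (length(missing))
    abort(paste("numeric columns without units:", paste(missing, collapse = ", ")),
          "cequant_error_units")
  structure(df, units = units, class = c("result_table", "data.frame"))
}

#' @rdname result_table
#' @param table a `result_table`.
#' @param path CSV output path.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "result_table"))
  units <- attr(table, "units")
  df <- as.data.frame(table)
  hdr <- vapply(names(df), function(nm) {
    u <- units[[nm]] %||% ""
    if (nzchar(u)) paste0(nm, ".", u) else nm
  }, "")
  out <- df
  names(out) <- hdr
  ok <- try(utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                             path, row.names = FALSE, quote = TRUE), silent = TRUE)
  if (inherits(ok, "try-error"))
    abort(sprintf("cannot write table at '%s'", path), "cequant_error_unwritable")
  invisible(path)
}

#' @rdname result_table
#' @export
read_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nms <- names(df)
  units <- setNames(rep("", length(nms)), nms)
  for (i in seq_along(nms)) {
    parts <- strsplit(nms[i], ".", fixed = TRUE)[[1]]
    if (length(parts) > 1L) {
      base <- parts[1]
      units[i] <- paste(parts[-1], collapse = ".")
      names(units)[i] <- base
      nms[i] <- base
    }
  }
  names(df) <- nms
  result_table(df, units = units)
}
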