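# Imaging model and rasterization: ground-truth marker masks -> blurred,
# noisy calibrated stacks with every generator answer recorded.

#' Imaging model
#'
#' Gaussian point-spread function plus Poisson shot noise and Gaussian read
#' noise. PSF defaults come from the confocal resolution of the source
#' system: lateral FWHM 0.28 um and axial FWHM 0.49 um (sigma = FWHM/2.355).
#' Offsets are the normal displacements of postsynaptic markers relative to
#' the presynaptic connexin, in image-scale (post-expansion) micrometres.
#'
#' @param psf_sigma_lateral um, lateral PSF sigma.
#' @param psf_sigma_axial um, axial PSF sigma.
#' @param pixel_size_xy um/px.
#' @param z_step um.
#' @param photon_scale expected photon count at unit label density.
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param background expected background photon count.
#' @param offset_cx um, connexin-connexin normal offset (postsynaptic Cx34.1).
#' @param offset_zo1 um, connexin-ZO1 normal offset.
#' @export
imaging_model <- function(psf_sigma_lateral = 0.28 / 2.355,
                          psf_sigma_axial = 0.49 / 2.355,
                          pixel_size_xy = 0.08,
                          z_step = 0.4,
                          photon_scale = 500,
                          read_noise_sd = 3,
                          background = 10,
                          offset_cx = 0.03,
                          offset_zo1 = 0.21) {
  if (psf_sigma_lateral <= 0 || psf_sigma_axial <= 0 || pixel_size_xy <= 0 ||
      z_step <= 0 || photon_scale <= 0)
    abort("sigmas, pixel sizes and photon scale must be positive",
          "cequant_error_model")
  if (offset_cx < 0 || offset_zo1 < 0)
    abort("offsets must be non-negative", "cequant_error_model")
  structure(list(psf_sigma_lateral = psf_sigma_lateral,
                 psf_sigma_axial = psf_sigma_axial,
                 pixel_size_xy = pixel_size_xy, z_step = z_step,
                 photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 background = background,
                 offset_cx = offset_cx, offset_zo1 = offset_zo1),
            class = "imaging_model")
}

# Per-pixel classification of the contact plane into gap junction, guard
# margin, receptor patch and adherens mesh. Works on the post-expansion
# scene; returns logical masks plus the occupancy fractions of the contact.
classify_scene <- function(scene, pixel_size, margin_um = 1.0) {
  g <- scene$geometry
  half_w <- g$a + margin_um
  half_h <- g$a + margin_um   # square-ish field; contact may be rotated
  nx <- as.integer(ceiling(2 * half_w / pixel_size))
  ny <- as.integer(ceiling(2 * half_h / pixel_size))
  x0 <- -nx * pixel_size / 2; y0 <- -ny * pixel_size / 2
  xs <- x0 + (seq_len(nx) - 0.5) * pixel_size
  ys <- y0 + (seq_len(ny) - 0.5) * pixel_size
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx, byrow = FALSE)

  rho <- elliptical_rho(X, Y, c(0, 0), g$a, g$b, g$angle)
  contact <- rho <= 1

  pu <- scene$puncta
  rl <- pu$radius_long %||% pu$radius
  rs <- pu$radius_short %||% pu$radius
  margin <- matrix(Inf, ny, nx)
  for (i in seq_len(nrow(pu))) {
    dx <- X - pu$x[i]; dy <- Y - pu$y[i]
    u <- dx * cos(g$angle) + dy * sin(g$angle)
    v <- -dx * sin(g$angle) + dy * cos(g$angle)
    reff <- sqrt(rl[i] * rs[i])
    m_i <- (sqrt((u / rl[i])^2 + (v / rs[i])^2) - 1) * reff
    margin <- pmin(margin, m_i)
  }
  guard_um <- scene$config$guard_band_post
  if (scene$expansion_state == "pre")
    guard_um <- guard_um / scene$config$expansion_factor
  gj <- contact & margin <= 0
  guard <- contact & margin > 0 & margin <= guard_um

  disk_union <- function(df) {
    rl <- df$radius_long %||% df$radius
    rs <- df$radius_short %||% df$radius
    inside <- matrix(FALSE, ny, nx)
    for (i in seq_len(nrow(df))) {
      dx <- X - df$x[i]; dy <- Y - df$y[i]
      u <- dx * cos(g$angle) + dy * sin(g$angle)
      v <- -dx * sin(g$angle) + dy * cos(g$angle)
      inside <- inside | (sqrt((u / rl[i])^2 + (v / rs[i])^2) <= 1)
    }
    inside
  }
  glur2 <- contact & disk_union(scene$glur2) & !gj & !guard
  dark <- contact & disk_union(scene$dark) & !gj & !guard & !glur2
  aj <- contact & !gj & !guard & !glur2 & !dark

  n_contact <- sum(contact)
  list(contact = contact, gj = gj, aj = aj, glur2 = glur2,
       guard = guard | dark, rho = rho, X = X, Y = Y, origin = c(x0, y0),
       pixel_size = pixel_size,
       occupancy = c(gj = sum(gj) / n_contact, aj = sum(aj) / n_contact,
                     glur2 = sum(glur2) / n_contact,
                     unlabeled = (sum(guard) + sum(dark)) / n_contact))
}

# Trilinear splat of a 2D density at per-pixel (x, y, z) positions into a
# [ny, nx, nz] grid. Positions in um relative to the grid origin.
splat3d <- function(density, xpos, ypos, zpos, ny, nx, nz,
                    pixel_size, z_step, z0) {
  sel <- which(density > 0)
  if (length(sel) == 0L) return(array(0, c(ny, nx, nz)))
  d <- density[sel]
  fx <- xpos[sel] / pixel_size + 0.5   # fractional pixel index
  fy <- ypos[sel] / pixel_size + 0.5
  fz <- (zpos[sel] - z0) / z_step + 0.5
  acc <- array(0, c(ny, nx, nz))
  ix0 <- floor(fx); iy0 <- floor(fy); iz0 <- floor(fz)
  wx1 <- fx - ix0; wy1 <- fy - iy0; wz1 <- fz - iz0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- iy0 + dy; jj <- ix0 + dx; kk <- iz0 + dz
    w <- (if (dx) wx1 else 1 - wx1) * (if (dy) wy1 else 1 - wy1) *
         (if (dz) wz1 else 1 - wz1) * d
    ok <- ii >= 1L & ii <= ny & jj >= 1L & jj <= nx & kk >= 1L & kk <= nz & w > 0
    if (!any(ok)) next
    lin <- (kk[ok] - 1L) * (ny * nx) + (jj[ok] - 1L) * ny + ii[ok]
    s <- rowsum(w[ok], lin)
    idx <- as.integer(rownames(s))
    acc[idx] <- acc[idx] + s[, 1]
  }
  acc
}

blur_stack <- function(arr, sigma_lat_px, sigma_ax_slices) {
  nz <- dim(arr)[3]
  if (sigma_lat_px > 0.05)
    for (k in seq_len(nz))
      arr[, , k] <- EBImage::gblur(arr[, , k], sigma = sigma_lat_px,
                                   boundary = 0)
  if (sigma_ax_slices > 0.05 && nz > 1L) {
    half <- max(1L, ceiling(3 * sigma_ax_slices))
    w <- stats::dnorm(-half:half, sd = sigma_ax_slices)
    w <- w / sum(w)
    out <- array(0, dim(arr))
    for (k in seq_len(nz)) {
      for (j in -half:half) {
        src <- k + j
        if (src >= 1L && src <= nz)
          out[, , k] <- out[, , k] + w[j + half + 1L] * arr[, , src]
      }
    }
    arr <- out
  }
  arr
}

#' Render a scene through the imaging model
#'
#' Rasterizes each marker mask onto the voxel grid at its surface height
#' (the contact surface is the paraboloid cap `z = c * rho^2`), displaces
#' postsynaptic markers along the local surface normal by their configured
#' offset, convolves with the anisotropic Gaussian PSF, and draws
#' `Poisson(photon_scale * density + background) + N(0, read_noise_sd)`
#' intensities clipped at zero.
#'
#' @param scene a (typically expanded) `contact_scene`.
#' @param model an [imaging_model()].
#' @param channels character subset of
#'   `c("Cx35.5", "Cx34.1", "ZO1", "GluR2", "NCad")`.
#' @param noise logical; `FALSE` returns the noiseless expectation.
#' @param seed optional RNG seed.
#' @return a [calibrated_stack()]; the ground truth (masks, occupancies,
#'   grid origin, scene truth) is attached as `metadata$truth`.
#' @export
render <- function(scene, model = imaging_model(),
                   channels = c("Cx35.5", "GluR2", "NCad"),
                   noise = TRUE, seed = NULL) {
  stopifnot(inherits(scene, "contact_scene"), inherits(model, "imaging_model"))
  if (!is.null(seed)) set.seed(seed)
  px <- model$pixel_size_xy
  cls <- classify_scene(scene, px, margin_um = 4 * model$psf_sigma_lateral + 0.6)
  ny <- nrow(cls$contact); nx <- ncol(cls$contact)
  g <- scene$geometry

  # surface height and unit normal of z = c * rho^2
  cdep <- g$concavity
  zsurf <- cdep * cls$rho^2
  u <- cls$X * cos(g$angle) + cls$Y * sin(g$angle)
  v <- -cls$X * sin(g$angle) + cls$Y * cos(g$angle)
  dzdu <- 2 * cdep * u / g$a^2
  dzdv <- 2 * cdep * v / g$b^2
  dzdx <- dzdu * cos(g$angle) - dzdv * sin(g$angle)
  dzdy <- dzdu * sin(g$angle) + dzdv * cos(g$angle)
  nrm <- sqrt(1 + dzdx^2 + dzdy^2)
  n_x <- -dzdx / nrm; n_y <- -dzdy / nrm; n_z <- 1 / nrm

  zmax <- cdep + max(model$offset_cx, model$offset_zo1)
  zpad <- 3 * model$psf_sigma_axial + model$z_step
  z0 <- -zpad
  nz <- max(1L, as.integer(ceiling((zmax + 2 * zpad) / model$z_step)))

  marker_offsets <- c("Cx35.5" = 0, "Cx34.1" = model$offset_cx,
                      "ZO1" = model$offset_zo1, "GluR2" = 0, "NCad" = 0)
  marker_masks <- list("Cx35.5" = cls$gj, "Cx34.1" = cls$gj, "ZO1" = cls$gj,
                       "GluR2" = cls$glur2, "NCad" = cls$aj)
  channels <- match.arg(channels, names(marker_masks), several.ok = TRUE)

  out <- list()
  for (ch in channels) {
    d <- marker_offsets[[ch]]
    dens <- marker_masks[[ch]] * 1.0
    xo <- cls$X - cls$origin[1] + d * n_x
    yo <- cls$Y - cls$origin[2] + d * n_y
    zo <- zsurf + d * n_z
    vol <- splat3d(dens, xo, yo, zo, ny, nx, nz, px, model$z_step, z0)
    vol <- blur_stack(vol, model$psf_sigma_lateral / px,
                      model$psf_sigma_axial / model$z_step)
    expected <- model$photon_scale * vol + model$background
    if (noise) {
      img <- stats::rpois(length(expected), expected) +
        stats::rnorm(length(expected), 0, model$read_noise_sd)
      img <- pmax(img, 0)
    } else img <- expected
    out[[ch]] <- array(img, c(ny, nx, nz))
  }

  truth <- scene$truth
  truth$masks <- list(contact = cls$contact, gj = cls$gj, aj = cls$aj,
                      glur2 = cls$glur2, unlabeled = cls$guard)
  truth$occupancy <- cls$occupancy
  truth$origin <- cls$origin
  truth$pixel_size <- px
  truth$offsets <- c(cx = model$offset_cx, zo1 = model$offset_zo1)
  calibrated_stack(out, px, model$z_step,
                   expansion_state = if (scene$expansion_state == "post")
                     "expanded" else "non-expanded",
                   metadata = list(truth = truth))
}

#' Render a flat side-view punctum for line-scan analysis
#'
#' The contact membrane seen edge-on: channel A is a thin vertical segment
#' (the presynaptic connexin hemiplaque cross-section), channel B the same
#' segment displaced by `offset_um` along the membrane normal (here the x
#' axis), both blurred by the lateral PSF with Poisson + read noise. This is
#' the geometry used to measure pre/postsynaptic peak offsets at the contact
#' periphery.
#'
#' @param model an [imaging_model()].
#' @param offset_um true normal offset of channel B (um, image scale).
#' @param channel_names length-2 character.
#' @param punctum_radius_um half-length of the membrane segment.
#' @param noise logical.
#' @param seed optional RNG seed.
#' @return list with `stack` (2-channel, 1-slice [calibrated_stack()]),
#'   `p0`, `p1` (line-scan endpoints, um), `width` (suggested averaging
#'   width, um) and `true_offset`.
#' @export
render_linescan_punctum <- function(model = imaging_model(), offset_um = model$offset_zo1,
                                    channel_names = c("Cx35.5", "ZO1"),
                                    punctum_radius_um = 0.35,
                                    noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  px <- model$pixel_size_xy
  w_um <- 3.0; h_um <- 2 * punctum_radius_um + 1.2
  nx <- as.integer(ceiling(w_um / px)); ny <- as.integer(ceiling(h_um / px))
  xc <- nx * px / 2; yc <- ny * px / 2
  xs <- (seq_len(nx) - 0.5) * px; ys <- (seq_len(ny) - 0.5) * px

  membrane <- function(x_at) {
    dens <- matrix(0, ny, nx)
    j <- x_at / px + 0.5
    j0 <- floor(j); f <- j - j0       # split the line across two columns
    rows <- which(abs(ys - yc) <= punctum_radius_um)
    if (j0 >= 1 && j0 <= nx) dens[rows, j0] <- dens[rows, j0] + (1 - f)
    if (j0 + 1 >= 1 && j0 + 1 <= nx) dens[rows, j0 + 1] <- dens[rows, j0 + 1] + f
    dens
  }
  mk <- function(dens) {
    b <- EBImage::gblur(dens, sigma = model$psf_sigma_lateral / px, boundary = 0)
    expected <- model$photon_scale * b + model$background
    if (noise) {
      img <- stats::rpois(length(expected), expected) +
        stats::rnorm(length(expected), 0, model$read_noise_sd)
      matrix(pmax(img, 0), ny, nx)
    } else matrix(expected, ny, nx)
  }
  chans <- list(mk(membrane(xc)), mk(membrane(xc + offset_um)))
  names(chans) <- channel_names
  stack <- calibrated_stack(chans, px, model$z_step)
  list(stack = stack,
       p0 = c(0.3, yc), p1 = c(w_um - 0.3, yc),
       width = punctum_radius_um, true_offset = offset_um)
}

#' Generate a deterministic synthetic dataset
#'
#' Samples, expands and renders `n_scenes` contacts under one seeded RNG
#' stream. Optionally writes each stack (TIFF + sidecar), a per-scene ground
#' truth CSV and a manifest CSV linking them.
#'
#' @param config generator configuration ([contact_config()]).
#' @param n_scenes number of scenes (>= 1).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param transform an [expansion_transform()].
#' @param model an [imaging_model()].
#' @param channels channels to render.
#' @param dir optional output directory.
#' @param noise logical.
#' @return list with `scenes` (list of `list(stack, truth)`) and `manifest`
#'   (data.frame).
#' @export
generate_dataset <- function(config = contact_config(), n_scenes = 10L, seed = 1L,
                             transform = expansion_transform(),
                             model = imaging_model(),
                             channels = c("Cx35.5", "GluR2", "NCad"),
                             dir = NULL, noise = TRUE) {
  if (n_scenes < 1L) abort("n_scenes must be >= 1", "cequant_error_config")
  set.seed(seed)
  scenes <- vector("list", n_scenes)
  rows <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sc <- sample_contact(config)
    sc <- apply_expansion(sc, transform)
    st <- render(sc, model, channels = channels, noise = noise)
    tr <- st$metadata$truth
    path <- NA_character_
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      path <- file.path(dir, sprintf("scene_%03d.tif", i))
      write_stack(st, path)
      gt <- result_table(
        data.frame(punctum = seq_along(tr$punctum_areas_post),
                   area = tr$punctum_areas_post),
        units = c(punctum = "", area = "um2"))
      write_table(gt, file.path(dir, sprintf("scene_%03d_truth.csv", i)))
    }
    scenes[[i]] <- list(stack = st, truth = tr)
    rows[[i]] <- data.frame(
      scene = i, path = path, seed = seed,
      n_puncta = tr$n_puncta,
      contact_area = tr$contact_area_post %||% tr$contact_area,
      sl_ratio = tr$sl_ratio,
      occupancy_gj = tr$occupancy[["gj"]], occupancy_aj = tr$occupancy[["aj"]],
      occupancy_glur2 = tr$occupancy[["glur2"]],
      occupancy_unlabeled = tr$occupancy[["unlabeled"]])
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    mt <- result_table(manifest, units = c(
      scene = "", path = "", seed = "", n_puncta = "count",
      contact_area = "um2", sl_ratio = "", occupancy_gj = "", occupancy_aj = "",
      occupancy_glur2 = "", occupancy_unlabeled = ""))
    write_table(mt, file.path(dir, "manifest.csv"))
  }
  list(scenes = scenes, manifest = manifest)
}
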