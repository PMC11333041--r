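# Ground-truth scene generation: contact geometry, gap-junction puncta
# layout, adherens-junction mesh, glutamate-receptor patches, and the
# expansion transform. All sampling happens in pre-expansion (biological)
# coordinates; the defaults are calibrated to the published club-ending
# morphometry (see the methods vignette).

#' Default generator configuration
#'
#' Study-condition defaults for the synthetic club-ending contact.
#' Diameters are pre-expansion micrometres; punctum areas and patch radii are
#' quoted post-expansion (image scale at the default 3.9x expansion) because
#' that is the scale on which they were measured, and converted internally.
#'
#' Fields:
#' * `long_diameter_mean/sd` (um): pre-expansion long diameter, 2.11 +- 0.228.
#' * `sl_ratio_mean/sd`: short/long diameter ratio, 0.77 +- 0.111,
#'   truncated to `[0.40, 0.98]`.
#' * `concavity_post` (um): paraboloid cap depth at the rim, post-expansion.
#' * `puncta_count_mean/sd`: 36.73 +- 4.27, rounded, truncated at >= 5.
#' * `area_meanlog/sdlog` (log um^2, post-expansion): log-normal punctum-area
#'   law, clipped to `area_range_post`.
#' * `min_edge_gap_post` (um): minimum edge-to-edge gap between puncta.
#' * `guard_band_post` (um): optional unlabeled membrane margin around each
#'   punctum (default 0; sub-resolution margins are not optically
#'   recoverable).
#' * `glur2_n_range`, `glur2_radius_range_post` (um): peripheral
#'   glutamate-receptor patches.
#' * `unlabeled_n_range`, `unlabeled_radius_range_post` (um): dark membrane
#'   patches carrying the unlabeled fraction of the contact; gap-junction
#'   placement avoids them.
#' * `expansion_factor`, `anisotropy_ratio`: the reference expansion used to
#'   convert the post-expansion calibrations above into biological scale.
#'
#' @return named list of parameters.
#' @export
contact_config <- function() {
  list(
    long_diameter_mean = 2.11, long_diameter_sd = 0.228,
    sl_ratio_mean = 0.77, sl_ratio_sd = 0.111,
    sl_ratio_range = c(0.40, 0.98),
    concavity_post = 1.0,
    puncta_count_mean = 36.73, puncta_count_sd = 4.27, puncta_count_min = 5L,
    area_meanlog = -1.204, area_sdlog = 0.68,
    area_range_post = c(0.06, 1.99),
    min_edge_gap_post = 0.15,
    guard_band_post = 0,
    glur2_n_range = c(12L, 18L),
    glur2_radius_range_post = c(0.3, 0.55),
    unlabeled_n_range = c(3L, 5L),
    unlabeled_radius_range_post = c(0.3, 0.5),
    expansion_factor = 3.9, anisotropy_ratio = 1.0,
    max_place_attempts = 8000L
  )
}

#' Expansion transform
#'
#' Linear scale `k` along the contact long axis and `k * r` along the short
#' axis; `r = 1` is isotropic expansion, in which every area scales by `k^2`.
#'
#' @param k linear expansion factor (> 0), default 3.9.
#' @param r anisotropy ratio (> 0), default 1.
#' @export
expansion_transform <- function(k = 3.9, r = 1.0) {
  if (k <= 0 || r <= 0) abort("k and r must be positive", "cequant_error_transform")
  structure(list(k = k, r = r), class = "expansion_transform")
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Sample a ground-truth contact scene
#'
#' Draws the contact ellipse, the gap-junction puncta (count and per-punctum
#' area from the configured laws, placed disjointly by largest-first
#' rejection sampling), the peripheral glutamate-receptor patches (centroids
#' confined to the outer quarter-area annulus), and records every draw in the
#' ground truth. The adherens-junction region is everything inside the
#' contact that is neither a punctum, a receptor patch, nor the guard margin
#' around a punctum; it is materialised at raster time by [render()].
#'
#' @param config list from [contact_config()] (entries may be overridden).
#' @param seed optional integer seed (sets the session RNG).
#' @return object of class `contact_scene` with elements `geometry`,
#'   `puncta` (x, y in um on the contact plane; radius um), `glur2`,
#'   `truth`, `expansion_state = "pre"`, and `config`.
#' @export
sample_contact <- function(config = contact_config(), seed = NULL) {
  cfg <- utils::modifyList(contact_config(), config)
  if (!is.null(seed)) set.seed(seed)
  k0 <- cfg$expansion_factor          # calibration scale for post-quoted values

  angle <- stats::runif(1, 0, pi)
  concavity <- cfg$concavity_post / k0

  rot_xy <- function(u, v) list(x = u * cos(angle) - v * sin(angle),
                                y = u * sin(angle) + v * cos(angle))

  # puncta count and per-punctum areas first: the contact must be large
  # enough to hold its (disjoint) plaques, so its size is redrawn while the
  # packing is infeasible (count and area marginals stay untouched)
  n <- max(cfg$puncta_count_min,
           as.integer(round(stats::rnorm(1, cfg$puncta_count_mean, cfg$puncta_count_sd))))
  areas_post <- pmin(pmax(stats::rlnorm(n, cfg$area_meanlog, cfg$area_sdlog),
                          cfg$area_range_post[1]), cfg$area_range_post[2])
  radii <- sqrt(areas_post / pi) / k0          # pre-expansion radii
  gap <- cfg$min_edge_gap_post / k0
  eff_total <- sum(pi * (radii + gap / 2)^2)
  for (redraw in 1:200) {
    L <- rtrunc_norm(1, cfg$long_diameter_mean, cfg$long_diameter_sd, lo = 0.8)
    sl <- rtrunc_norm(1, cfg$sl_ratio_mean, cfg$sl_ratio_sd,
                      cfg$sl_ratio_range[1], cfg$sl_ratio_range[2])
    a <- L / 2; b <- a * sl
    if (eff_total <= 0.52 * pi * a * b) break
  }

  # glutamate-receptor patches: centroid uniform-in-area over the peripheral
  # quarter annulus (rho > sqrt(3)/2), drawn before gap-junction placement
  # so it can avoid them
  ng <- sample(cfg$glur2_n_range[1]:cfg$glur2_n_range[2], 1)
  grad <- stats::runif(ng, cfg$glur2_radius_range_post[1],
                       cfg$glur2_radius_range_post[2]) / k0
  grho <- sqrt(stats::runif(ng, 0.75, 1))
  gth <- stats::runif(ng, 0, 2 * pi)
  gp <- rot_xy(a * grho * cos(gth), b * grho * sin(gth))
  gx <- gp$x; gy <- gp$y

  # dark membrane patches: the unlabeled fraction of the contact, fully inside
  nd <- sample(cfg$unlabeled_n_range[1]:cfg$unlabeled_n_range[2], 1)
  drad <- stats::runif(nd, cfg$unlabeled_radius_range_post[1],
                       cfg$unlabeled_radius_range_post[2]) / k0
  dx <- dy <- numeric(nd)
  for (i in seq_len(nd)) {
    aa <- max(a - drad[i], 1e-6); bb <- max(b - drad[i], 1e-6)
    rho <- sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
    p <- rot_xy(aa * rho * cos(th), bb * rho * sin(th))
    dx[i] <- p$x; dy[i] <- p$y
  }

  ord <- order(radii, decreasing = TRUE)
  radii <- radii[ord]; areas_post <- areas_post[ord]
  px <- py <- numeric(n)
  # Placement relaxation ladder for dense draws: (1) all constraints,
  # (2) drop receptor-patch avoidance (carved at mask level instead),
  # (3) drop the inter-punctum gap (disjointness always kept),
  # (4) shrink the stuck punctum by 10% and retry (at most 5 times).
  soft1 <- ceiling(0.5 * cfg$max_place_attempts)
  soft2 <- ceiling(0.8 * cfg$max_place_attempts)
  for (i in seq_len(n)) {
    placed <- FALSE
    shrinks <- 0L
    repeat {
      for (att in seq_len(cfg$max_place_attempts)) {
        aa <- max(a - radii[i], 1e-6); bb <- max(b - radii[i], 1e-6)
        rho <- sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
        p <- rot_xy(aa * rho * cos(th), bb * rho * sin(th))
        x <- p$x; y <- p$y
        g_i <- if (att <= soft2) gap else 0
        if (i > 1L) {
          dd <- sqrt((px[seq_len(i - 1L)] - x)^2 + (py[seq_len(i - 1L)] - y)^2)
          if (any(dd < radii[seq_len(i - 1L)] + radii[i] + g_i)) next
        }
        if (nd > 0L &&
            any(sqrt((dx - x)^2 + (dy - y)^2) < drad + radii[i])) next
        if (att <= soft1 && ng > 0L &&
            any(sqrt((gx - x)^2 + (gy - y)^2) < grad + radii[i])) next
        px[i] <- x; py[i] <- y; placed <- TRUE; break
      }
      if (placed || shrinks >= 5L) break
      shrinks <- shrinks + 1L
      radii[i] <- radii[i] * 0.9
      areas_post[i] <- pi * (radii[i] * k0)^2
    }
    if (!placed)
      abort(sprintf("could not place punctum %d of %d: configuration too dense", i, n),
            "cequant_error_placement")
  }

  geometry <- list(center = c(0, 0, 0), a = a, b = b, angle = angle,
                   concavity = concavity)
  truth <- list(
    n_puncta = n,
    punctum_areas_post = areas_post,
    punctum_areas = pi * radii^2,
    long_diameter = 2 * a, short_diameter = 2 * b, sl_ratio = sl,
    contact_area = pi * a * b,
    glur2_rho = grho
  )
  structure(
    list(geometry = geometry,
         puncta = data.frame(x = px, y = py, radius = radii),
         glur2 = data.frame(x = gx, y = gy, radius = grad),
         dark = data.frame(x = dx, y = dy, radius = drad),
         truth = truth, expansion_state = "pre", config = cfg),
    class = "contact_scene"
  )
}

#' Apply the expansion transform to a scene
#'
#' Scales all in-plane coordinates by `k` along the contact long axis and
#' `k * r` along the short axis, and the concavity depth by `k`. With
#' `r = 1` every radius scales by `k` and every area by exactly `k^2`; with
#' `r != 1` circular puncta become ellipses, represented by per-axis radii.
#'
#' @param scene a `contact_scene` in pre-expansion coordinates.
#' @param transform an [expansion_transform()].
#' @return the expanded scene (`expansion_state = "post"`), ground truth
#'   augmented with post-expansion diameters and areas.
#' @export
apply_expansion <- function(scene, transform = expansion_transform()) {
  stopifnot(inherits(scene, "contact_scene"))
  if (scene$expansion_state != "pre")
    abort("scene already expanded", "cequant_error_state")
  k <- transform$k; r <- transform$r
  g <- scene$geometry
  scale_points <- function(x, y) {
    u <- x * cos(g$angle) + y * sin(g$angle)
    v <- -x * sin(g$angle) + y * cos(g$angle)
    u <- u * k; v <- v * k * r
    list(x = u * cos(g$angle) - v * sin(g$angle),
         y = u * sin(g$angle) + v * cos(g$angle))
  }
  p <- scale_points(scene$puncta$x, scene$puncta$y)
  q <- scale_points(scene$glur2$x, scene$glur2$y)
  w <- scale_points(scene$dark$x, scene$dark$y)
  out <- scene
  out$geometry$a <- g$a * k
  out$geometry$b <- g$b * k * r
  out$geometry$concavity <- g$concavity * k
  out$puncta <- data.frame(x = p$x, y = p$y,
                           radius_long = scene$puncta$radius * k,
                           radius_short = scene$puncta$radius * k * r)
  out$glur2 <- data.frame(x = q$x, y = q$y,
                          radius_long = scene$glur2$radius * k,
                          radius_short = scene$glur2$radius * k * r)
  out$dark <- data.frame(x = w$x, y = w$y,
                         radius_long = scene$dark$radius * k,
                         radius_short = scene$dark$radius * k * r)
  out$expansion_state <- "post"
  out$transform <- transform
  tr <- out$truth
  tr$long_diameter_post <- 2 * out$geometry$a
  tr$short_diameter_post <- 2 * out$geometry$b
  tr$sl_ratio_post <- out$geometry$b / out$geometry$a
  tr$contact_area_post <- pi * out$geometry$a * out$geometry$b
  tr$punctum_areas_post_actual <- pi * out$puncta$radius_long * out$puncta$radius_short
  out$truth <- tr
  out
}
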