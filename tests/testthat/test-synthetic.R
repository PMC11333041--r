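# Ground-truth generator: sampling laws, geometry invariants, the expansion
# transform and the imaging model.

test_that("forced single-punctum draw is recorded exactly in the truth", {
  cfg <- contact_config()
  cfg$puncta_count_mean <- 1; cfg$puncta_count_sd <- 0; cfg$puncta_count_min <- 1L
  cfg$area_meanlog <- log(0.5); cfg$area_sdlog <- 0
  sc <- sample_contact(cfg, seed = 5)
  expect_equal(sc$truth$n_puncta, 1L)
  expect_equal(sc$truth$punctum_areas_post, 0.5, tolerance = 1e-12)
  expect_equal(pi * sc$puncta$radius^2 * cfg$expansion_factor^2, 0.5,
               tolerance = 1e-12)
})

test_that("every receptor-patch centroid lies in the peripheral quarter annulus", {
  for (seed in c(2, 9, 31)) {
    sc <- sample_contact(seed = seed)
    g <- sc$geometry
    # brute containment check from the stored coordinates, not the recorded rho
    rho <- sqrt(((sc$glur2$x * cos(g$angle) + sc$glur2$y * sin(g$angle)) / g$a)^2 +
                ((-sc$glur2$x * sin(g$angle) + sc$glur2$y * cos(g$angle)) / g$b)^2)
    expect_true(all(rho > sqrt(0.75) - 1e-9))
    expect_true(all(rho <= 1 + 1e-9))
  }
})

test_that("empirical mean puncta count matches the configured law", {
  set.seed(100)
  counts <- replicate(300, sample_contact()$truth$n_puncta)
  se <- contact_config()$puncta_count_sd / sqrt(length(counts))
  expect_lt(abs(mean(counts) - contact_config()$puncta_count_mean), 3 * se)
})

test_that("gap-junction disks are pairwise disjoint", {
  for (seed in c(4, 17)) {
    sc <- sample_contact(seed = seed)
    p <- sc$puncta
    n <- nrow(p)
    for (i in seq_len(n - 1)) {
      dd <- sqrt((p$x[(i + 1):n] - p$x[i])^2 + (p$y[(i + 1):n] - p$y[i])^2)
      expect_true(all(dd >= p$radius[(i + 1):n] + p$radius[i] - 1e-9))
    }
  }
})

test_that("isotropic expansion scales areas by exactly k^2 and k = 1 is identity", {
  sc <- sample_contact(seed = 3)
  ex <- apply_expansion(sc, expansion_transform(k = 3.9, r = 1))
  expect_equal(ex$truth$contact_area_post, 3.9^2 * sc$truth$contact_area,
               tolerance = 1e-12)
  expect_equal(ex$truth$punctum_areas_post_actual,
               3.9^2 * sc$truth$punctum_areas, tolerance = 1e-12)
  expect_equal(ex$truth$sl_ratio_post, sc$truth$sl_ratio, tolerance = 1e-12)

  id <- apply_expansion(sc, expansion_transform(k = 1, r = 1))
  expect_equal(id$puncta$x, sc$puncta$x)
  expect_equal(id$puncta$radius_long, sc$puncta$radius)
  expect_equal(id$geometry$a, sc$geometry$a)
})

test_that("anisotropic expansion changes the fitted S/L ratio by the factor r", {
  sc <- sample_contact(seed = 21)
  r <- 0.82
  ex <- apply_expansion(sc, expansion_transform(k = 3.9, r = r))
  # fit-and-compare on rasterized outlines, independent of the stored axes
  fit_of <- function(g, px) {
    img <- ellipse_image(ceiling(2.4 * g$a / px), ceiling(2.4 * g$a / px), px,
                         c(1.2 * g$a, 1.2 * g$a), g$a, g$b, g$angle)
    fit_contact_outline(img, px, threshold = 0.5)$measure
  }
  pre <- fit_of(sc$geometry, 0.02)
  post <- fit_of(ex$geometry, 0.08)
  expect_equal(post$sl_ratio / pre$sl_ratio, r, tolerance = 0.03)
})

test_that("ground-truth occupancy fractions partition the contact", {
  ds <- generate_dataset(scene_defaults_small(), n_scenes = 2, seed = 8,
                         channels = "Cx35.5")
  for (s in ds$scenes) {
    oc <- s$truth$occupancy
    expect_equal(sum(oc), 1, tolerance = 1e-12)
    masks <- s$truth$masks
    expect_equal(sum(masks$gj) + sum(masks$aj) + sum(masks$glur2) +
                 sum(masks$unlabeled), sum(masks$contact))
    expect_false(any(masks$gj & masks$aj))
    expect_false(any(masks$gj & masks$glur2))
  }
})

test_that("rendered offset channels separate by the configured distance", {
  m <- imaging_model()
  sim <- render_linescan_punctum(m, offset_um = 0.21, noise = FALSE)
  prof <- extract_profile(lapply(sim$stack$channels, function(a) a[, , 1]),
                          sim$p0, sim$p1, m$pixel_size_xy, width = sim$width)
  po <- peak_offset(prof)
  expect_equal(abs(po$offset), 0.21, tolerance = m$pixel_size_xy / 2)

  # zero offset: channel maxima coincide
  sim0 <- render_linescan_punctum(m, offset_um = 0, noise = FALSE)
  prof0 <- extract_profile(lapply(sim0$stack$channels, function(a) a[, , 1]),
                           sim0$p0, sim0$p1, m$pixel_size_xy, width = sim0$width)
  po0 <- peak_offset(prof0)
  expect_lt(abs(po0$offset), 1e-6)
})

test_that("background-only channel renders at the configured background level", {
  cfg <- scene_defaults_small()
  cfg$glur2_n_range <- c(0L, 0L)
  set.seed(12)
  sc <- apply_expansion(sample_contact(cfg))
  st <- render(sc, channels = "GluR2", seed = 12)
  v <- as.numeric(st$channels[[1]])
  m <- imaging_model()
  se <- sqrt(m$background + m$read_noise_sd^2) / sqrt(length(v))
  expect_lt(abs(mean(v) - m$background), 3 * se + 0.01)
})

test_that("dataset generation is deterministic in the seed", {
  a <- generate_dataset(scene_defaults_small(), n_scenes = 2, seed = 7,
                        channels = "Cx35.5")
  b <- generate_dataset(scene_defaults_small(), n_scenes = 2, seed = 7,
                        channels = "Cx35.5")
  expect_identical(a$scenes[[1]]$stack$channels, b$scenes[[1]]$stack$channels)
  expect_identical(a$manifest$n_puncta, b$manifest$n_puncta)
  expect_equal(nrow(a$manifest), 2L)

  c_ <- generate_dataset(scene_defaults_small(), n_scenes = 2, seed = 8,
                         channels = "Cx35.5")
  expect_false(identical(a$scenes[[1]]$stack$channels,
                         c_$scenes[[1]]$stack$channels))
})

test_that("imaging model and transform validate their parameters", {
  expect_error(imaging_model(photon_scale = 0), class = "cequant_error_model")
  expect_error(imaging_model(offset_cx = -0.1), class = "cequant_error_model")
  expect_error(expansion_transform(k = 0), class = "cequant_error_transform")
})

test_that("manders on mutually exclusive channels shrinks as the PSF shrinks", {
  set.seed(6)
  sc <- apply_expansion(sample_contact(scene_defaults_small()))
  m1 <- numeric(0)
  for (sig in c(0.06, 0.28 / 2.355, 0.24)) {
    m <- imaging_model(psf_sigma_lateral = sig)
    st <- render(sc, m, channels = c("Cx35.5", "NCad"), noise = FALSE)
    p <- sum_project(st)
    roi <- st$metadata$truth$masks$contact
    th <- select_thresholds(p$channels[[1]], p$channels[[2]], roi)
    m1 <- c(m1, manders(p$channels[[1]], p$channels[[2]], roi, th[1], th[2])$M1)
  }
  expect_true(all(diff(m1) > 0))
})
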