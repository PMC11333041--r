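# Line-scan profiles, subpixel peak localization and offset statistics.

test_that("profiles of constant and row-aligned images are exact", {
  img <- matrix(4.2, 12, 20)
  pr <- extract_profile(img, c(0.2, 0.6), c(1.8, 0.6), 0.1, width = 0)
  expect_true(all(abs(pr$intensity[[1]] - 4.2) < 1e-12))

  set.seed(2)
  img2 <- matrix(runif(12 * 20), 12, 20)
  px <- 0.1
  row <- 5
  # along the pixel-center row, sampling at pixel centers, width 0
  pr2 <- extract_profile(img2, c(0.5 * px, (row - 0.5) * px),
                         c(19.5 * px, (row - 0.5) * px), px, width = 0,
                         step = px)
  expect_equal(pr2$intensity[[1]], img2[row, 1:20], tolerance = 1e-12)

  expect_error(extract_profile(img, c(0, 0.6), c(0, 0.6), 0.1),
               class = "cequant_error_line")
  expect_error(extract_profile(img, c(-5, 0.6), c(1, 0.6), 0.1),
               class = "cequant_error_line")
})

test_that("a diagonal profile of a linear ramp is linear with the predicted slope", {
  px <- 0.1
  nx <- 30; ny <- 30
  xs <- (seq_len(nx) - 0.5) * px
  img <- matrix(xs, ny, nx, byrow = TRUE)   # intensity = x coordinate (um)
  p0 <- c(0.5, 0.5); p1 <- c(2.5, 2.5)
  pr <- extract_profile(img, p0, p1, px, width = 0)
  # closed form: I(t) = p0_x + t * cos(45 deg)
  pred <- p0[1] + pr$position * cos(pi / 4)
  expect_equal(pr$intensity[[1]], pred, tolerance = 1e-9)
})

test_that("peak localization is subpixel-accurate on noiseless shapes", {
  x <- seq(0, 7, by = 0.04)
  g <- exp(-(x - 3.70)^2 / (2 * 0.15^2))
  pk <- locate_peak(x, g, window = 0.3)
  expect_equal(pk$position, 3.70, tolerance = 0.005)
  expect_equal(pk$method, "gaussian")

  tri <- pmax(0, 1 - abs(x - 2.0) / 0.5)
  pt <- locate_peak(x, tri, window = 0.2)
  expect_equal(pt$position, 2.0, tolerance = 0.02)

  # boundary maximum is flagged
  mono <- seq_along(x)
  pb <- locate_peak(x, mono)
  expect_true(pb$boundary)
})

test_that("peak localization is unbiased under shot noise", {
  set.seed(14)
  x <- seq(0, 4, by = 0.04)
  mu <- 1.97
  est <- replicate(100, {
    y <- rpois(length(x), 400 * exp(-(x - mu)^2 / (2 * 0.12^2)) + 10)
    locate_peak(x, y, window = 0.3)$position
  })
  expect_lt(abs(mean(est) - mu), 0.01)
})

test_that("offsets are antisymmetric in channel order and exact when constructed", {
  x <- seq(0, 4, by = 0.04)
  a <- exp(-(x - 1.80)^2 / (2 * 0.12^2))
  b <- exp(-(x - 2.01)^2 / (2 * 0.12^2))
  pr <- structure(list(position = x, intensity = list(A = a, B = b),
                       p0 = c(0, 0), p1 = c(4, 0), width = 0),
                  class = "line_profile")
  fwd <- peak_offset(pr, channels = c("A", "B"))
  expect_equal(fwd$offset, 0.21, tolerance = 0.005)
  rev <- peak_offset(pr, channels = c("B", "A"))
  expect_equal(rev$offset, -fwd$offset, tolerance = 1e-12)

  same <- peak_offset(structure(list(position = x,
                                     intensity = list(A = a, B = a)),
                                class = "line_profile"),
                      channels = c("A", "B"))
  expect_equal(same$offset, 0)
})

test_that("sub-resolution offsets are recovered in the noiseless limit", {
  m <- imaging_model()
  sim <- render_linescan_punctum(m, offset_um = 0.03,
                                 channel_names = c("Cx35.5", "Cx34.1"),
                                 noise = FALSE)
  pr <- extract_profile(lapply(sim$stack$channels, function(a) a[, , 1]),
                        sim$p0, sim$p1, m$pixel_size_xy, width = sim$width)
  po <- peak_offset(pr, channels = c("Cx35.5", "Cx34.1"))
  expect_lt(abs(abs(po$offset) - 0.03), 0.005)
})

test_that("fluorophore swap leaves the offset magnitude unchanged", {
  set.seed(27)
  d1 <- measure_sideview_offsets(12, 0.21, channel_names = c("Cx35.5", "ZO1"))
  d2 <- measure_sideview_offsets(12, 0.21, channel_names = c("ZO1", "Cx35.5"))
  se <- sqrt(stats::var(abs(d1)) / length(d1) + stats::var(abs(d2)) / length(d2))
  expect_lt(abs(mean(abs(d1)) - mean(abs(d2))), 2 * se + 0.005)
})

test_that("offset recovery at the default separation over many profiles", {
  set.seed(41)
  d <- measure_sideview_offsets(15, 0.21)
  se <- stats::sd(abs(d)) / sqrt(length(d))
  expect_lt(abs(mean(abs(d)) - 0.21), 2 * se + 0.002)
})

test_that("group offset statistics match textbook ANOVA and Tukey", {
  g <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8))
  st <- offset_stats(g)
  # hand-computed: SSB = 42 on 2 df, SSW = 6 on 6 df, F = 21
  expect_equal(st$anova_F, 21, tolerance = 1e-10)
  expect_equal(st$table$mean, c(2, 3, 7))
  expect_equal(st$table$sem, rep(1 / sqrt(3), 3))

  same <- offset_stats(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_gt(same$tukey[1, "p adj"], 0.99)
  expect_error(offset_stats(list(a = 1:3)), class = "cequant_error_input")
})

test_that("the published group sizes give overwhelming ANOVA power", {
  set.seed(50)
  rej <- replicate(100, {
    o <- list(cx = rnorm(37, 0.03, 0.06), zo1 = rnorm(30, 0.21, 0.06))
    offset_stats(o)$anova_p < 1e-4
  })
  expect_gt(mean(rej), 0.9)
})
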