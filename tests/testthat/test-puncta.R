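# Punctum segmentation, morphometry, connexon arithmetic, histograms.

test_that("disjoint bright disks segment into one label each with exact areas", {
  px <- 0.08
  img <- disk_image(80, 80, px, c(1.5, 1.5), 0.4, 100) +
         disk_image(80, 80, px, c(4.5, 1.8), 0.6, 100) +
         disk_image(80, 80, px, c(3.0, 4.8), 0.3, 100)
  roi <- matrix(TRUE, 80, 80)
  lab <- segment_puncta(img, roi, px, threshold = 50)
  expect_equal(max(lab), 3L)
  rec <- measure_puncta(lab, px, areal_expansion_factor = 1)
  # brute pixel counts per disk
  expect_equal(sort(rec$area_um2),
               sort(c(sum(disk_image(80, 80, px, c(1.5, 1.5), 0.4) > 0),
                      sum(disk_image(80, 80, px, c(4.5, 1.8), 0.6) > 0),
                      sum(disk_image(80, 80, px, c(3.0, 4.8), 0.3) > 0)) * px^2))
})

test_that("a blank image yields an empty labeling, not an error", {
  lab <- segment_puncta(matrix(0, 20, 20), matrix(TRUE, 20, 20), 0.08,
                        threshold = 1)
  expect_equal(max(lab), 0L)
  expect_equal(nrow(measure_puncta(lab, 0.08, 13.4)), 0L)
  expect_error(segment_puncta(matrix(0, 5, 5), matrix(FALSE, 5, 5), 0.08),
               class = "cequant_error_empty_roi")
})

test_that("close puncta merge when the PSF grows (the stated caveat)", {
  px <- 0.04
  dens <- disk_image(120, 120, px, c(1.8, 2.4), 0.3) +
          disk_image(120, 120, px, c(3.0, 2.4), 0.3)   # edge gap 0.6 um
  roi <- matrix(TRUE, 120, 120)
  narrow <- EBImage::gblur(dens, sigma = 0.119 / px, boundary = 0)
  wide <- EBImage::gblur(dens, sigma = 3 * 0.119 / px, boundary = 0)
  lab1 <- segment_puncta(narrow, roi, px)
  lab2 <- segment_puncta(wide, roi, px)
  expect_equal(max(lab1), 2L)
  expect_equal(max(lab2), 1L)
})

test_that("connexon arithmetic follows area / expansion x density", {
  lab <- matrix(0L, 40, 40)
  lab[5:15, 5:20] <- 1L
  px <- sqrt(1.99 / sum(lab == 1L))   # image-scale area exactly 1.99 um^2
  rec <- measure_puncta(lab, px, areal_expansion_factor = 13.4,
                        connexon_density = 12000)
  expect_equal(rec$area_um2, 1.99, tolerance = 1e-12)
  expect_equal(rec$connexons, round(1.99 / 13.4 * 12000))  # 1782

  unit <- measure_puncta(lab, sqrt(1 / sum(lab == 1L)), 1, 12000)
  expect_equal(unit$connexons, 12000L)

  # linear in density and area, inverse in expansion factor
  r2 <- measure_puncta(lab, px, 13.4, 24000)
  expect_equal(r2$biological_area_um2 * 24000, 2 * rec$biological_area_um2 * 12000)
  r3 <- measure_puncta(lab, px, 26.8, 12000)
  expect_equal(r3$biological_area_um2, rec$biological_area_um2 / 2)
  expect_error(measure_puncta(lab, px, 0), class = "cequant_error_input")
})

test_that("Sturges histograms use ceil(1 + log2 n) bins and conserve counts", {
  set.seed(1)
  v <- runif(33, 0.06, 1.99)
  h <- area_histogram(v)
  expect_equal(h$k, 7L)               # ceil(1 + log2 33) = 7
  expect_equal(sum(h$counts), 33L)
  expect_equal(length(h$breaks), 8L)

  h1 <- area_histogram(0.5)
  expect_equal(h1$k, 1L)
  expect_equal(sum(h1$counts), 1L)

  v2 <- runif(200)
  expect_equal(sum(area_histogram(v2)$counts), 200L)
  expect_error(area_histogram(numeric(0)), class = "cequant_error_input")
})

test_that("contact summaries total their records", {
  rec <- data.frame(label = 1:2, area_um2 = c(0.5, 1.0),
                    centroid_x_um = c(1, 2), centroid_y_um = c(1, 2),
                    biological_area_um2 = c(0.05, 0.1),
                    connexons = c(100L, 200L))
  sm <- contact_summary(rec)
  expect_equal(sm$n, 2L)
  expect_equal(sm$total_connexons, 300L)
  expect_equal(sm$total_area_um2, 1.5)

  sm0 <- contact_summary(measure_puncta(matrix(0L, 4, 4), 0.1, 1))
  expect_equal(sm0$n, 0L)
  expect_equal(sm0$total_connexons, 0)
  expect_null(sm0$histogram)
})

test_that("noiseless well-separated scenes are counted exactly", {
  cfg <- contact_config()
  cfg$puncta_count_mean <- 15; cfg$puncta_count_sd <- 0
  cfg$area_meanlog <- log(0.5); cfg$area_sdlog <- 0.3
  cfg$area_range_post <- c(0.2, 1.99)
  cfg$min_edge_gap_post <- 0.3    # >= 2 lateral PSF sigma
  for (seed in c(2, 13)) {
    set.seed(seed)
    sc <- apply_expansion(sample_contact(cfg))
    st <- render(sc, channels = "Cx35.5", noise = FALSE)
    tr <- st$metadata$truth
    p <- sum_project(st)
    lab <- segment_puncta(p$channels[[1]], tr$masks$contact, 0.08)
    expect_equal(max(lab), tr$n_puncta)
  }
})

test_that("detected area distributions are statistically consistent with truth", {
  ds <- generate_dataset(n_scenes = 50, seed = 31, channels = "Cx35.5")
  all_det <- all_tru <- relerr <- c()
  for (s in ds$scenes) {
    tr <- s$truth
    img <- sum_project(s$stack)$channels[[1]]
    fit <- fit_contact_outline(img, 0.08)
    lab <- segment_puncta(img, fit$mask, 0.08, split_touching = TRUE)
    rec <- measure_puncta(lab, 0.08, 13.4)
    tlab <- EBImage::bwlabel(tr$masks$gj)
    ta <- tabulate(tlab[tlab > 0]) * 0.08^2
    for (k in seq_len(max(tlab))) {
      pix <- lab[tlab == k]; pix <- pix[pix > 0]
      if (!length(pix)) next
      dlab <- as.integer(names(sort(table(pix), decreasing = TRUE))[1])
      relerr <- c(relerr, abs(rec$area_um2[dlab] - ta[k]) / ta[k])
    }
    all_det <- c(all_det, rec$area_um2); all_tru <- c(all_tru, ta)
  }
  expect_lt(stats::median(relerr), 0.15)
  ks <- suppressWarnings(stats::ks.test(all_det, all_tru))
  expect_gt(ks$p.value, 0.01)
})
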