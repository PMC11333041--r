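# Center/periphery partition, CTCF and labeling occupancy.

fit_ellipse_contact <- function(a = 4, b = 2.5, angle = 0.7, px = 0.04) {
  n <- ceiling(2.6 * a / px)
  img <- ellipse_image(n, n, px, c(1.3 * a, 1.3 * a), a, b, angle, value = 10)
  fit_contact_outline(img, px, threshold = 5)
}

test_that("center ellipse holds three quarters of the contact area", {
  fit <- fit_ellipse_contact()
  part <- partition_center_periphery(fit$mask, fit$measure)
  frac <- sum(part$center) / sum(fit$mask)
  expect_equal(frac, 0.75, tolerance = 0.01)
  # masks partition the contact exactly
  expect_equal(sum(part$center) + sum(part$periphery), sum(fit$mask))
  expect_false(any(part$center & part$periphery))

  # circle: center radius is R * sqrt(3)/2
  circ <- fit_ellipse_contact(a = 3, b = 3, angle = 0)
  pc <- partition_center_periphery(circ$mask, circ$measure)
  expect_equal(sum(pc$center) / sum(circ$mask), 0.75, tolerance = 0.01)
})

test_that("lateral-view contacts are refused", {
  fit <- fit_ellipse_contact()
  m <- fit$measure
  m$view <- "lateral"
  expect_error(partition_center_periphery(fit$mask, m),
               class = "cequant_error_lateral_view")
})

test_that("ctcf follows its defining identity", {
  img <- matrix(2, 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[1:5, 1:10] <- TRUE       # 50 px
  bg <- matrix(FALSE, 20, 20); bg[15:20, 15:20] <- TRUE
  img[roi] <- 20                                             # int. density 1000
  v <- ctcf(img, roi, bg)
  expect_equal(v$integrated_density, 1000)
  expect_equal(v$background_mean, 2)
  expect_equal(v$ctcf, 1000 - 50 * 2)                         # 900

  # zero background: ctcf equals integrated density
  img0 <- img; img0[bg] <- 0
  expect_equal(ctcf(img0, roi, bg)$ctcf, 1000)

  # uniform image: exact zero by the identity v*A - A*v
  u <- matrix(7.3, 20, 20)
  expect_equal(ctcf(u, roi, bg)$ctcf, 0)
  expect_error(ctcf(img, roi, matrix(FALSE, 20, 20)),
               class = "cequant_error_empty_roi")
})

test_that("ctcf is linear in the image", {
  set.seed(4)
  A <- matrix(rpois(400, 10), 20)
  B <- matrix(rpois(400, 30), 20)
  roi <- matrix(FALSE, 20, 20); roi[3:9, 3:9] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[15:19, 15:19] <- TRUE
  expect_equal(ctcf(A + B, roi, bg)$ctcf,
               ctcf(A, roi, bg)$ctcf + ctcf(B, roi, bg)$ctcf,
               tolerance = 1e-9)
})

test_that("occupancy fractions add up and respect exclusivity", {
  roi <- matrix(TRUE, 20, 20)
  half <- matrix(0, 20, 20); half[, 1:10] <- 5
  oc <- occupancy(list(a = half), roi, thresholds = c(a = 1))
  expect_equal(unname(oc$fractions[["a"]]), 0.5)
  expect_equal(oc$unlabeled, 0.5)

  ch1 <- matrix(0, 20, 20); ch1[, 1:8] <- 5     # 0.40
  ch2 <- matrix(0, 20, 20); ch2[1:14, 11:20] <- 5  # 0.35
  oc2 <- occupancy(list(a = ch1, b = ch2), roi, thresholds = c(a = 1, b = 1))
  expect_equal(unname(oc2$fractions), c(0.40, 0.35))
  expect_equal(oc2$unlabeled, 0.25)
  expect_equal(sum(oc2$fractions) + oc2$unlabeled, 1)

  # overlap goes to the channel with the larger threshold-normalized intensity
  ov1 <- matrix(0, 10, 10); ov1[, 1:6] <- 10
  ov2 <- matrix(0, 10, 10); ov2[, 4:10] <- 30
  oc3 <- occupancy(list(a = ov1, b = ov2), matrix(TRUE, 10, 10),
                   thresholds = c(a = 1, b = 1))
  expect_equal(unname(oc3$fractions), c(0.3, 0.7))
  expect_equal(sum(oc3$fractions) + oc3$unlabeled, 1)
  # non-exclusive mode double-counts the overlap
  oc4 <- occupancy(list(a = ov1, b = ov2), matrix(TRUE, 10, 10),
                   thresholds = c(a = 1, b = 1), exclusive = FALSE)
  expect_equal(unname(oc4$fractions), c(0.6, 0.7))
})

test_that("noiseless synthetic occupancies recover ground truth within 0.03", {
  for (seed in c(11, 5)) {
    set.seed(seed)
    sc <- apply_expansion(sample_contact())
    st <- render(sc, channels = c("Cx35.5", "GluR2", "NCad"), noise = FALSE)
    tr <- st$metadata$truth
    p <- sum_project(st)
    oc <- occupancy(p$channels[c("Cx35.5", "GluR2", "NCad")], tr$masks$contact)
    measured <- c(oc$fractions, unlabeled = oc$unlabeled)
    truth <- tr$occupancy[c("gj", "glur2", "aj", "unlabeled")]
    expect_lt(max(abs(unname(measured) - unname(truth))), 0.03)
  }
})

test_that("center/periphery analysis reproduces the peripheral-receptor layout", {
  set.seed(23)
  contacts <- list()
  for (i in 1:3) {
    sc <- apply_expansion(sample_contact())
    st <- render(sc, channels = c("Cx35.5", "GluR2"))
    p <- sum_project(st)
    fit <- fit_contact_outline(p$channels[["Cx35.5"]], p$pixel_size_xy)
    part <- partition_center_periphery(fit$mask, fit$measure)
    contacts[[i]] <- list(chA = p$channels[["Cx35.5"]],
                          chB = p$channels[["GluR2"]],
                          partition = part,
                          background_roi = default_background_roi(
                            p$channels[["Cx35.5"]], fit$mask))
  }
  out <- center_periphery_analysis(contacts)
  tb <- out$table
  # connexin dominates the center; receptor fluorescence is peripheral
  expect_true(all(tb$Cx35.5_center > tb$GluR2_center))
  expect_true(all(tb$GluR2_periphery > tb$GluR2_center))
  # each contact is normalized to its own brightest channel x ROI value
  vals <- as.matrix(tb[, 2:5])
  expect_true(all(abs(apply(vals, 1, max) - 1) < 1e-9))
  expect_lt(out$tests$center$p_value, 0.05)

  # identical channels: the cross-channel test cannot reject
  same <- lapply(contacts, function(ct) { ct$chB <- ct$chA; ct })
  out2 <- center_periphery_analysis(same)
  expect_equal(out2$tests$center$p_value, 1, tolerance = 1e-9)
})
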