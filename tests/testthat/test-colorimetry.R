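test_that("optical-density unmixing separates pure stains", {
  # pure white: zero optical density, zero concentration for both stains
  white <- array(255L, c(8, 8, 3))
  dw <- deconvolve_stains(white)
  expect_true(all(abs(dw$conc[, 1:2]) < 1e-3))

  # image whose absorption is exactly the basis hematoxylin vector at fixed
  # strength: unmixing recovers hematoxylin and (near-)zero eosin everywhere
  basis <- stain_od_matrix("HE")
  pal <- chromogen_palette("basis", j = basis[1, ], k = basis[2, ])
  h <- matrix(1.5, 16, 16)
  img <- unclass(beer_lambert_render(h, h * 0, pal))
  dh <- deconvolve_stains(img)
  expect_true(all(dh$conc[, 1] > 10 * abs(dh$conc[, 2])))
  expect_equal(mean(dh$conc[, 1]), 1.5, tolerance = 0.01)

  # basis round trip: concentrations times the basis reconstruct OD
  set.seed(20)
  rnd <- array(sample.int(200, 6 * 6 * 3, replace = TRUE) + 20L, c(6, 6, 3))
  d <- deconvolve_stains(rnd)
  od <- -log((as.numeric(rnd) + 1) / 256)
  dim(od) <- c(36, 3)
  expect_equal(d$conc %*% d$basis, od, tolerance = 1e-10,
               ignore_attr = TRUE)

  # collinear basis is rejected
  expect_error(deconvolve_stains(rnd, rbind(c(1, 0, 0), c(1, 0, 0))),
               "collinear")
})

test_that("Otsu thresholding matches an exhaustive-search oracle", {
  set.seed(21)
  p <- matrix(pmin(pmax(c(rnorm(600, 0.2, 0.05), rnorm(424, 0.8, 0.05)), 0), 1),
              32, 32)
  thr <- EBImage::otsu(EBImage::Image(p), range = c(0, 1))
  oracle <- otsu_oracle(p)
  # the objective is flat between well-separated modes, so compare the
  # achieved between-class variance and the induced classification, not the
  # raw argmax
  bcv <- function(t) {
    w0 <- mean(p <= t)
    w0 * (1 - w0) * (mean(p[p <= t]) - mean(p[p > t]))^2
  }
  expect_gt(bcv(thr), 0.999 * bcv(oracle))
  expect_identical(p > thr, p > oracle)
  expect_gt(thr, 0.3); expect_lt(thr, 0.7) # between the modes
})

test_that("segmentation removes small objects and opens away thin spurs", {
  # a 2x2 blob (area 4) vanishes under area_min = 10
  p <- matrix(0, 32, 32)
  p[10:11, 10:11] <- 1
  seg <- suppressWarnings(
    segment_structures(list(a = p, b = matrix(0, 32, 32)),
                       median_size = 1, area_min = 10, opening_radius = 1))
  expect_false(any(seg$masks$a))

  # opening with r = 3: a 1-pixel-wide spur disappears, a radius-5 disk stays
  q <- matrix(0, 48, 48)
  yy <- matrix(rep(-23:24, 48), 48); xx <- t(yy)
  disk <- (yy + 10)^2 + (xx + 10)^2 <= 25   # radius-5 disk
  q[disk] <- 1
  q[30, 5:40] <- 1                          # 1-px spur
  seg2 <- suppressWarnings(
    segment_structures(list(a = q, b = matrix(0, 48, 48)),
                       median_size = 1, area_min = 1, opening_radius = 3))
  expect_false(any(seg2$masks$a[30, 1:20] & !disk[30, 1:20]))
  expect_true(any(seg2$masks$a & disk))

  # constant probability maps: empty masks, one warning per constant map
  w <- capture_warnings(
    seg3 <- segment_structures(list(a = matrix(0.5, 16, 16),
                                    b = matrix(0, 16, 16))))
  expect_length(w, 2)
  expect_match(w, "constant", all = TRUE)
  expect_false(any(seg3$masks$a))
})

test_that("overlapping claims go to the stain with higher concentration", {
  a <- matrix(0.1, 16, 16); b <- matrix(0.1, 16, 16)
  a[, 1:8] <- 0.9; b[, 5:12] <- 0.8
  # Otsu masks overlap on columns 5:8; stain a has the higher concentration
  seg <- segment_structures(list(a = a, b = b), median_size = 1,
                            area_min = 1, opening_radius = 1)
  expect_false(any(seg$masks$a & seg$masks$b))
  expect_true(all(seg$masks$a[, 5:8]))
  expect_false(any(seg$masks$b[, 5:8]))
  expect_true(all(seg$masks$b[, 9:12]))
})

test_that("HSV medians reproduce color-model identities", {
  red <- array(0L, c(8, 8, 3)); red[, , 1] <- 255L
  full <- list(stain = matrix(TRUE, 8, 8))
  rep1 <- measure_hsv(red, full)
  expect_equal(rep1$hue, 0); expect_equal(rep1$saturation, 1)
  expect_equal(rep1$value, 1)

  gray <- array(128L, c(8, 8, 3))
  rep2 <- measure_hsv(gray, full)
  expect_equal(rep2$saturation, 0); expect_equal(rep2$value, 128 / 255)

  # two-tone image: per-region medians equal the region colors
  img <- array(0L, c(8, 8, 3))
  img[, 1:4, ] <- rep(c(200L, 40L, 220L), each = 32)   # purple-ish
  img[, 5:8, ] <- rep(c(250L, 120L, 180L), each = 32)  # pink-ish
  masks <- list(left = cbind(matrix(TRUE, 8, 4), matrix(FALSE, 8, 4)),
                right = cbind(matrix(FALSE, 8, 4), matrix(TRUE, 8, 4)))
  rep3 <- measure_hsv(img, masks)
  exp_l <- grDevices::rgb2hsv(200, 40, 220, maxColorValue = 255)
  exp_r <- grDevices::rgb2hsv(250, 120, 180, maxColorValue = 255)
  expect_equal(unlist(rep3[1, c("hue", "saturation", "value")]),
               exp_l[, 1], ignore_attr = TRUE)
  expect_equal(unlist(rep3[2, c("hue", "saturation", "value")]),
               exp_r[, 1], ignore_attr = TRUE)

  # empty masks give NA statistics, and zero-valued pixels are ignored
  none <- measure_hsv(red, list(s = matrix(FALSE, 8, 8)))
  expect_true(is.na(none$hue)); expect_equal(none$n, 0L)
  blk <- array(0L, c(4, 4, 3)); blk[1, 1, ] <- c(10L, 20L, 30L)
  repb <- measure_hsv(blk, list(s = matrix(TRUE, 4, 4)))
  expect_equal(repb$n, 1L)
})

test_that("masks of a rendered two-color image recover labeled pixels", {
  # left: hematoxylin-rendered, right: eosin-rendered, on white
  h <- matrix(0, 64, 64); e <- matrix(0, 64, 64)
  h[8:56, 8:28] <- 2.5
  e[8:56, 36:56] <- 1.2
  img <- unclass(beer_lambert_render(h, e))
  seg <- segment_structures(deconvolve_stains(img), area_min = 16)
  truth_h <- h > 0; truth_e <- e > 0
  recov_h <- sum(seg$masks$hematoxylin & truth_h) / sum(truth_h)
  recov_e <- sum(seg$masks$eosin & truth_e) / sum(truth_e)
  expect_gt(recov_h, 0.90)
  expect_gt(recov_e, 0.90)
  # and the masks stay essentially inside the truth regions
  expect_lt(sum(seg$masks$hematoxylin & !truth_h) / sum(truth_h), 0.05)
})

test_that("ROI sampling is deterministic, tissue-aware, and warns when short", {
  blank <- array(255L, c(64, 64, 3))
  expect_warning(r0 <- sample_rois(blank, n_rois = 3, roi_shape = c(16, 16),
                                   seed = 1, max_tries = 50), "only 0")
  expect_length(r0, 0)

  img <- array(255L, c(128, 128, 3))
  img[32:96, 32:96, ] <- 100L
  r1 <- sample_rois(img, n_rois = 5, roi_shape = c(24, 24), seed = 99)
  r2 <- sample_rois(img, n_rois = 5, roi_shape = c(24, 24), seed = 99)
  expect_identical(attr(r1, "origins"), attr(r2, "origins"))
  expect_length(r1, 5)
  for (roi in r1) expect_gte(mean(roi[, , 1] < 235), 0.2)
  expect_error(sample_rois(img, roi_shape = c(256, 256)), "smaller")
})

test_that("consistency summaries aggregate per-ROI medians like a box plot", {
  mk <- function(hue) structure(
    data.frame(stain = "hematoxylin", hue = hue, saturation = 0.5,
               value = 0.5, n = 10L),
    class = c("color_report", "data.frame"))
  same <- consistency_report(list(mk(0.8), mk(0.8), mk(0.8)))
  expect_equal(same$std[same$component == "hue"], 0)

  two <- consistency_report(list(mk(0.80), mk(0.82)))
  hrow <- two[two$component == "hue", ]
  expect_equal(hrow$median, 0.81)
  expect_equal(hrow$std, sd(c(0.80, 0.82)))
  expect_equal(hrow$p10, percentile_oracle(c(0.80, 0.82), 0.10))
  expect_named(two, c("stain", "component", "median", "std", "p10", "p90", "n"))
  expect_setequal(unique(two$component), c("hue", "saturation", "value"))
  expect_error(consistency_report(list(mk(0.8))), "at least 2")
})
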