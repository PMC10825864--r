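test_that("a constant image yields an empty mask with a warning, not an error", {
  img <- micro_image(matrix(5, 32, 32), 325)
  expect_warning(m <- segment_cells(img), "no intensity gradients")
  expect_equal(m$area_px, 0)
})

test_that("a noiseless bright disk is segmented with IoU >= 0.90", {
  img <- micro_image(disk_pixels(64, 64, 32.5, 32.5, 12, 100, 10), 325)
  truth <- disk_pixels(64, 64, 32.5, 32.5, 12, 1, 0) > 0
  m <- segment_cells(img)$mask
  expect_gte(sum(m & truth) / sum(m | truth), 0.90)
})

test_that("two disjoint blobs segment into exactly two components", {
  px <- pmax(disk_pixels(64, 64, 18, 18, 8, 100, 10),
             disk_pixels(64, 64, 46, 46, 8, 100, 10))
  m <- segment_cells(micro_image(px, 325),
                     segmentation_params(min_object_area = 20))
  expect_equal(max(EBImage::bwlabel(m$mask)), 2)
})

test_that("increasing the minimum object area never grows the mask", {
  img <- micro_image(disk_pixels(64, 64, 20, 20, 6, 80, 5) +
                       disk_pixels(64, 64, 48, 48, 12, 80, 5), 325)
  areas <- vapply(c(0, 20, 50, 120, 400, 2000), function(a)
    segment_cells(img, segmentation_params(min_object_area = a))$area_px,
    numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("masked mean intensity matches hand arithmetic and the loop oracle", {
  img22 <- micro_image(matrix(c(1, 5, 3, 7), 2, 2), 100)  # [[1,3],[5,7]]
  full <- matrix(TRUE, 2, 2)
  q <- mean_masked_intensity(img22, full)
  expect_equal(q$mean_intensity, 4.0)
  expect_equal(q$sum_intensity, 16)
  expect_equal(q$area_px, 4)
  cimg <- micro_image(matrix(2.5, 8, 8), 100)
  expect_equal(mean_masked_intensity(cimg, matrix(TRUE, 8, 8))$mean_intensity, 2.5)
  set.seed(21)
  px <- matrix(runif(64 * 64, 0, 50), 64, 64)
  mask <- matrix(runif(64 * 64) < 0.3, 64, 64)
  s <- 0; a <- 0
  for (i in 1:64) for (j in 1:64) if (mask[i, j]) { s <- s + px[i, j]; a <- a + 1 }
  q2 <- mean_masked_intensity(micro_image(px, 100), mask)
  expect_equal(q2$sum_intensity, s)
  expect_equal(q2$area_px, a)
  expect_equal(q2$mean_intensity, s / a)
})

test_that("masked mean is permutation-invariant, linear, and fails loudly", {
  set.seed(4)
  px <- matrix(runif(256, 0, 10), 16, 16)
  mask <- matrix(runif(256) < 0.4, 16, 16)
  m1 <- mean_masked_intensity(micro_image(px, 100), mask)$mean_intensity
  perm <- sample(256)  # same multiset of (pixel, mask) pairs, new layout
  m2 <- mean_masked_intensity(micro_image(matrix(px[perm], 16, 16), 100),
                              matrix(mask[perm], 16, 16))$mean_intensity
  expect_equal(m1, m2)
  expect_equal(mean_masked_intensity(micro_image(3 * px, 100), mask)$mean_intensity,
               3 * m1)
  expect_error(mean_masked_intensity(micro_image(px, 100),
                                     matrix(FALSE, 16, 16)), "empty mask")
  expect_error(mean_masked_intensity(micro_image(px, 100),
                                     matrix(TRUE, 8, 8)), "shapes differ")
})

test_that("SNR reproduces the closed form of its definition", {
  set.seed(7)
  mask <- disk_pixels(48, 48, 24, 24, 10, 1, 0) > 0
  bgv <- rnorm(sum(!mask))
  bgv <- (bgv - mean(bgv)) / sd(bgv) * 10 + 50  # exact mean 50, sd 10
  px <- matrix(0, 48, 48)
  px[mask] <- 150
  px[!mask] <- bgv
  img <- micro_image(px, 325)
  expect_equal(compute_snr(img, mask, bg_exclusion_radius = 0),
               (150 - 50) / 10, tolerance = 1e-9)
})

test_that("SNR is near zero when foreground and background are exchangeable", {
  mask <- disk_pixels(48, 48, 24, 24, 12, 1, 0) > 0
  snrs <- vapply(1:50, function(s) {
    set.seed(s)
    img <- micro_image(matrix(rpois(48 * 48, 30), 48, 48), 325)
    compute_snr(img, mask, bg_exclusion_radius = 2)
  }, numeric(1))
  expect_lt(mean(abs(snrs)), 0.2)
  expect_lt(abs(mean(snrs)), 0.1)
})

test_that("SNR is invariant when offset and background spread scale together", {
  mask <- disk_pixels(32, 32, 16, 16, 8, 1, 0) > 0
  set.seed(11)
  bg <- rnorm(sum(!mask))
  bg <- (bg - mean(bg)) / sd(bg)
  build <- function(k) {
    px <- matrix(0, 32, 32)
    px[mask] <- 100 + 20 * k
    px[!mask] <- 100 + k * 5 * bg
    micro_image(px, 325)
  }
  expect_equal(compute_snr(build(1), mask, 0), compute_snr(build(2), mask, 0),
               tolerance = 1e-9)
})

test_that("degenerate SNR inputs are rejected", {
  px <- matrix(5, 16, 16); px[4:8, 4:8] <- 50
  mask <- matrix(FALSE, 16, 16); mask[4:8, 4:8] <- TRUE
  img <- micro_image(px, 325)
  expect_error(compute_snr(img, mask, 0), "zero spread")
  expect_error(compute_snr(img, matrix(FALSE, 16, 16), 0), "empty mask")
  expect_error(compute_snr(img, matrix(TRUE, 16, 16), 0), "background region is empty")
})
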