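test_that("DoG of a constant image is zero and the filter is linear", {
  img <- matrix(7.5, 64, 64)
  out <- dog_filter(img, dog_params(1, 4))
  expect_lt(max(abs(out)), 1e-9)
  set.seed(2)
  rnd <- matrix(runif(32 * 32), 32, 32)
  expect_equal(dog_filter(2 * rnd, dog_params(1, 3)),
               2 * dog_filter(rnd, dog_params(1, 3)), tolerance = 1e-10)
})

test_that("DoG impulse response matches dense direct convolution", {
  img <- matrix(0, 31, 31); img[16, 16] <- 1
  p <- dog_params(1, 2)
  got <- dog_filter(img, p)
  k_lo <- prolifscan:::gaussian_kernel(1)
  k_hi <- prolifscan:::gaussian_kernel(2)
  want <- dense_conv2(img, k_lo) - dense_conv2(img, k_hi)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("DoG parameter validation enforces sigma ordering", {
  expect_error(dog_params(2, 2), "strictly smaller")
  expect_error(dog_params(0, 2), "positive")
})

test_that("k-means threshold isolates a perfectly separated bright class", {
  set.seed(1)
  img <- matrix(10, 40, 40)
  bright <- sample(length(img), 160)        # 10% of pixels
  img[bright] <- 200
  res <- kmeans_threshold(img, 2)
  expect_gt(res$threshold, 10); expect_lt(res$threshold, 200)
  expect_identical(res$mask, img == 200)
})

test_that("k-means split of [1,2,3,10,11,12] recovers the two groups", {
  img <- matrix(c(1, 2, 3, 10, 11, 12), 2, 3)
  res <- kmeans_threshold(img, 2)
  expect_gt(res$threshold, 3); expect_lt(res$threshold, 10)
  expect_identical(res$mask, img >= 10)
})

test_that("k=2 threshold equals the exhaustive split oracle on random images", {
  set.seed(7)
  for (i in 1:10) {
    img <- matrix(round(runif(64), 2), 8, 8)   # coarse values keep oracle cheap
    if (length(unique(as.numeric(img))) < 2) next
    res <- kmeans_threshold(img, 2)
    expect_identical(res$mask, img > split_oracle(as.numeric(img)))
  }
})

test_that("constant images have no k-means threshold", {
  expect_error(kmeans_threshold(matrix(5, 10, 10)), "degenerate")
})

test_that("watershed keeps a lone disc whole and splits fused discs", {
  m1 <- disc_mask(50, 50, 25, 25, 10)
  lab1 <- hybrid_watershed(matrix(0, 50, 50), m1)
  expect_equal(max(lab1), 1)
  expect_identical(lab1 > 0, m1)

  m2 <- disc_mask(60, 60, 30, 23, 10) | disc_mask(60, 60, 30, 37, 10)
  lab2 <- hybrid_watershed(matrix(0, 60, 60), m2, tolerance = 1)
  expect_equal(max(lab2), 2)
  disc_area <- sum(disc_mask(60, 60, 30, 23, 10))
  areas <- tabulate(lab2[lab2 > 0])
  expect_true(all(abs(areas - disc_area) / disc_area < 0.15))
  # labels partition the mask
  expect_identical(lab2 > 0, m2)
})

test_that("an empty mask yields zero regions, not an error", {
  lab <- hybrid_watershed(matrix(0, 20, 20), matrix(FALSE, 20, 20))
  expect_equal(max(lab), 0)
})

test_that("region filtering matches a per-label brute-force oracle", {
  # one uniform region below the intensity floor is removed
  lab <- matrix(0L, 20, 20); lab[5:10, 5:10] <- 1L
  img <- matrix(50, 20, 20)
  out <- filter_regions(lab, img, segmentation_params(
    min_mean_intensity = 60, min_region_area = 1))
  expect_equal(max(out), 0)
  # vacuous thresholds are the identity
  expect_identical(
    filter_regions(lab, img, segmentation_params(min_mean_intensity = 0,
                                                 min_region_area = 1)),
    lab)
  # random label map + random image against the naive per-region oracle
  set.seed(11)
  rl <- matrix(sample(0:6, 400, replace = TRUE), 20, 20)
  ri <- matrix(runif(400), 20, 20)
  orc <- region_stats_oracle(rl, ri)
  params <- segmentation_params(min_mean_intensity = 0.45, min_region_area = 50)
  keep <- orc$label[orc$mean >= 0.45 & orc$area >= 50]
  out2 <- filter_regions(rl, ri, params)
  surv <- sort(unique(rl[out2 > 0]))       # original ids of survivors
  expect_setequal(surv, keep)
  expect_equal(sort(unique(out2[out2 > 0])), seq_along(keep))
})

test_that("nucleus count is monotone in the acceptance thresholds", {
  f <- clean_field(n = 15, seed = 9, noise_sd = 0.02,
                   background_amplitude = 0.05)
  d <- dog_filter(f$channels$dapi)
  lab <- hybrid_watershed(d, kmeans_threshold(d)$mask, tolerance = 0.3)
  counts_i <- sapply(c(0, 0.2, 0.4, 0.5, 0.6), function(mi)
    max(filter_regions(lab, f$channels$dapi,
                       segmentation_params(min_mean_intensity = mi))))
  expect_true(all(diff(counts_i) <= 0))
  counts_a <- sapply(c(1, 40, 120, 250, 400), function(ma)
    max(filter_regions(lab, f$channels$dapi,
                       segmentation_params(min_region_area = ma))))
  expect_true(all(diff(counts_a) <= 0))
})

test_that("well-separated noise-free nuclei are recovered with accurate centroids", {
  f <- clean_field(n = 20, seed = 5)
  lab <- segment_nuclei(f$channels$dapi)
  expect_equal(max(lab), 20)
  rt <- region_table(lab)
  for (i in seq_len(20)) {
    d <- sqrt((rt$centroid_row - f$truth$center_row[i])^2 +
              (rt$centroid_col - f$truth$center_col[i])^2)
    expect_lt(min(d), 2)
  }
})

test_that("blank images raise the degenerate-threshold error", {
  expect_error(segment_nuclei(matrix(0.3, 64, 64)), "degenerate")
})

test_that("fused pairs are split back to the true cell count at zero noise", {
  f <- simulate_field(simulation_config(
    image_shape = c(320L, 320L), n_cells = 50, touching_fraction = 0.1,
    noise_sd = 0, background_amplitude = 0, seed = 17))
  cc <- EBImage::bwlabel(matrix(as.numeric(f$channels$dapi > 0.1), 320, 320))
  expect_lt(max(cc), 50)                   # fusion actually happened
  lab <- segment_nuclei(f$channels$dapi)
  expect_gt(max(lab), max(cc))             # the watershed split fused blobs
  expect_lte(abs(max(lab) - 50) / 50, 0.05)
})
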