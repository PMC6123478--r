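full_mask <- function(nr = 64, nc = 64) matrix(TRUE, nr, nc)

test_that("focus detection matches the planted ground truth at zero noise", {
  sc <- foci_scene(n_a = 10, n_b = 0, n_overlap = 0, noise_sd = 0,
                   seed = 81)
  im <- simulate_foci_image(sc)
  f <- detect_foci(im$channel_a, im$mask, threshold = 500)
  expect_equal(count_foci(f), 10)
  blank <- detect_foci(matrix(0, 64, 64), full_mask(), threshold = 10)
  expect_equal(count_foci(blank), 0)
  # threshold at/above the maximum yields an empty set, not an error
  high <- detect_foci(im$channel_a, im$mask,
                      threshold = max(im$channel_a))
  expect_equal(count_foci(high), 0)
  expect_error(detect_foci(im$channel_a, matrix(FALSE, 128, 128), 100),
               "empty")
})

test_that("raising the threshold never increases the focus count", {
  sc <- foci_scene(n_a = 15, n_b = 0, n_overlap = 0, noise_sd = 100,
                   seed = 82)
  im <- simulate_foci_image(sc)
  counts <- vapply(c(300, 600, 1200, 2400),
                   function(t) count_foci(detect_foci(im$channel_a,
                                                      im$mask, t)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("touching spots merge into a single connected component", {
  img <- matrix(0, 32, 32)
  img[10:14, 10:14] <- 100
  img[15, 15] <- 100          # diagonal touch: joined under 8-connectivity
  img[14:18, 15:19] <- 100
  f8 <- detect_foci(img, full_mask(32, 32), threshold = 50, min_area = 1)
  expect_equal(count_foci(f8), 1)
  img2 <- matrix(0, 32, 32)
  img2[5, 5] <- 100; img2[6, 6] <- 100
  f4 <- detect_foci(img2, full_mask(32, 32), threshold = 50, min_area = 1,
                    connectivity = 4)
  expect_equal(count_foci(f4), 2)
  expect_equal(count_foci(detect_foci(img2, full_mask(32, 32), 50,
                                      min_area = 1, connectivity = 8)), 1)
})

test_that("percent area covers the trivial geometric cases", {
  mask <- full_mask(20, 20)
  all_img <- matrix(100, 20, 20)
  f_all <- detect_foci(all_img, mask, threshold = 50, min_area = 1)
  expect_equal(percent_area(f_all, mask), 100)
  none <- detect_foci(matrix(0, 20, 20), mask, threshold = 50)
  expect_equal(percent_area(none, mask), 0)
  half_img <- matrix(0, 20, 20); half_img[, 1:10] <- 100
  f_half <- detect_foci(half_img, mask, threshold = 50, min_area = 1)
  expect_equal(percent_area(f_half, mask), 50)
})

test_that("colocalization percentages are exact on planted scenes", {
  sc <- foci_scene(n_a = 20, n_b = 12, n_overlap = 8, noise_sd = 0,
                   seed = 83)
  im <- simulate_foci_image(sc)
  fa <- detect_foci(im$channel_a, im$mask, 500)
  fb <- detect_foci(im$channel_b, im$mask, 500)
  expect_equal(percent_colocalized(fa, fb), 100 * im$truth$overlap_fraction)
  expect_equal(percent_colocalized(fa, fa), 100)
  expect_equal(percent_tif(fa, fb), percent_colocalized(fa, fb))
  # disjoint scene
  sc0 <- foci_scene(n_a = 8, n_b = 8, n_overlap = 0, noise_sd = 0,
                    seed = 84)
  im0 <- simulate_foci_image(sc0)
  fa0 <- detect_foci(im0$channel_a, im0$mask, 500)
  fb0 <- detect_foci(im0$channel_b, im0$mask, 500)
  expect_equal(percent_colocalized(fa0, fb0), 0)
  # all-overlap scene scores 100%
  sc1 <- foci_scene(n_a = 5, n_b = 5, n_overlap = 5, noise_sd = 0,
                    seed = 85)
  im1 <- simulate_foci_image(sc1)
  expect_equal(percent_colocalized(detect_foci(im1$channel_a, im1$mask, 500),
                                   detect_foci(im1$channel_b, im1$mask, 500)),
               100)
  # zero reference foci -> undefined
  empty <- detect_foci(matrix(0, 64, 64), full_mask(), 10)
  expect_true(is.na(percent_colocalized(empty, fb)))
})

test_that("adding partner foci never decreases colocalization", {
  sc <- foci_scene(n_a = 12, n_b = 10, n_overlap = 4, noise_sd = 0,
                   seed = 86)
  im <- simulate_foci_image(sc)
  fa <- detect_foci(im$channel_a, im$mask, 500)
  fb <- detect_foci(im$channel_b, im$mask, 500)
  base <- percent_colocalized(fa, fb)
  richer <- im$channel_b + im$channel_a   # partner now contains every a focus
  fb2 <- detect_foci(richer, im$mask, 500)
  expect_gte(percent_colocalized(fa, fb2), base)
  expect_equal(percent_colocalized(fa, fb2), 100)
})

test_that("planted overlap is recovered within 5 points under noise", {
  amp <- 3000
  hits <- vapply(1:5, function(i) {
    sc <- foci_scene(n_a = 20, n_b = 12, n_overlap = 8, amplitude = amp,
                     noise_sd = 0.2 * amp, seed = 860 + i)
    im <- simulate_foci_image(sc)
    fa <- detect_foci(im$channel_a, im$mask, 1500)
    fb <- detect_foci(im$channel_b, im$mask, 1500)
    percent_colocalized(fa, fb)
  }, 0)
  expect_true(all(abs(hits - 40) <= 5))
})

test_that("nucleus scoring emits the per-nucleus record under one config", {
  sc <- foci_scene(n_a = 15, n_b = 9, n_overlap = 6, noise_sd = 0,
                   seed = 87)
  im <- simulate_foci_image(sc)
  row <- score_nuclei(im$channel_a, im$channel_b, im$mask, 500, 500,
                      nucleus = 7L)
  expect_identical(names(row), c("nucleus", "channel_a_foci",
                                 "channel_b_foci", "pct_area_a",
                                 "pct_coloc", "pct_tif"))
  expect_equal(row$channel_a_foci, 15)
  expect_equal(row$channel_b_foci, 9)
  expect_equal(row$pct_coloc, 40)
  # identical-threshold policy: scoring twice is bit-identical
  expect_identical(row, score_nuclei(im$channel_a, im$channel_b, im$mask,
                                     500, 500, nucleus = 7L))
})

test_that("channel images and masks survive the 16-bit TIFF round trip", {
  sc <- foci_scene(n_a = 6, n_b = 3, n_overlap = 2, noise_sd = 30,
                   seed = 88)
  im <- simulate_foci_image(sc)
  p_img <- tempfile(fileext = ".tif"); p_mask <- tempfile(fileext = ".tif")
  on.exit(unlink(c(p_img, p_mask)))
  write_channel_image(im$channel_a, p_img)
  write_nucleus_mask(im$mask, p_mask)
  back <- read_channel_image(p_img)
  expect_equal(dim(back), dim(im$channel_a))
  expect_lt(max(abs(back - round(im$channel_a))), 1.5)  # 16-bit quantization
  expect_identical(read_nucleus_mask(p_mask), im$mask > 0)
})
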