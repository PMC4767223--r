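test_that("image statistics match hand-computed moments", {
  # [DERIVED] pixels {1,2,3,10}: mean 4; population var 12.5;
  # contrast sqrt(12.5)/4; skew = m3 / sd^3 with
  # m3 = mean((x-4)^3) = (-27 - 8 - 1 + 216)/4 = 45
  img <- matrix(c(1, 2, 3, 10), 2)
  st <- image_stats(img)
  expect_equal(st$mean, 4)
  expect_equal(st$contrast, sqrt(12.5) / 4, tolerance = 1e-12)
  expect_equal(st$skewness, 45 / 12.5^1.5, tolerance = 1e-12)
  expect_equal(st$n_pixels, 4L)
})

test_that("uniform and symmetric images follow the stated conventions", {
  # [TRIVIAL] uniform image: contrast 0 and skew 0 by convention
  st <- image_stats(matrix(0.5, 4, 4))
  expect_equal(st$contrast, 0)
  expect_equal(st$skewness, 0)
  # [TRIVIAL] equal counts of two values are symmetric: skew 0
  st2 <- image_stats(matrix(c(0.2, 0.8), 4, 4))
  expect_equal(st2$skewness, 0, tolerance = 1e-12)
  expect_error(image_stats(matrix(0, 2, 2)), class = "surfdecode_degenerate")
})

test_that("contrast and skew are scale invariant; mean scales linearly", {
  set.seed(14)
  img <- matrix(runif(64, 0.1, 0.9), 8)
  a <- image_stats(img)
  b <- image_stats(3 * img)
  expect_equal(b$mean, 3 * a$mean)
  expect_equal(b$contrast, a$contrast, tolerance = 1e-12)
  expect_equal(b$skewness, a$skewness, tolerance = 1e-12)
})

test_that("spectrum difference is zero for identical and translated images", {
  set.seed(15)
  img <- matrix(runif(32 * 32), 32)
  # [TRIVIAL] image paired with itself
  sd0 <- spectrum_difference(list(a = img, b = img))
  expect_equal(sd0$mean_difference, 0, tolerance = 1e-10)
  # [TRIVIAL] circular translation leaves the amplitude spectrum unchanged
  shifted <- img[c(9:32, 1:8), c(5:32, 1:4)]
  sd1 <- spectrum_difference(list(a = img, b = shifted))
  expect_equal(sd1$mean_difference, 0, tolerance = 1e-10)
})

test_that("sinusoidal gratings match a direct two-profile computation", {
  n <- 32
  g1 <- matrix(sin(2 * pi * 4 * (0:(n - 1)) / n), n, n)        # 4 cyc/img
  g2 <- matrix(sin(2 * pi * 8 * (0:(n - 1)) / n), n, n, byrow = TRUE)
  prof <- spectrum_profiles(list(f4 = g1, f8 = g2))
  p1 <- prof[prof$image == "f4", ]
  p2 <- prof[prof$image == "f8", ]
  # each grating's profile peaks at its own frequency
  expect_equal(p1$frequency[which.max(p1$log_amplitude)], 4L)
  expect_equal(p2$frequency[which.max(p2$log_amplitude)], 8L)
  # [DERIVED] direct oracle: RMS of the profile difference
  sdm <- spectrum_difference(list(f4 = g1, f8 = g2))
  expect_equal(sdm$pairwise$rms_difference,
               sqrt(mean((p1$log_amplitude - p2$log_amplitude)^2)),
               tolerance = 1e-12)
  expect_gt(sdm$mean_difference, 0)
})

test_that("spectrum difference is symmetric and validates sizes", {
  set.seed(16)
  imgs <- list(a = matrix(runif(64), 8), b = matrix(runif(64), 8),
               c = matrix(runif(64), 8))
  res <- spectrum_difference(imgs)
  expect_equal(nrow(res$pairwise), 3L)
  res_rev <- spectrum_difference(rev(imgs))
  expect_equal(sort(res$pairwise$rms_difference),
               sort(res_rev$pairwise$rms_difference), tolerance = 1e-12)
  expect_true(all(res$pairwise$rms_difference >= 0))
  expect_equal(res$mean_difference, mean(res$pairwise$rms_difference))
  expect_error(spectrum_difference(list(matrix(0.5, 4, 4), matrix(0.5, 5, 5))),
               "dimensions")
  expect_error(spectrum_difference(list(matrix(0.5, 4, 4))), "at least 2")
})
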