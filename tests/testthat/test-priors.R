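test_that("region statistics use the population divisor", {
  img <- matrix(c(100, 100, 100, 100), 2, 2)
  expect_equal(compute_region_stats(img, matrix(1, 2, 2))$mean, 100)
  expect_equal(compute_region_stats(img, matrix(1, 2, 2))$sd, 0)

  img2 <- matrix(c(90, 110, 5, 5), 2, 2)
  msk2 <- matrix(c(1, 1, 0, 0), 2, 2)
  st <- compute_region_stats(img2, msk2)
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 10)
  expect_equal(st$n_pixels, 2L)

  img3 <- matrix(c(1, 2, 3, 4), 2, 2)
  st3 <- compute_region_stats(img3, matrix(1, 2, 2))
  expect_equal(st3$mean, 2.5)
  expect_equal(st3$sd, sqrt(1.25))
})

test_that("degenerate or mismatched region inputs error", {
  img <- matrix(0, 3, 3)
  expect_error(compute_region_stats(img, matrix(0, 3, 3)), "degenerate")
  expect_error(compute_region_stats(img, matrix(1, 2, 2)), "shape")
})

test_that("two-branch density matches its closed forms at the landmarks", {
  s <- list(mean = 100, sd = 10)
  expect_equal(intensity_density(100, s), 1.0)
  expect_equal(intensity_density(120, s), exp(-2))
  expect_equal(intensity_density(80, s), exp(-2))
  expect_equal(intensity_density(130, s), -1.5)
})

test_that("density is non-increasing in |x - mean| over both branches", {
  for (sd_val in c(0.5, 3, 17)) {
    s <- list(mean = 50, sd = sd_val)
    x <- 50 + seq(0, 8 * sd_val, length.out = 400)
    d <- intensity_density(x, s)
    expect_true(all(diff(d) <= 1e-12))
    expect_equal(intensity_density(50 - (x - 50), s), d)
  }
})

test_that("sd = 0 samples use the exact-match limit convention", {
  s <- list(mean = 42, sd = 0)
  expect_equal(intensity_density(42, s), 1)
  expect_equal(intensity_density(45, s), -3)
})

test_that("votes count closed-interval membership over all entries", {
  fs <- feature_set(list(mean = 100, sd = 5, n_pixels = 1),
                    list(mean = 100, sd = 5, n_pixels = 1),
                    list(mean = 100, sd = 5, n_pixels = 1))
  expect_equal(density_votes(100, fs), c(affirmative = 3L, negative = 0L))

  fs2 <- feature_set(list(mean = 100, sd = 5, n_pixels = 1),
                     list(mean = 120, sd = 5, n_pixels = 1),
                     list(mean = 90, sd = 4, n_pixels = 1))
  expect_equal(density_votes(100, fs2), c(affirmative = 1L, negative = 2L))

  # interval endpoint is affirmative (closed interval)
  fs3 <- feature_set(list(mean = 100, sd = 5, n_pixels = 1))
  expect_equal(density_votes(110, fs3)[["affirmative"]], 1L)
})

test_that("voting resolution picks max on majority, min on tie or minority", {
  fs <- feature_set(list(mean = 100, sd = 10, n_pixels = 1))
  expect_equal(resolve_density(100, fs), 1.0)

  fs2 <- feature_set(list(mean = 100, sd = 10, n_pixels = 1),
                     list(mean = 100, sd = 10, n_pixels = 1),
                     list(mean = 200, sd = 10, n_pixels = 1))
  expect_equal(resolve_density(100, fs2), 1.0)

  fs3 <- feature_set(list(mean = 100, sd = 10, n_pixels = 1),
                     list(mean = 200, sd = 10, n_pixels = 1),
                     list(mean = 210, sd = 10, n_pixels = 1))
  expect_equal(resolve_density(100, fs3), -5.5)
})

test_that("resolution agrees with the brute-force oracle on random cases", {
  set.seed(4821)
  for (rep in 1:300) {
    fs <- random_feature_set(sample(1:9, 1))
    x <- runif(1, 20, 240)
    expect_identical(resolve_density(x, fs), oracle_resolve(x, fs))
  }
})

test_that("duplicating a winning-side entry never flips the resolution side", {
  set.seed(91)
  for (rep in 1:100) {
    fs <- random_feature_set(sample(2:7, 1))
    x <- runif(1, 40, 210)
    v <- density_votes(x, fs)
    majority <- v[["affirmative"]] > v[["negative"]]
    for (i in seq_len(nrow(fs))) {
      agrees <- oracle_inside(x, fs$mean[i], fs$sd[i]) == majority
      if (!agrees) next
      fs2 <- fs_append(fs, list(mean = fs$mean[i], sd = fs$sd[i],
                                n_pixels = fs$n_pixels[i]))
      v2 <- density_votes(x, fs2)
      expect_identical(v2[["affirmative"]] > v2[["negative"]], majority)
    }
  }
})

test_that("gaussian samples fall in the 2-sigma interval at the normal rate", {
  set.seed(7)
  x <- rnorm(40000, 100, 9)
  frac <- mean(abs(x - 100) <= 18)
  expect_lt(abs(frac - 0.9545), 0.01)
})

test_that("probability map applies resolution pixel-wise with a 0 sentinel", {
  fs <- feature_set(list(mean = 100, sd = 10, n_pixels = 4))
  img <- matrix(100, 4, 4)
  mask <- matrix(0, 4, 4); mask[2:3, 2:3] <- 1
  pm <- probability_map(img, mask, fs)
  expect_equal(pm[mask != 0], rep(1, 4))
  expect_equal(pm[mask == 0], rep(0, 12))

  set.seed(5)
  img2 <- matrix(runif(9, 50, 150), 3, 3)
  fs2 <- random_feature_set(3)
  pm2 <- probability_map(img2, matrix(1, 3, 3), fs2)
  for (i in seq_len(9)) {
    expect_identical(pm2[i], oracle_resolve(img2[i], fs2))
  }
})

test_that("object interior scores above far-outlier background in the map", {
  fs <- feature_set(list(mean = 150, sd = 8, n_pixels = 100))
  img <- matrix(90, 10, 10)
  img[4:7, 4:7] <- 150
  pm <- probability_map(img, matrix(1, 10, 10), fs)
  expect_true(min(pm[img == 150]) > max(pm[img == 90]))
})

test_that("feature sets grow in order, window-cap, and round-trip as text", {
  fs <- feature_set(list(mean = 1, sd = 2, n_pixels = 3))
  fs <- fs_append(fs, list(mean = 4, sd = 5, n_pixels = 6))
  fs <- fs_append(fs, list(mean = 7, sd = 8, n_pixels = 9))
  expect_equal(fs$mean, c(1, 4, 7))
  capped <- fs_append(fs, list(mean = 10, sd = 11, n_pixels = 12),
                      window = 2)
  expect_equal(capped$mean, c(7, 10))

  path <- tempfile(fileext = ".txt")
  write_feature_set(fs, path)
  fs2 <- read_feature_set(path)
  expect_equal(as.data.frame(fs2), as.data.frame(fs))
  unlink(path)
})
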