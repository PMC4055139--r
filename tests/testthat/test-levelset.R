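test_that("double-well potential has its wells and midpoint value", {
  expect_equal(double_well_p(0), 0)
  expect_equal(double_well_p(1), 0)
  expect_equal(double_well_p(0.5), 2 / (2 * pi)^2)
  # continuity and differentiability across the branch point
  eps <- 1e-7
  expect_lt(abs(double_well_p(1 + eps) - double_well_p(1 - eps)), 1e-10)
  s <- seq(0, 3, by = 0.01)
  expect_true(all(double_well_p(s) >= 0))
})

test_that("diffusion rate d_p fills the removable singularity", {
  expect_equal(d_p(0), 1)
  expect_equal(d_p(1e-12), 1)
  expect_equal(d_p(1), 0)
  expect_equal(d_p(2), 0.5)
  # negative (backward diffusion) between the wells
  expect_lt(d_p(0.75), 0)
})

test_that("smoothed delta and heaviside have the stated support and mass", {
  expect_equal(dirac_eps(0, 1.5), 2 / 3)
  expect_equal(dirac_eps(1.5, 1.5), 0)
  expect_equal(dirac_eps(-1.5, 1.5), 0)
  expect_equal(dirac_eps(2.5, 1.5), 0)
  expect_equal(heaviside_eps(0, 1.5), 0.5)
  expect_equal(heaviside_eps(-1.5, 1.5), 0)
  expect_equal(heaviside_eps(1.5, 1.5), 1)
  expect_equal(heaviside_eps(-9, 1.5), 0)
  expect_equal(heaviside_eps(9, 1.5), 1)

  for (eps in c(0.5, 1.5, 4)) {
    x <- seq(-eps, eps, length.out = 20001)
    quad <- sum((dirac_eps(x[-1], eps) + dirac_eps(x[-length(x)], eps)) / 2) *
      diff(x)[1]
    expect_lt(abs(quad - 1), 1e-6)
  }
})

test_that("edge indicator is 1 on flat images and dips on a step edge", {
  flat <- matrix(7, 20, 20)
  expect_true(all(edge_indicator(flat, 1.5) == 1))

  step <- matrix(0, 30, 30); step[, 16:30] <- 100
  g <- edge_indicator(step, 1.5)
  expect_true(all(g > 0 & g <= 1))
  mins <- apply(g, 1, which.min)
  expect_true(all(abs(mins - 15.5) <= 2))
})

test_that("phase-2 evolution equals phase-1 with the balloon removed", {
  set.seed(2)
  phi <- init_lsf(make_disk(40, 20, 20, 9), 2)
  img <- matrix(runif(1600, 80, 160), 40, 40)
  g <- edge_indicator(img, 1.5)
  pmap <- matrix(runif(1600, -1, 1), 40, 40)
  p <- evolution_params(mu = 0.04, alpha = 0, lambda = 2, dt = 5, iters = 5)
  a <- evolve_phase1(phi, pmap, g, p)
  b <- evolve_phase2(phi, g, p)
  expect_identical(a[, ], b[, ])
})

test_that("negating alpha and the probability map leaves the update invariant", {
  set.seed(8)
  phi <- init_lsf(make_disk(40, 20, 20, 8), 2)
  g <- matrix(runif(1600, 0.2, 1), 40, 40)
  pmap <- matrix(runif(1600, -1, 1), 40, 40)
  p_pos <- evolution_params(mu = 0.04, alpha = -1, lambda = 2, dt = 5,
                            iters = 4)
  p_neg <- evolution_params(mu = 0.04, alpha = 1, lambda = 2, dt = 5,
                            iters = 4)
  a <- evolve_phase1(phi, pmap, g, p_pos)
  b <- evolve_phase1(phi, -pmap, g, p_neg)
  expect_identical(a[, ], b[, ])
})

test_that("evolution is translation-equivariant away from the borders", {
  set.seed(13)
  n <- 56; dr <- 4; dc <- 6
  img <- matrix(runif(n * n, 80, 160), n, n)
  mask <- make_disk(n, 22, 20, 8)
  img_s <- img; img_s[] <- 0
  img_s[(1 + dr):n, (1 + dc):n] <- img[1:(n - dr), 1:(n - dc)]
  mask_s <- mask; mask_s[] <- 0
  mask_s[(1 + dr):n, (1 + dc):n] <- mask[1:(n - dr), 1:(n - dc)]
  fs <- feature_set(list(mean = 120, sd = 15, n_pixels = 50))
  p <- evolution_params(mu = 0.04, alpha = -1, lambda = 2, dt = 5, iters = 4)
  run <- function(im, mk) {
    g <- edge_indicator(im, 1.5)
    pm <- probability_map(im, matrix(1, n, n), fs)
    evolve_phase1(init_lsf(mk, 2), pm, g, p)
  }
  a <- run(img, mask)
  b <- run(img_s, mask_s)
  core_a <- a[16:(n - dr - 16), 16:(n - dc - 16)]
  core_b <- b[(16 + dr):(n - 16), (16 + dc):(n - 16)]
  expect_equal(core_a, core_b, tolerance = 1e-12)
})

test_that("the regularizer rebuilds a unit-slope profile near the zero set", {
  phi <- init_lsf(make_disk(64, 32, 32, 14), 2)
  p <- evolution_params(mu = 0.04, alpha = 0, lambda = 0, dt = 5, iters = 30)
  phi2 <- evolve_phase1(phi, matrix(0, 64, 64), matrix(1, 64, 64), p)
  band <- abs(phi2) <= 1.5
  gm <- grad_mag(phi2)
  expect_gt(mean(gm[band]), 0.8)
  expect_lt(mean(gm[band]), 1.2)
})

test_that("pure curvature flow with g = 1 shrinks a circle", {
  phi <- init_lsf(make_disk(64, 32, 32, 16), 2)
  g1 <- matrix(1, 64, 64)
  p <- evolution_params(mu = 0.04, alpha = 0, lambda = 2, dt = 5, iters = 30)
  phi2 <- evolve_phase2(phi, g1, p)
  expect_lt(sum(phi2 < 0), sum(phi < 0))
})

test_that("evolution stays finite over long runs at the stability bound", {
  phi <- init_lsf(make_disk(64, 32, 32, 12), 2)
  img <- matrix(100, 64, 64); img[make_disk(64, 32, 32, 12) != 0] <- 160
  g <- edge_indicator(img, 1.5)
  pmap <- matrix(0.5, 64, 64)
  p <- evolution_params(mu = 0.04, alpha = -1, lambda = 3, dt = 5,
                        iters = 500)
  expect_silent(phi2 <- evolve_phase1(phi, pmap, g, p))
  expect_true(all(is.finite(phi2)))
})

test_that("parameter validation enforces the stability product", {
  expect_error(evolution_params(mu = 0.2, dt = 5), "stability")
  expect_error(evolution_params(mu = 0.3, dt = 1), "stability")
  expect_silent(evolution_params(mu = 0.2, dt = 1))
})

test_that("field thresholding recovers regions and flags empty interiors", {
  r <- make_disk(20, 10, 10, 5)
  expect_identical(field_to_mask(init_lsf(r, 2)), r)
  expect_warning(m <- field_to_mask(matrix(2, 5, 5)), "empty")
  expect_equal(sum(m), 0)
  set.seed(31)
  phi <- matrix(rnorm(100), 10, 10)
  expect_identical(field_to_mask(phi), matrix(as.numeric(phi < 0), 10, 10))
})
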