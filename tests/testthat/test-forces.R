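test_that("gaussian kernels are normalized with the documented default size", {
  k <- gaussian_kernel(3)
  expect_equal(k$size, 13L)
  expect_equal(sum(k$k1d), 1)
  expect_equal(k$k1d, rev(k$k1d))
  expect_error(gaussian_kernel(-1), "sigma")
  expect_error(gaussian_kernel(2, size = 4), "odd")
})

test_that("separable convolution matches the brute-force 2D oracle", {
  for (seed in 1:3) {
    x <- rand_field(12, 12, scale = 255, seed = seed)
    kern <- gaussian_kernel(1.5)
    expect_lt(max(abs(erbls:::conv_gauss(x, kern) - oracle_conv(x, kern))),
              1e-10)
  }
})

test_that("conv cache holds the two contour-independent convolutions", {
  img <- matrix(1, 10, 12)
  kern <- gaussian_kernel(2)
  cache <- build_conv_cache(img, kern)
  # ones image: g*I equals g*1, and both are exactly 1 under reflect padding
  expect_equal(cache$g_conv_I, cache$g_conv_ones)
  expect_equal(max(abs(cache$g_conv_ones - 1)), 0, tolerance = 1e-12)
  x <- rand_field(12, 12, scale = 100, seed = 9)
  cache <- build_conv_cache(x, kern)
  expect_lt(max(abs(cache$g_conv_I - oracle_conv(x, kern))), 1e-10)
})

test_that("edge detecting function is 1 on flat images and dips at edges", {
  edf <- compute_edf(matrix(42, 9, 9), sigma_g = 2)
  expect_equal(edf$values, matrix(1, 9, 9))
  # vertical step: minimum on the step, ~1 far away
  img <- cbind(matrix(50, 20, 10), matrix(200, 20, 10))
  edf <- compute_edf(img, sigma_g = 1)
  expect_true(all(apply(edf$values, 1, which.min) %in% 10:11))
  expect_gt(min(edf$values[, c(1:3, 18:20)]), 0.98)
  expect_error(compute_edf(img, sigma_g = 0), "sigma_g")
})

test_that("edge detecting function matches a compositional oracle", {
  img <- rand_field(16, 16, scale = 255, seed = 4)
  sg <- 1.2
  edf <- compute_edf(img, sg)
  g <- oracle_grad(oracle_conv(img, gaussian_kernel(sg)))
  expect_lt(max(abs(edf$values - 1 / (1 + sqrt(g$gy^2 + g$gx^2)))), 1e-10)
  expect_true(all(edf$values > 0 & edf$values <= 1))
})

test_that("local means recover phase intensities under a hard partition", {
  tp <- two_phase()
  phi <- ifelse(tp$mask, 1e12, -1e12)   # H numerically 0/1
  cache <- build_conv_cache(tp$image, gaussian_kernel(3))
  lm <- suppressWarnings(local_means(tp$image, phi, cache))
  interior <- disc_sdf(c(40, 40), 20, 20, 12) > 7
  exterior <- disc_sdf(c(40, 40), 20, 20, 12) < -7
  expect_lt(max(abs(lm$c1[interior] - 200)), 1e-6)
  expect_lt(max(abs(lm$c2[exterior] - 50)), 1e-6)
  # weighted means stay within the image range everywhere
  expect_true(all(lm$c1 >= 50 - 1e-9 & lm$c1 <= 200 + 1e-9))
  expect_true(all(lm$c2 >= 50 - 1e-9 & lm$c2 <= 200 + 1e-9))
})

test_that("degenerate all-inside field falls back to global means with warning", {
  tp <- two_phase()
  cache <- build_conv_cache(tp$image, gaussian_kernel(3))
  phi <- matrix(1e13, 40, 40)
  expect_warning(lm <- local_means(tp$image, phi, cache), "outside phase")
  # everything inside: c1 is the local mean of I, c2 the global mean fallback
  expect_lt(max(abs(lm$c1 - cache$g_conv_I)), 1e-4)
  expect_lt(max(abs(lm$c2 - mean(tp$image))), 1e-6)
})

test_that("two-convolution cached path equals the naive four-convolution path", {
  img <- rand_field(14, 14, scale = 255, seed = 11)
  phi <- rand_field(14, 14, scale = 4, seed = 12) - 2
  kern <- gaussian_kernel(2)
  cache <- build_conv_cache(img, kern)
  lm <- local_means(img, phi, cache)
  # naive path: four independent convolutions, no cache algebra
  H <- heaviside_reg(phi, 1)
  c1_naive <- erbls:::conv_gauss(img * H, kern) / erbls:::conv_gauss(H, kern)
  c2_naive <- erbls:::conv_gauss(img * (1 - H), kern) /
    erbls:::conv_gauss(1 - H, kern)
  expect_lt(max(abs(lm$c1 - c1_naive)), 1e-10)
  expect_lt(max(abs(lm$c2 - c2_naive)), 1e-10)
})

test_that("exactly two convolutions are performed per local_means call", {
  img <- rand_field(14, 14, scale = 255, seed = 2)
  phi <- box_phi(c(14, 14), c(4, 9), c(5, 10))
  cache <- build_conv_cache(img, gaussian_kernel(3))
  conv_count_reset()
  invisible(local_means(img, phi, cache))
  expect_identical(conv_count(), 2L)
  conv_count_reset()
})

test_that("rdf is positive inside a bright object and negative outside", {
  tp <- two_phase()
  phi <- ifelse(tp$mask, 1e13, -1e13)
  cache <- build_conv_cache(tp$image, gaussian_kernel(3))
  lm <- suppressWarnings(local_means(tp$image, phi, cache))
  rdf <- compute_rdf(tp$image, lm)
  sdf <- disc_sdf(c(40, 40), 20, 20, 12)
  expect_true(all(rdf$values[sdf > 7] > 0))
  expect_true(all(rdf$values[sdf < -7] < 0))
  expect_equal(max(abs(rdf$values)), 1)
})

test_that("rdf magnitude is larger deep in homogeneous phases than at the boundary", {
  tp <- two_phase()
  phi <- ifelse(tp$mask, 1e13, -1e13)
  cache <- build_conv_cache(tp$image, gaussian_kernel(3))
  lm <- suppressWarnings(local_means(tp$image, phi, cache))
  rdf <- compute_rdf(tp$image, lm)
  sdf <- disc_sdf(c(40, 40), 20, 20, 12)
  deep <- abs(sdf) > 7
  band <- abs(sdf) < 2
  expect_gt(min(abs(rdf$raw[deep])), max(abs(rdf$raw[band])) * 0.99)
})

test_that("rdf vanishes identically on a constant image", {
  img <- matrix(120, 12, 12)
  phi <- box_phi(c(12, 12), c(3, 8), c(4, 9))
  cache <- build_conv_cache(img, gaussian_kernel(2))
  lm <- local_means(img, phi, cache)
  rdf <- compute_rdf(img, lm)
  expect_equal(rdf$values, matrix(0, 12, 12))
})

test_that("rdf normalization peak is exactly 1 or the field is all zero", {
  for (seed in 1:5) {
    img <- rand_field(11, 13, scale = 255, seed = seed)
    phi <- rand_field(11, 13, scale = 6, seed = seed + 50) - 3
    cache <- build_conv_cache(img, gaussian_kernel(2))
    rdf <- compute_rdf(img, local_means(img, phi, cache))
    expect_true(max(abs(rdf$values)) %in% c(0, 1))
    expect_true(all(abs(rdf$values) <= 1))
  }
})

test_that("rdf sign pattern survives a smooth multiplicative bias field", {
  tp <- two_phase()
  withr::with_seed(5, {
    yy <- matrix(seq_len(40), 40, 40)
    xx <- t(yy)
    bias <- 1 + 0.5 * cos(2 * pi * xx / 55 + 1) * cos(2 * pi * yy / 70)
  })
  expect_true(min(bias) >= 0.5 && max(bias) <= 1.5)
  phi <- ifelse(tp$mask, 1e13, -1e13)
  sdf <- disc_sdf(c(40, 40), 20, 20, 12)
  signs <- lapply(list(tp$image, tp$image * bias), function(img) {
    cache <- build_conv_cache(img, gaussian_kernel(3))
    lm <- suppressWarnings(local_means(img, phi, cache))
    rdf <- compute_rdf(img, lm)
    sign(rdf$values[abs(sdf) > 7])
  })
  expect_identical(signs[[1]], signs[[2]])
})
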