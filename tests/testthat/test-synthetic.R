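test_that("disc rasterization matches a per-pixel counting oracle", {
  spec <- phantom_spec(c(100, 100), shape_disc(c(50, 50), 20))
  ph <- generate_phantom(spec)
  cnt <- 0L
  for (i in 1:100) for (j in 1:100)
    if ((i - 50)^2 + (j - 50)^2 <= 400) cnt <- cnt + 1L
  expect_identical(sum(ph$mask), cnt)
  expect_setequal(unique(as.vector(ph$image)), c(50, 200))
  expect_identical(ph$mask, ph$image > 125)
})

test_that("intensity degradations leave the ground-truth mask untouched", {
  base <- phantom_spec(c(80, 80), shape_disc(c(40, 40), 18))
  degraded <- phantom_spec(c(80, 80), shape_disc(c(40, 40), 18),
                           bias_amplitude = 0.4, blur_sigma = 2,
                           noise_sigma = 10, gap = 0.2, seed = 8)
  expect_identical(generate_phantom(base)$mask, generate_phantom(degraded)$mask)
  img <- generate_phantom(degraded)$image
  expect_gt(length(unique(as.vector(img))), 2)
})

test_that("generation is a pure function of the spec", {
  spec <- phantom_spec(c(60, 60), shape_disc(c(30, 30), 15),
                       bias_amplitude = 0.3, noise_sigma = 12, seed = 41)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  # generation must not disturb the session RNG stream
  withr::with_seed(1, {
    r1 <- runif(1)
    invisible(generate_phantom(spec))
    r2 <- runif(1)
  })
  withr::with_seed(1, r_ref <- runif(2))
  expect_identical(c(r1, r2), r_ref)
})

test_that("bias field multiplies intensities within the stated amplitude", {
  spec <- phantom_spec(c(80, 80), shape_disc(c(40, 40), 18),
                       bias_amplitude = 0.4, seed = 3)
  ph <- generate_phantom(spec)
  ratio <- ph$image / (50 + 150 * ph$mask)
  expect_gte(min(ratio), 0.6)
  expect_lte(max(ratio), 1.4)
})

test_that("the boundary gap removes the sharp edge but preserves phases", {
  spec <- phantom_spec(c(100, 100), shape_disc(c(50, 50), 25),
                       gap = 0.2, gap_angle = 0)
  ph <- generate_phantom(spec)
  yy <- matrix(1:100, 100, 100); xx <- t(yy)
  theta <- (atan2(yy - 50, xx - 50)) %% (2 * pi)
  d <- sqrt((yy - 50)^2 + (xx - 50)^2)
  in_gap <- theta < 2 * pi * 0.2
  gap_core <- theta > 0.2 & theta < 2 * pi * 0.2 - 0.2  # off sector borders
  ring <- abs(d - 25) < 1
  # gradient across the rim is much weaker inside the gap sector
  g <- gradient_c(ph$image)
  gm <- sqrt(g$gy^2 + g$gx^2)
  expect_lt(max(gm[ring & gap_core]), 25)
  expect_gt(max(gm[ring & !in_gap]), 70)
  # deep interior and exterior intensities are unchanged
  expect_true(all(ph$image[d < 8] == 200))
  expect_true(all(ph$image[d > 45] == 50))
})

test_that("out-of-frame objects are rejected", {
  expect_error(phantom_spec(c(50, 50), shape_disc(c(25, 45), 10)), "frame")
  expect_error(phantom_spec(c(50, 50), shape_disc(c(25, 25), 10),
                            fg_level = 80, bg_level = 80), "differ")
})

test_that("the fixture suite has the seven canonical members", {
  suite <- fixture_suite(1)
  expect_length(suite, 7)
  expect_setequal(names(suite),
                  c("clean-disc", "bias-disc", "blurred-disc",
                    "gap-outline-disc", "two-disc", "drifting-disc",
                    "vertebra-phantom"))
  for (nm in setdiff(names(suite), "drifting-disc")) {
    expect_gt(sum(suite[[nm]]$mask), 0)
    expect_identical(dim(suite[[nm]]$image), dim(suite[[nm]]$mask))
  }
  expect_length(suite[["drifting-disc"]]$images, 9)
  expect_length(suite[["drifting-disc"]]$masks, 9)
  expect_equal(n_components(suite[["two-disc"]]$mask), 2)
})

test_that("the vertebra phantom is one component with >= 3 convexity defects", {
  skip_if_not_installed("pracma")
  mask <- fixture_suite(1)[["vertebra-phantom"]]$mask
  expect_equal(n_components(mask), 1)
  pts <- which(mask, arr.ind = TRUE)
  hull <- pts[grDevices::chull(pts), ]
  yy <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  xx <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  inside <- matrix(pracma::inpolygon(as.vector(yy), as.vector(xx),
                                     hull[, 1], hull[, 2]),
                   nrow(mask), ncol(mask))
  defects <- inside & !mask
  sizes <- tabulate(EBImage::bwlabel(defects * 1))
  expect_gte(sum(sizes >= 30), 3)
})
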