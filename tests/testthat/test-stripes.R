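test_that("block-mean downsampling preserves means and handles errors", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(downsample(img, 5.2, 5.2), img)
  d <- downsample(img, 5.2, 10.4)
  expect_equal(dim(d), c(32L, 32L))
  expect_equal(mean(d), mean(img))
  expect_equal(d[1, 1], mean(img[1:2, 1:2]))
  # checkerboard of period 2 collapses to its mean
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_equal(downsample(cb, 1, 2), matrix(0.5, 8, 8))
  expect_error(downsample(img, 10.4, 5.2), ">=")
  expect_error(downsample(img, 1, 2.5), "integer")
})

test_that("stripe/destriped decomposition is exact and directional", {
  with_test_seed(31, {
    img <- matrix(rnorm(96 * 96), 96, 96)
  })
  iso <- isolate_stripes(img, "parallel")
  expect_equal(iso$stripe_image + iso$destriped_image, img,
               tolerance = 1e-10)
  # constant image: no stripe content (DC excluded)
  cc <- matrix(7, 64, 64)
  expect_equal(max(abs(isolate_stripes(cc, "parallel")$stripe_image)), 0,
               tolerance = 1e-10)
  # horizontal-stripe sinusoid (constant along rows): >= 99% of AC
  # energy captured by the parallel wedge
  s <- matrix(sin(2 * pi * 24 * (1:96) / 96), 96, 96)
  iso_s <- isolate_stripes(s, "parallel")
  expect_gte(sum(iso_s$stripe_image^2) / sum(s^2), 0.99)
  # and essentially none by the perpendicular control
  iso_p <- isolate_stripes(s, "perpendicular")
  expect_lt(sum(iso_p$stripe_image^2) / sum(s^2), 0.01)
  expect_error(isolate_stripes(matrix(c(1, NA, 3, 4), 2)), "non-finite")
})

test_that("white-noise stripe energy is direction-symmetric", {
  with_test_seed(77, {
    fr <- replicate(20, {
      img <- matrix(rnorm(64 * 64), 64, 64)
      c(sum(isolate_stripes(img, "parallel")$stripe_image^2),
        sum(isolate_stripes(img, "perpendicular")$stripe_image^2)) /
        sum((img - mean(img))^2)
    })
  })
  d <- fr[1, ] - fr[2, ]
  expect_lt(abs(mean(d)), 3 * stats::sd(d))
})

test_that("rotation equivariance: parallel on rotated = perpendicular", {
  with_test_seed(17, {
    img <- matrix(rnorm(80 * 80), 80, 80)
  })
  a <- isolate_stripes(t(img), "parallel")$stripe_image
  b <- isolate_stripes(img, "perpendicular")$stripe_image
  expect_equal(t(a), b, tolerance = 1e-10)
})

test_that("binarization is monotone in level and empty for zero stripes", {
  ph <- test_phantom()
  sl <- render_slice(ph, 1, acquisition_config(
    obstacles = place_edge_obstacles(ph, 4, 25, 0, seed = 2), seed = 1))
  bm <- sl$brain_mask_slice
  ref <- sl$gauss_image
  iso <- isolate_stripes(ref, "parallel")
  m1 <- binarize_stripe_mask(iso$stripe_image, bm, ref, level = 0.4)
  m2 <- binarize_stripe_mask(iso$stripe_image, bm, ref, level = 0.6)
  m3 <- binarize_stripe_mask(iso$stripe_image, bm, ref, level = 0.8)
  expect_true(all(m2 | !m3))  # m3 subset of m2
  expect_true(all(m1 | !m2))
  z <- binarize_stripe_mask(matrix(0, nrow(bm), ncol(bm)), bm, ref)
  expect_equal(sum(z), 0)
  expect_error(binarize_stripe_mask(iso$stripe_image, bm & FALSE, ref),
               "empty")
})

test_that("stripe fraction arithmetic is exact", {
  brain <- matrix(TRUE, 10, 10)
  expect_equal(stripe_fraction(brain, brain), 100)
  expect_equal(stripe_fraction(brain & FALSE, brain), 0)
  half <- brain; half[, 6:10] <- FALSE
  expect_equal(stripe_fraction(half, brain), 50)
  expect_error(stripe_fraction(half, brain & FALSE), "empty")
})

test_that("estimator recovers ground-truth fractions within 3 points", {
  ph <- test_phantom()
  err <- c()
  for (target in c(5, 20, 40)) {
    for (s in 1:2) {
      of <- obstacles_for_fraction(ph, target, acquisition_config(),
                                   radius_um = 20, seed = 100 * s + target)
      cfg <- acquisition_config(obstacles = of$obstacles, seed = s)
      sl <- render_slice(ph, 2, cfg)
      truth <- 100 * sum(sl$gauss_shadow_mask) / sum(sl$brain_mask_slice)
      res <- analyze_slice_stripes(sl$gauss_image, sl$brain_mask_slice)
      err <- c(err, res$fraction_parallel - truth)
    }
  }
  expect_lte(mean(abs(err)), 3)
})

test_that("parallel detection dominates the perpendicular control", {
  ph <- test_phantom()
  of <- obstacles_for_fraction(ph, 20, acquisition_config(),
                               radius_um = 20, seed = 7)
  cfg <- acquisition_config(obstacles = of$obstacles, seed = 1,
                            noise = FALSE)
  sl <- render_slice(ph, 2, cfg)
  res <- analyze_slice_stripes(sl$gauss_image, sl$brain_mask_slice)
  expect_gte(res$fraction_parallel,
             5 * max(res$fraction_perpendicular, 1e-9))
})

test_that("volume summary recovers the generating Gaussian", {
  with_test_seed(101, {
    fr <- rnorm(5000, 16.4, 6.3)
  })
  s <- volume_striping_summary(fr)
  expect_equal(s$peak, 16.4, tolerance = 0.05)
  expect_equal(s$sd, 6.3, tolerance = 0.05)
  # exactly Gaussian-shaped histogram: parameters back to ~1e-6
  x <- seq(0, 40, length.out = 4000)
  w <- exp(-(x - 16.4)^2 / (2 * 6.3^2))
  samples <- rep(x, times = round(1e4 * w))
  s2 <- volume_striping_summary(samples)
  expect_equal(s2$peak, 16.4, tolerance = 1e-3)
  expect_equal(s2$sd, 6.3, tolerance = 2e-2)
  expect_warning(s3 <- volume_striping_summary(rep(10, 50)), "identical")
  expect_equal(s3$peak, 10)
  expect_equal(s3$sd, 0)
  expect_error(volume_striping_summary(1:5), "at least 10")
})

test_that("quantify_stripes downsamples to the working pitch", {
  ph <- test_phantom()
  of <- obstacles_for_fraction(ph, 20, acquisition_config(),
                               radius_um = 30, seed = 7)
  cfg <- acquisition_config(obstacles = of$obstacles, seed = 1)
  sl <- render_slice(ph, 2, cfg)
  # render at 5.2 um by upsampling 2x: block-mean path must engage
  up <- sl$gauss_image[rep(1:192, each = 2), rep(1:256, each = 2)]
  bup <- sl$brain_mask_slice[rep(1:192, each = 2), rep(1:256, each = 2)]
  stack <- image_stack(array(up, c(384, 512, 1)), 5.2)
  rep1 <- quantify_stripes(stack, array(bup, c(384, 512, 1)))
  truth <- 100 * sum(sl$gauss_shadow_mask) / sum(sl$brain_mask_slice)
  expect_equal(rep1$fraction_parallel, truth, tolerance = 0.35)
})
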