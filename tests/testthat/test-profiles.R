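test_that("column profiles average masked rows and drop empty columns", {
  img <- matrix(5, 10, 8)
  p <- column_profile(img)
  expect_equal(p$values, rep(5, 8))
  # separable image: profile proportional to the column factor
  u <- runif(10); v <- runif(8)
  ps <- column_profile(outer(u, v))
  expect_equal(ps$values, mean(u) * v)
  # single-row mask returns that row
  m <- matrix(FALSE, 10, 8); m[3, ] <- TRUE
  expect_equal(column_profile(img * 2, m)$values, rep(10, 8))
  # columns with no masked rows are dropped and flagged
  m2 <- matrix(TRUE, 10, 8); m2[, 4] <- FALSE
  p2 <- column_profile(img, m2)
  expect_equal(p2$positions, setdiff(1:8, 4))
  expect_equal(attr(p2, "dropped"), 4L)
})

test_that("profile difference is relative, symmetric, and guarded", {
  g <- c(1, 1, 0.8, 1, 0.8, 1)
  b <- rep(1, 6)
  mk <- function(g, b) structure(
    list(positions = seq_along(g), gauss_profile = g, bessel_profile = b,
         shift = 0L, normalization = "mode-ratio"),
    class = "profile_pair")
  d <- profile_difference(mk(g, b), normalize = FALSE)
  expect_equal(d, c(0, 0, 0.2, 0, 0.2, 0))
  # symmetry under channel swap
  expect_equal(profile_difference(mk(b, g), normalize = FALSE), d)
  # identical profiles: zero everywhere, with or without gain matching
  expect_equal(profile_difference(mk(b, b)), rep(0, 6))
  # gain mismatch is absorbed by normalization
  d2 <- profile_difference(mk(2 * b, b))
  expect_equal(d2, rep(0, 6), tolerance = 1e-9)
  expect_error(profile_difference(mk(rep(0, 6), b)), "zero")
})

test_that("barcode thresholds and sweep are monotone", {
  d <- c(rep(0.2, 4), rep(0, 6))
  expect_equal(barcode(d, 0.05)$affected_percent, 40)
  expect_equal(barcode(d, 0.25)$affected_percent, 0)
  expect_equal(barcode(rep(0, 10), 0.01)$affected_percent, 0)
  # monotone non-increasing for arbitrary inputs
  with_test_seed(9, {
    for (i in 1:100) {
      dd <- abs(rnorm(50, 0, 0.2))
      g <- 1 + abs(rnorm(50)); b <- g * (1 - dd)
      pair <- structure(list(positions = 1:50, gauss_profile = g,
                             bessel_profile = pmax(b, 1e-6), shift = 0L,
                             normalization = "mode-ratio"),
                        class = "profile_pair")
      curve <- threshold_sweep(pair, seq(0.02, 0.3, by = 0.04))
      expect_true(all(diff(curve$affected_percent) <= 0))
    }
  })
})

test_that("alignment recovers an integer profile shift", {
  with_test_seed(23, {
    base <- abs(rnorm(120)) + 1
  })
  img_g <- matrix(rep(base, each = 30), 30, 120)
  shift <- 4L
  img_b <- img_g[, c((shift + 1):120, 1:shift)]
  pair <- profile_pair(img_g, img_b, align = TRUE, max_shift = 8)
  expect_equal(abs(pair$shift), shift)
  d <- profile_difference(pair)
  expect_lt(stats::median(d), 0.02)
})

test_that("constructed stripes of known depth and coverage are recovered", {
  ph <- test_phantom()
  for (f in c(10, 30, 50)) {
    of <- obstacles_for_row_fraction(ph, f, radius_um = 20,
                                     transmittance = 0.7, seed = 10 + f)
    cfg <- acquisition_config(obstacles = of$obstacles, seed = 2,
                              bessel_haze_fraction = 0)
    sl <- render_slice(ph, 2, cfg)
    pair <- profile_pair(t(sl$gauss_image), t(sl$bessel_image),
                         t(sl$brain_mask_slice), align = FALSE)
    bc <- barcode(profile_difference(pair), 0.05)
    expect_lt(abs(bc$affected_percent - of$achieved_pct), 4)
  }
})

test_that("null pairs stay under 2% affected at the 5% threshold", {
  ph <- test_phantom()
  sl_a <- render_slice(ph, 2, acquisition_config(seed = 11))
  sl_b <- render_slice(ph, 2, acquisition_config(seed = 99))
  pair <- profile_pair(t(sl_a$gauss_image), t(sl_b$gauss_image),
                       t(sl_a$brain_mask_slice), align = FALSE)
  expect_lte(barcode(profile_difference(pair), 0.05)$affected_percent, 2)
})

test_that("slab summaries give mean and sample SD", {
  expect_equal(slab_summary(rep(37.5, 5)), list(mean = 37.5, sd = 0))
  s <- slab_summary(c(30, 40))
  expect_equal(s$mean, 35)
  expect_equal(s$sd, 7.0711, tolerance = 1e-4)
  expect_error(slab_summary(37.5), "at least 2")
})
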