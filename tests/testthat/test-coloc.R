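test_that("known rigid transforms are recovered", {
  img <- blob_image()
  sh <- translate_image(img, 3, -2); sh[is.na(sh)] <- 0
  r <- rigid_register(image_stack(img, 1), image_stack(sh, 1),
                      "translation")
  expect_equal(unname(r$transforms$dy), 3)
  expect_equal(unname(r$transforms$dx), -2)
  rot <- rotate_image(img, 2); rot[is.na(rot)] <- 0
  r2 <- rigid_register(image_stack(img, 1), image_stack(rot, 1), "rigid")
  expect_lt(abs(r2$transforms$angle_deg - 2), 0.2)
  # identical stacks: identity transform
  r0 <- rigid_register(image_stack(img, 1), image_stack(img, 1),
                       "translation")
  expect_equal(unname(unlist(r0$transforms[, c("dy", "dx")])), c(0, 0))
  # featureless slice: identity with a warning
  flat <- image_stack(matrix(1, 32, 32), 1)
  expect_warning(rf <- rigid_register(flat, flat, "translation"),
                 "featureless")
  expect_equal(rf$transforms$dy, 0)
})

test_that("gamma correction is a monotone rescaled power law", {
  img <- matrix(seq(0, 100, by = 2.5), 41, 1)
  expect_equal(gamma_correct(img, 1), img)
  g <- gamma_correct(img, 1.1)
  # normalized value 0.25 maps to 0.25^1.1 = 0.2176
  expect_equal(g[img == 25] / 100, 0.25^1.1, tolerance = 1e-6)
  expect_equal(range(g), range(img))
  with_test_seed(2, {
    x <- matrix(runif(100, 0, 50), 10, 10)
    for (gam in c(0.5, 1.1, 2.4)) {
      y <- gamma_correct(x, gam)
      expect_equal(order(x), order(y))
    }
  })
})

test_that("IsoData matches a brute-force fixed-point scan", {
  # two equal-mass populations at 10 and 20: t = 15
  x <- c(rep(10, 50), rep(20, 50))
  expect_equal(isodata_threshold(x), 15)
  # shift equivariance
  expect_equal(isodata_threshold(x + 7), 22)
  expect_error(isodata_threshold(rep(3, 10)), "constant")
  # 50 random bimodal integer histograms vs exhaustive scan
  with_test_seed(44, {
    for (i in 1:50) {
      x <- round(c(rnorm(300, runif(1, 30, 60), runif(1, 4, 12)),
                   rnorm(200, runif(1, 110, 180), runif(1, 8, 25))))
      t_iter <- isodata_threshold(x)
      fixed <- which(vapply(min(x):max(x), function(t) {
        lo <- x[x <= t]; hi <- x[x > t]
        length(lo) > 0 && length(hi) > 0 &&
          abs(t - (mean(lo) + mean(hi)) / 2) <= 0.5
      }, logical(1))) + min(x) - 1
      expect_gte(length(fixed), 1)
      expect_lte(min(abs(t_iter - fixed)), 1)
      # returned threshold satisfies the fixed-point condition
      lo <- x[x <= t_iter]; hi <- x[x > t_iter]
      expect_lt(abs(t_iter - (mean(lo) + mean(hi)) / 2), 0.5)
    }
  })
})

test_that("Manders coefficients are exact on constructed cases", {
  a <- matrix(0, 10, 10); a[1:5, ] <- 2
  mask_full <- a > 0
  expect_equal(manders(a, mask_full), 1)
  expect_equal(manders(a, !mask_full), 0)
  # uniform A, mask covering 60% of its support
  mask60 <- matrix(FALSE, 10, 10); mask60[1:3, ] <- TRUE
  expect_equal(manders(a, mask60), 0.6)
  # invariant to positive rescaling
  expect_equal(manders(5.7 * a, mask60), 0.6)
  expect_error(manders(a * 0, mask_full), "undefined")
})

test_that("the paired t statistic matches the closed form", {
  with_test_seed(12, {
    m1 <- 0.6 + rnorm(39, 0, 0.02)
    m2 <- 0.9 + rnorm(39, 0, 0.01)
  })
  d <- m1 - m2
  t_closed <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  tt <- stats::t.test(m1, m2, paired = TRUE)
  expect_equal(unname(tt$statistic), t_closed, tolerance = 1e-12)
  # and the pipeline reports the same statistic for stacks whose
  # per-slice coefficients it computes
  ph <- make_phantom("vessels", c(96L, 128L, 4L), seed = 5,
                     params = list(background = 0.05))
  obs <- place_edge_obstacles(ph, 5, 25, 0, seed = 9)
  cfg <- acquisition_config(obstacles = obs, seed = 3)
  ga <- array(0, c(96, 128, 4)); be <- ga
  for (k in 1:4) {
    sl <- render_slice(ph, k, cfg)
    ga[, , k] <- sl$gauss_image; be[, , k] <- sl$bessel_image
  }
  res <- coloc_pipeline(image_stack(ga, 10.4), image_stack(be, 10.4),
                        coloc_config(registration_mode = "translation"))
  dd <- res$per_slice$M_gauss_in_bessel - res$per_slice$M_bessel_in_gauss
  expect_equal(res$t_statistic,
               mean(dd) / (stats::sd(dd) / sqrt(length(dd))),
               tolerance = 1e-10)
})

test_that("striped synthetics order the Manders pair on every slice", {
  ph <- make_phantom("vessels", c(96L, 128L, 4L), seed = 5,
                     params = list(background = 0.05))
  obs <- place_edge_obstacles(ph, 6, 25, 0, seed = 9)
  cfg <- acquisition_config(obstacles = obs, seed = 3)
  ga <- array(0, c(96, 128, 4)); be <- ga
  for (k in 1:4) {
    sl <- render_slice(ph, k, cfg)
    ga[, , k] <- sl$gauss_image; be[, , k] <- sl$bessel_image
  }
  res <- coloc_pipeline(image_stack(ga, 10.4), image_stack(be, 10.4),
                        coloc_config(registration_mode = "translation"))
  expect_true(all(res$per_slice$M_bessel_in_gauss <
                    res$per_slice$M_gauss_in_bessel))
  expect_true(all(res$per_slice[, -1] >= 0 & res$per_slice[, -1] <= 1))
})

test_that("identical stacks give M = 1 and flag zero variance", {
  img <- blob_image(n = 64, n_blobs = 20, seed = 8)
  stk <- image_stack(array(rep(img, 3), c(64, 64, 3)), 1)
  expect_warning(res <- coloc_pipeline(stk, stk,
                                       coloc_config(registration_mode = "none",
                                                    presence = "nonzero")),
                 "zero variance")
  expect_equal(res$per_slice$M_gauss_in_bessel, rep(1, 3))
  expect_equal(res$per_slice$M_bessel_in_gauss, rep(1, 3))
  expect_true(is.na(res$t_statistic))
})
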