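test_that("phantom generation is deterministic and mask-contained", {
  p1 <- make_phantom("mixed", c(64L, 96L, 2L), seed = 9)
  p2 <- make_phantom("mixed", c(64L, 96L, 2L), seed = 9)
  expect_identical(p1$density, p2$density)
  expect_true(all(p1$density[!p1$brain_mask] == 0))
  expect_true(all(p1$density >= 0))
  p3 <- make_phantom("mixed", c(64L, 96L, 2L), seed = 10)
  expect_false(identical(p1$density, p3$density))
  expect_error(make_phantom("nonsense", c(32L, 32L, 1L)))
})

test_that("somata with zero blobs and no background give zero density", {
  p <- make_phantom("somata", c(48L, 48L, 1L),
                    params = list(n_blobs = 0L, background = 0))
  expect_true(all(p$density == 0))
})

test_that("vessel volume fraction is stable across seeds", {
  fr <- vapply(1:10, function(s) {
    p <- make_phantom("vessels", c(64L, 64L, 4L), seed = s,
                      params = list(background = 0))
    mean(p$density[p$brain_mask] > 0)
  }, numeric(1))
  # tubes of radius 1-2.5 px over 40 walks in a small volume: sparse but
  # nonzero occupancy
  expect_true(all(fr > 0.005 & fr < 0.5))
  expect_lt(stats::sd(fr) / mean(fr), 0.5)
})

test_that("Gaussian attenuation casts semi-infinite multiplicative shadows", {
  mask <- matrix(TRUE, 40, 60)
  px <- 10
  # no obstacles, no bulk: all ones
  A0 <- attenuation_gaussian(mask, obstacle_set(), "lr", px)
  expect_equal(A0, matrix(1, 40, 60))
  # one opaque obstacle: exact zero band to the image edge
  obs <- obstacle_set(y_um = 200, x_um = 100, z_um = 5, radius_um = 15,
                      transmittance = 0)
  A1 <- attenuation_gaussian(mask, obs, "lr", px, slice_z_um = 5)
  band_rows <- which(abs((seq_len(40) - 0.5) * px - 200) <= 15)
  expect_true(all(A1[band_rows, 11:60] == 0))
  expect_true(all(A1[-band_rows, ] == 1))
  # two obstacles on the same rows multiply: 0.5 * 0.5 = 0.25
  obs2 <- obstacle_set(y_um = c(200, 200), x_um = c(100, 200),
                       z_um = c(5, 5), radius_um = c(15, 15),
                       transmittance = c(0.5, 0.5))
  A2 <- attenuation_gaussian(mask, obs2, "lr", px, slice_z_um = 5)
  expect_equal(unique(as.vector(A2[band_rows, 25:60])), 0.25)
})

test_that("Bessel shadows are conical and recover; theta -> 0 is Gaussian", {
  mask <- matrix(TRUE, 20, 200)
  px <- 10
  obs <- obstacle_set(y_um = 100, x_um = 100, z_um = 5, radius_um = 20,
                      transmittance = 0)
  bb <- bessel_beam(0.561, 20 * pi / 180, 1.46, 1000)
  A <- attenuation_bessel(mask, obs, "lr", bb, px, slice_z_um = 5)
  row <- 10  # inside the band
  expect_lt(A[row, 12], 0.5)        # just behind the obstacle
  expect_equal(A[row, 200], 1)      # far field fully recovered
  expect_true(all(diff(A[row, 11:200]) >= 0))  # monotone recovery
  # recovery completes at x_c + 1.5 L
  L <- shadow_reconstruction_distance(20, bb$cone_angle_theta)
  col_done <- ceiling((100 + 1.5 * L) / px) + 1
  expect_equal(A[row, col_done], 1, tolerance = 1e-9)
  # tiny cone angle degenerates to the semi-infinite Gaussian shadow
  bb0 <- bessel_beam(0.561, 1e-8, 1.46, 1000)
  A0 <- attenuation_bessel(mask, obs, "lr", bb0, px, slice_z_um = 5)
  Ag <- attenuation_gaussian(mask, obs, "lr", px, slice_z_um = 5)
  expect_equal(A0, Ag, tolerance = 1e-6)
})

test_that("bulk Beer-Lambert attenuation decays along the path", {
  mask <- matrix(TRUE, 4, 50)
  A <- attenuation_gaussian(mask, obstacle_set(), "lr", pixel_size = 10,
                            bulk_mu = 0.001)
  expect_equal(A[1, ], exp(-0.001 * 10 * seq_len(50)))
  Arl <- attenuation_gaussian(mask, obstacle_set(), "rl", pixel_size = 10,
                              bulk_mu = 0.001)
  expect_equal(Arl[1, ], rev(A[1, ]))
})

test_that("rendered slice pairs are deterministic with correct truth masks", {
  ph <- make_phantom("mixed", c(64L, 96L, 2L), seed = 4)
  obs <- place_edge_obstacles(ph, 2, radius_um = 25, transmittance = 0,
                              seed = 6)
  cfg <- acquisition_config(obstacles = obs, seed = 13)
  s1 <- render_slice(ph, 1, cfg)
  s2 <- render_slice(ph, 1, cfg)
  expect_identical(s1$gauss_image, s2$gauss_image)
  expect_identical(s1$bessel_image, s2$bessel_image)
  # containment: truth inside brain; truth inside the gaussian shadow
  expect_true(all(!s1$truth_stripe_mask | s1$brain_mask_slice))
  expect_true(all(!s1$truth_stripe_mask | s1$gauss_shadow_mask))
  # no obstacles: empty truth, images equal up to haze and noise
  cfg0 <- acquisition_config(seed = 13, bessel_haze_fraction = 0,
                             noise = FALSE)
  s0 <- render_slice(ph, 1, cfg0)
  expect_equal(sum(s0$truth_stripe_mask), 0)
  expect_equal(s0$gauss_image, s0$bessel_image)
})

test_that("noise-free renders obey the modality ordering inside stripes", {
  ph <- make_phantom("mixed", c(96L, 128L, 2L), seed = 21)
  obs <- place_edge_obstacles(ph, 4, radius_um = 25, transmittance = 0,
                              seed = 3)
  cfg <- acquisition_config(obstacles = obs, seed = 1, noise = FALSE,
                            bessel_haze_fraction = 0)
  sl <- render_slice(ph, 1, cfg)
  tr <- sl$truth_stripe_mask
  expect_gt(sum(tr), 0)
  expect_lt(mean(sl$gauss_image[tr]), mean(sl$bessel_image[tr]))
  # gaussian shadows reach the split column; bessel shadows are finite
  expect_true(any(sl$gauss_attenuation < 0.95 & sl$bessel_attenuation >= 0.95))
})

test_that("truth area matches obstacle geometry on a noise-free render", {
  ph <- make_phantom("mixed", c(96L, 128L, 1L), seed = 8)
  px <- ph$pixel_size
  mask <- ph$brain_mask[, , 1]
  k <- 3; r_um <- 26
  obs <- place_edge_obstacles(ph, k, radius_um = r_um, transmittance = 0,
                              z_um = 0.5 * px, seed = 5)
  cfg <- acquisition_config(obstacles = obs, seed = 1, noise = FALSE)
  sl <- render_slice(ph, 1, cfg)
  # each opaque surface obstacle shadows a band of ~2r/px rows from its
  # entry point to the split column
  split <- round(mean(which(mask, arr.ind = TRUE)[, 2]))
  expected <- 0
  for (o in seq_len(k)) {
    rows <- which(abs((seq_len(nrow(mask)) - 0.5) * px - obs$y_um[o]) <= r_um)
    entry <- ceiling(obs$x_um[o] / px)
    side_cols <- if (obs$x_um[o] < split * px) entry:split
                 else (split + 1):entry
    expected <- expected + sum(mask[rows, side_cols])
  }
  expect_equal(sum(sl$gauss_shadow_mask), expected, tolerance = 0.1)
})

test_that("dataset generation writes a self-consistent, reproducible bundle", {
  ph <- make_phantom("mixed", c(48L, 64L, 2L), seed = 2)
  obs <- place_edge_obstacles(ph, 2, radius_um = 25, seed = 3)
  cfg <- acquisition_config(obstacles = obs, seed = 5)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  m1 <- generate_dataset(ph, cfg, d1)
  m2 <- generate_dataset(ph, cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     info = f)
  }
  # manifest truth fraction recomputable from the written masks
  truth <- read_mask_stack(file.path(d1, "truth_mask.tif"))
  brain <- read_mask_stack(file.path(d1, "brain_mask.tif"))
  for (kk in 1:2) {
    expect_equal(100 * sum(truth[, , kk]) / sum(brain[, , kk]),
                 m1$truth_fraction_pct[kk])
    expect_true(all(!truth[, , kk] | brain[, , kk]))
  }
  # n_slices = 0 still yields a valid manifest
  d0 <- file.path(tempdir(), "ds0")
  m0 <- generate_dataset(ph, cfg, d0, n_slices = 0)
  expect_equal(m0$n_slices, 0)
  expect_true(file.exists(file.path(d0, "manifest.json")))
})
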