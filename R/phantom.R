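#' Brain-like fluorophore phantom
#'
#' Generates a 3D fluorophore-density grid inside an elliptical "brain"
#' support, emulating the two sample types the pipeline is aimed at:
#' sparse neuron-like somata (Gaussian blobs) and vessel-like tubes
#' (random-walk centerlines stamped with spheres), optionally on top of a
#' diffuse tissue background. Density is in arbitrary units, normalized
#' to unit mean inside the mask; it is zero outside the mask.
#'
#' @param kind one of `"vessels"`, `"somata"`, `"mixed"`.
#' @param size integer vector `c(rows, cols, slices)` of the voxel grid.
#' @param pixel_size voxel pitch (um), isotropic.
#' @param params list of generator parameters; see Details.
#' @param seed integer seed; identical `(kind, size, params, seed)` give
#'   voxel-identical phantoms.
#'
#' @details Recognized `params` (defaults in parentheses):
#' `n_vessels` (40), `vessel_radius_px` range (c(1, 2.5)), `vessel_steps`
#' (150); `n_blobs` (150), `blob_sigma_px` range (c(1.5, 3)); `background`
#' (0.3, diffuse level relative to the structured signal; 0 disables);
#' `mask_semiaxes` (c(0.42, 0.45), row/col semi-axes as fractions of the
#' grid).
#'
#' @return object of class `phantom`: list with `density` (3D array),
#'   `brain_mask` (3D logical array, elliptical cylinder along z),
#'   `pixel_size` (um).
#' @export
make_phantom <- function(kind = c("mixed", "vessels", "somata"),
                         size = c(192L, 256L, 8L),
                         pixel_size = 10.4,
                         params = list(),
                         seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(size) == 3, all(size >= 1), pixel_size > 0)
  p <- utils::modifyList(list(
    n_vessels = 40L, vessel_radius_px = c(1, 2.5), vessel_steps = 150L,
    n_blobs = 150L, blob_sigma_px = c(1.5, 3),
    background = 0.3, mask_semiaxes = c(0.42, 0.45)
  ), params)

  ny <- size[1]; nx <- size[2]; nz <- size[3]
  mask2d <- ellipse_mask(ny, nx, p$mask_semiaxes)
  brain_mask <- array(mask2d, dim = c(ny, nx, nz))

  density <- array(0, dim = c(ny, nx, nz))
  with_seed(seed, {
    if (kind %in% c("vessels", "mixed")) {
      density <- density + draw_vessels(size, p$n_vessels,
                                        p$vessel_radius_px, p$vessel_steps,
                                        mask2d)
    }
    if (kind %in% c("somata", "mixed")) {
      density <- density + draw_somata(size, p$n_blobs, p$blob_sigma_px,
                                       mask2d)
    }
    if (p$background > 0) {
      fg <- mean(density[brain_mask])
      base <- if (fg > 0) fg else 1
      bg <- smooth_background(size, base * p$background)
      density <- density + bg
    }
  })
  density[!brain_mask] <- 0
  m <- mean(density[brain_mask])
  if (m > 0) density <- density / m
  structure(list(density = density, brain_mask = brain_mask,
                 pixel_size = pixel_size),
            class = "phantom")
}

ellipse_mask <- function(ny, nx, semiaxes_frac) {
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  ay <- semiaxes_frac[1] * ny; ax <- semiaxes_frac[2] * nx
  yy <- (seq_len(ny) - cy) / ay
  xx <- (seq_len(nx) - cx) / ax
  outer(yy^2, xx^2, "+") <= 1
}

draw_vessels <- function(size, n_vessels, radius_range, steps, mask2d) {
  ny <- size[1]; nx <- size[2]; nz <- size[3]
  d <- array(0, dim = size)
  if (n_vessels < 1) return(d)
  for (v in seq_len(n_vessels)) {
    r <- stats::runif(1, radius_range[1], radius_range[2])
    pos <- c(stats::runif(1, 1, ny), stats::runif(1, 1, nx),
             stats::runif(1, 1, nz))
    dir <- stats::rnorm(3); dir[3] <- dir[3] * 0.3  # mostly in-plane
    dir <- dir / sqrt(sum(dir^2))
    for (s in seq_len(steps)) {
      dir <- dir + stats::rnorm(3, sd = 0.25)
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir
      ij <- round(pos)
      if (any(ij < 1) || ij[1] > ny || ij[2] > nx || ij[3] > nz) break
      d <- stamp_ball(d, ij, r)
    }
  }
  d
}

stamp_ball <- function(d, center, radius) {
  rr <- ceiling(radius)
  dims <- dim(d)
  i <- max(1L, center[1] - rr):min(dims[1], center[1] + rr)
  j <- max(1L, center[2] - rr):min(dims[2], center[2] + rr)
  k <- max(1L, center[3] - rr):min(dims[3], center[3] + rr)
  di <- (i - center[1])^2
  dj <- (j - center[2])^2
  dk <- (k - center[3])^2
  ball <- outer(outer(di, dj, "+"), dk, "+") <= radius^2
  sub <- d[i, j, k, drop = FALSE]
  sub[ball] <- pmax(sub[ball], 1)
  d[i, j, k] <- sub
  d
}

draw_somata <- function(size, n_blobs, sigma_range, mask2d) {
  ny <- size[1]; nx <- size[2]; nz <- size[3]
  d <- array(0, dim = size)
  if (n_blobs < 1) return(d)
  inside <- which(mask2d, arr.ind = TRUE)
  for (b in seq_len(n_blobs)) {
    yx <- inside[sample.int(nrow(inside), 1L), ]
    cz <- stats::runif(1, 1, nz)
    sg <- stats::runif(1, sigma_range[1], sigma_range[2])
    half <- ceiling(3 * sg)
    i <- max(1L, yx[1] - half):min(ny, yx[1] + half)
    j <- max(1L, yx[2] - half):min(nx, yx[2] + half)
    k <- max(1L, round(cz) - half):min(nz, round(cz) + half)
    gi <- exp(-(i - yx[1])^2 / (2 * sg^2))
    gj <- exp(-(j - yx[2])^2 / (2 * sg^2))
    gk <- exp(-(k - cz)^2 / (2 * sg^2))
    blob <- outer(outer(gi, gj), gk)
    d[i, j, k] <- d[i, j, k, drop = FALSE] + blob
  }
  d
}

smooth_background <- function(size, level) {
  ny <- size[1]; nx <- size[2]; nz <- size[3]
  bg <- array(stats::runif(prod(size), 0.5, 1.5), dim = size)
  for (k in seq_len(nz)) bg[, , k] <- gaussian_blur(bg[, , k], 6)
  bg * level
}

#' Obstacle set for shadow simulation
#'
#' Absorbing/scattering obstacles (bubbles, debris, incompletely cleared
#' spots) that cast stripe shadows in the illumination path. Positions
#' are in micrometres in the phantom's coordinate frame (voxel centre of
#' `[i, j, k]` is at `(i - 0.5, j - 0.5, k - 0.5) * pixel_size`).
#'
#' @param y_um,x_um,z_um obstacle centre coordinates (um).
#' @param radius_um obstacle radii (um), > 0.
#' @param transmittance intensity transmittance in `[0, 1]`
#'   (0 = fully absorbing).
#' @return data.frame of class `obstacle_set`.
#' @export
obstacle_set <- function(y_um = numeric(), x_um = numeric(),
                         z_um = numeric(), radius_um = numeric(),
                         transmittance = numeric()) {
  stopifnot(all(radius_um > 0),
            all(transmittance >= 0 & transmittance <= 1))
  structure(data.frame(y_um = y_um, x_um = x_um, z_um = z_um,
                       radius_um = radius_um,
                       transmittance = transmittance),
            class = c("obstacle_set", "data.frame"))
}

#' Acquisition configuration for synthetic renders
#'
#' Bundles the illumination, haze, noise and ground-truth settings used
#' by [render_slice()] and [generate_dataset()].
#'
#' @param gaussian a [gaussian_beam()] (metadata; the Gaussian shadow
#'   model itself is geometric).
#' @param bessel a [bessel_beam()]; its cone angle sets the conical
#'   shadow reconstruction length.
#' @param obstacles an [obstacle_set()].
#' @param bidirectional illuminate each image half from its nearer side
#'   (split at the brain-mask centroid column); if `FALSE`, a single
#'   left-to-right sheet.
#' @param bessel_haze_fraction fraction in `[0, 1]` of a wide-blurred
#'   copy of the density added to the Bessel channel, modeling the
#'   out-of-focus excitation by the beam's outer rings.
#' @param haze_sigma_um blur scale of the haze (um).
#' @param gain photon gain (expected photons per density unit).
#' @param read_sd Gaussian read-noise standard deviation (counts).
#' @param bulk_mu bulk Beer-Lambert absorption coefficient (1/um) applied
#'   along the illumination path inside the brain mask.
#' @param stripe_truth_threshold transmission below which a pixel counts
#'   as shadowed when building ground-truth masks.
#' @param noise apply Poisson + read noise (`FALSE` gives noise-free
#'   expected counts).
#' @param seed integer root seed for the noise; slice `k` uses
#'   `seed + k`.
#' @return list of class `acquisition_config`.
#' @export
acquisition_config <- function(gaussian = gaussian_beam(0.561, 6),
                               bessel = bessel_beam(0.561,
                                                    axicon_alpha = 20 * pi / 180,
                                                    refractive_index_n = 1.46,
                                                    input_radius_d = 1000),
                               obstacles = obstacle_set(),
                               bidirectional = TRUE,
                               bessel_haze_fraction = 0.1,
                               haze_sigma_um = 80,
                               gain = 50,
                               read_sd = 2,
                               bulk_mu = 0,
                               stripe_truth_threshold = 0.95,
                               noise = TRUE,
                               seed = 1L) {
  stopifnot(bessel_haze_fraction >= 0, bessel_haze_fraction <= 1,
            gain > 0, read_sd >= 0, bulk_mu >= 0,
            stripe_truth_threshold > 0, stripe_truth_threshold <= 1)
  structure(list(gaussian = gaussian, bessel = bessel,
                 obstacles = obstacles, bidirectional = bidirectional,
                 bessel_haze_fraction = bessel_haze_fraction,
                 haze_sigma_um = haze_sigma_um, gain = gain,
                 read_sd = read_sd, bulk_mu = bulk_mu,
                 stripe_truth_threshold = stripe_truth_threshold,
                 noise = noise, seed = as.integer(seed)),
            class = "acquisition_config")
}

#' Transmission field of a Gaussian light sheet through obstacles
#'
#' Geometric shadow model for Gaussian illumination: transmission along
#' each propagation row drops by an obstacle's transmittance and never
#' recovers downstream (semi-infinite stripe), on top of smooth
#' Beer-Lambert bulk attenuation inside the brain mask.
#'
#' @param brain_mask_slice 2D logical matrix.
#' @param obstacles an [obstacle_set()].
#' @param direction `"lr"` (left-to-right along rows) or `"rl"`.
#' @param pixel_size pixel pitch (um).
#' @param bulk_mu bulk absorption coefficient (1/um).
#' @param slice_z_um axial position of this slice (um); obstacles
#'   contribute with their in-plane radius
#'   `sqrt(radius^2 - (z - z_c)^2)` when it is positive.
#' @return matrix of intensity transmission in `[0, 1]`.
#' @export
attenuation_gaussian <- function(brain_mask_slice, obstacles,
                                 direction = c("lr", "rl"),
                                 pixel_size = 10.4, bulk_mu = 0,
                                 slice_z_um = 0) {
  direction <- match.arg(direction)
  attenuation_field(brain_mask_slice, obstacles, direction, pixel_size,
                    bulk_mu, slice_z_um, recovery_length = Inf)
}

#' Transmission field of a Bessel light sheet through obstacles
#'
#' Like [attenuation_gaussian()], but every shadow band recovers
#' linearly to full transmission around the conical-shadow
#' reconstruction length `L = r / tan(theta)`: full shadow up to `L/2`
#' downstream of the obstacle, linear recovery over `[L/2, 3L/2]` (the
#' profile the wave oracle shows); bulk attenuation is unchanged.
#'
#' @inheritParams attenuation_gaussian
#' @param beam a [bessel_beam()]; its `cone_angle_theta` sets the
#'   reconstruction length.
#' @return matrix of intensity transmission in `[0, 1]`.
#' @export
attenuation_bessel <- function(brain_mask_slice, obstacles,
                               direction = c("lr", "rl"),
                               beam,
                               pixel_size = 10.4, bulk_mu = 0,
                               slice_z_um = 0) {
  direction <- match.arg(direction)
  stopifnot(inherits(beam, "bessel_beam"))
  attenuation_field(brain_mask_slice, obstacles, direction, pixel_size,
                    bulk_mu, slice_z_um,
                    theta = beam$cone_angle_theta)
}

# Shared geometric shadow engine. recovery_length = Inf gives the
# Gaussian semi-infinite shadow; finite theta gives the Bessel conical
# shadow with a linear recovery ramp of length r_eff / tan(theta).
attenuation_field <- function(mask, obstacles, direction, pixel_size,
                              bulk_mu, slice_z_um,
                              recovery_length = NULL, theta = NULL) {
  ny <- nrow(mask); nx <- ncol(mask)
  x_um <- (seq_len(nx) - 0.5) * pixel_size
  y_um <- (seq_len(ny) - 0.5) * pixel_size
  A <- matrix(1, ny, nx)

  if (nrow(obstacles) > 0) {
    for (o in seq_len(nrow(obstacles))) {
      # z_um = NA marks surface debris spanning the whole slab; spheres
      # contribute their in-plane chord radius at this slice otherwise
      if (is.na(obstacles$z_um[o])) {
        r_eff <- obstacles$radius_um[o]
      } else {
        dz <- slice_z_um - obstacles$z_um[o]
        r2 <- obstacles$radius_um[o]^2 - dz^2
        if (r2 <= 0) next
        r_eff <- sqrt(r2)
      }
      rows <- which(abs(y_um - obstacles$y_um[o]) <= r_eff)
      if (!length(rows)) next
      s <- if (direction == "lr") x_um - obstacles$x_um[o]
           else obstacles$x_um[o] - x_um
      tr <- obstacles$transmittance[o]
      L <- if (is.null(theta)) Inf
           else shadow_reconstruction_distance(r_eff, theta)
      # transmission profile downstream of the obstacle centre:
      # full-depth shadow over the geometric shadow zone, then linear
      # recovery centred on the reconstruction distance L (ramp from
      # L/2 to 3L/2, the shape the wave oracle shows)
      fac <- rep(1, nx)
      down <- s >= 0
      if (is.finite(L)) {
        ramp <- clamp((s[down] - 0.5 * L) / L, 0, 1)
      } else {
        ramp <- 0
      }
      fac[down] <- tr + (1 - tr) * ramp
      A[rows, ] <- A[rows, , drop = FALSE] *
        matrix(fac, length(rows), nx, byrow = TRUE)
    }
  }

  if (bulk_mu > 0) {
    path_px <- t(apply(mask, 1, function(row) {
      if (direction == "lr") cumsum(row) else rev(cumsum(rev(row)))
    }))
    A <- A * exp(-bulk_mu * pixel_size * path_px)
  }
  A
}

# combined bidirectional attenuation for one slice; split at the brain
# mask centroid column
combined_attenuation <- function(mask, obstacles, config, pixel_size,
                                 slice_z_um, modality = c("gauss", "bessel")) {
  modality <- match.arg(modality)
  att <- function(direction) {
    if (modality == "gauss") {
      attenuation_gaussian(mask, obstacles, direction, pixel_size,
                           config$bulk_mu, slice_z_um)
    } else {
      attenuation_bessel(mask, obstacles, direction, config$bessel,
                         pixel_size, config$bulk_mu, slice_z_um)
    }
  }
  if (!config$bidirectional) return(att("lr"))
  split <- mask_split_column(mask)
  A <- att("lr")
  Ar <- att("rl")
  if (split < ncol(mask)) {
    A[, (split + 1):ncol(mask)] <- Ar[, (split + 1):ncol(mask)]
  }
  A
}

# centroid column of a mask (split point for bidirectional illumination)
mask_split_column <- function(mask) {
  if (!any(mask)) return(ncol(mask) %/% 2L)
  round(mean(which(mask, arr.ind = TRUE)[, 2]))
}

#' Render one synthetic Gaussian/Bessel slice pair
#'
#' Applies the geometric shadow models of both modalities to one phantom
#' plane, adds the Bessel out-of-focus haze, and applies
#' Poisson(gain x signal) photon noise plus Gaussian read noise. The
#' ground-truth stripe mask marks pixels whose Gaussian transmission
#' falls below the truth threshold while the Bessel transmission stays at
#' or above it (the area the self-healing beam rescues); the Gaussian
#' shadow mask marks all pixels the Gaussian sheet fails to reach.
#'
#' @param phantom a [make_phantom()] result.
#' @param z_index slice index (1-based).
#' @param config an [acquisition_config()].
#' @return list of class `slice_pair`: `gauss_image`, `bessel_image`
#'   (counts), `truth_stripe_mask`, `gauss_shadow_mask`,
#'   `brain_mask_slice` (logical), `gauss_attenuation`,
#'   `bessel_attenuation`, `pixel_size`.
#' @export
render_slice <- function(phantom, z_index, config) {
  stopifnot(inherits(phantom, "phantom"),
            inherits(config, "acquisition_config"))
  nz <- dim(phantom$density)[3]
  if (z_index < 1 || z_index > nz) stop("z_index outside phantom")
  px <- phantom$pixel_size
  dens <- phantom$density[, , z_index]
  mask <- phantom$brain_mask[, , z_index]
  z_um <- (z_index - 0.5) * px

  Ag <- combined_attenuation(mask, config$obstacles, config, px, z_um,
                             "gauss")
  Ab <- combined_attenuation(mask, config$obstacles, config, px, z_um,
                             "bessel")

  gauss_clean <- dens * Ag
  haze <- if (config$bessel_haze_fraction > 0) {
    config$bessel_haze_fraction *
      gaussian_blur(dens, config$haze_sigma_um / px)
  } else 0
  bessel_clean <- dens * Ab + haze

  gain <- config$gain
  if (config$noise) {
    imgs <- with_seed(config$seed + z_index, {
      g <- stats::rpois(length(gauss_clean), gain * gauss_clean) +
        stats::rnorm(length(gauss_clean), 0, config$read_sd)
      b <- stats::rpois(length(bessel_clean), gain * bessel_clean) +
        stats::rnorm(length(bessel_clean), 0, config$read_sd)
      list(g = g, b = b)
    })
    gauss_img <- matrix(imgs$g, nrow(dens), ncol(dens))
    bessel_img <- matrix(imgs$b, nrow(dens), ncol(dens))
  } else {
    gauss_img <- gain * gauss_clean
    bessel_img <- gain * bessel_clean
  }

  thr <- config$stripe_truth_threshold
  truth <- mask & (Ag < thr) & (Ab >= thr)
  shadow <- mask & (Ag < thr)
  structure(list(gauss_image = gauss_img, bessel_image = bessel_img,
                 truth_stripe_mask = truth, gauss_shadow_mask = shadow,
                 brain_mask_slice = mask,
                 gauss_attenuation = Ag, bessel_attenuation = Ab,
                 pixel_size = px),
            class = "slice_pair")
}

#' Place shadow-casting obstacles on the brain surface
#'
#' Obstacles (bubbles, debris) settle on the sample surface, so by
#' default they are placed where the light sheet enters the brain mask:
#' at the first masked column of a randomly chosen row (left side) or the
#' last (right side). Rows are drawn without replacement with a minimum
#' separation of one obstacle diameter so the resulting stripes do not
#' overlap.
#'
#' @param phantom a [make_phantom()] result.
#' @param n number of obstacles.
#' @param radius_um obstacle radius (um).
#' @param transmittance intensity transmittance (0 = opaque).
#' @param sides which sides to use; obstacles alternate over them.
#' @param z_um axial positions (recycled); the default `NA` marks
#'   surface debris that spans the whole slab (bubbles and dust are
#'   usually larger than a thin acquisition slab), so the shadow band is
#'   present in every slice. Finite values give spherical obstacles with
#'   a z-dependent chord radius.
#' @param seed integer seed.
#' @param allow_fewer return as many as fit instead of erroring when `n`
#'   non-overlapping rows cannot be found.
#' @return an [obstacle_set()].
#' @export
place_edge_obstacles <- function(phantom, n, radius_um = 20,
                                 transmittance = 0,
                                 sides = c("left", "right"),
                                 z_um = NA_real_, seed = 1L,
                                 allow_fewer = FALSE) {
  stopifnot(inherits(phantom, "phantom"), n >= 0)
  px <- phantom$pixel_size
  mask <- phantom$brain_mask[, , 1]
  if (n == 0) return(obstacle_set())
  rows_ok <- which(apply(mask, 1, any))
  sep <- max(1L, ceiling(2 * radius_um / px))
  with_seed(seed, {
    chosen <- integer(0)
    cand <- sample(rows_ok)
    for (r in cand) {
      if (length(chosen) >= n) break
      if (all(abs(chosen - r) >= sep)) chosen <- c(chosen, r)
    }
    if (length(chosen) < n) {
      if (!allow_fewer) {
        stop("could not place ", n, " non-overlapping obstacles")
      }
      n <- length(chosen)
      if (n == 0) return(obstacle_set())
    }
    side <- rep_len(sides, n)
    y <- (chosen - 0.5) * px
    x <- vapply(seq_len(n), function(i) {
      cols <- which(mask[chosen[i], ])
      cx <- if (side[i] == "left") min(cols) else max(cols)
      (cx - 0.5) * px
    }, numeric(1))
    obstacle_set(y_um = y, x_um = x,
                 z_um = rep_len(z_um, n),
                 radius_um = rep_len(radius_um, n),
                 transmittance = rep_len(transmittance, n))
  })
}

#' Choose obstacles that shadow a target fraction of the brain
#'
#' Adds surface obstacles one at a time (alternating sides) until the
#' Gaussian-shadow area reaches the requested percentage of the brain
#' area on the middle slice. Returns the obstacles together with the
#' fraction actually achieved, which downstream recovery tests use as the
#' ground truth.
#'
#' @param phantom a [make_phantom()] result.
#' @param target_pct target Gaussian-shadow area (% of brain area).
#' @param config an [acquisition_config()] (its threshold and
#'   bidirectional flag are honoured).
#' @param radius_um obstacle radius (um).
#' @param transmittance obstacle transmittance.
#' @param seed integer seed.
#' @param max_n safety cap on the number of obstacles.
#' @return list with `obstacles` (an [obstacle_set()]) and
#'   `achieved_pct`.
#' @export
obstacles_for_fraction <- function(phantom, target_pct, config,
                                   radius_um = 20, transmittance = 0,
                                   seed = 1L, max_n = 80L) {
  stopifnot(target_pct >= 0, target_pct <= 100)
  px <- phantom$pixel_size
  mask <- phantom$brain_mask[, , 1]
  thr <- config$stripe_truth_threshold
  brain_area <- sum(mask)

  shadow_pct <- function(obs) {
    cfg <- config; cfg$obstacles <- obs
    A <- combined_attenuation(mask, obs, cfg, px, 0, "gauss")
    100 * sum(mask & A < thr) / brain_area
  }
  all_obs <- place_edge_obstacles(phantom, max_n, radius_um,
                                  transmittance, seed = seed,
                                  allow_fewer = TRUE)
  max_n <- nrow(all_obs)
  best <- obstacle_set(); best_pct <- 0
  for (k in seq_len(max_n)) {
    obs <- all_obs[seq_len(k), , drop = FALSE]
    class(obs) <- class(all_obs)
    pct <- shadow_pct(obs)
    if (abs(pct - target_pct) < abs(best_pct - target_pct)) {
      best <- obs; best_pct <- pct
    }
    if (pct >= target_pct) break
  }
  list(obstacles = best, achieved_pct = best_pct)
}

#' Generate and write a paired synthetic dataset
#'
#' Renders every requested slice of a phantom under both illumination
#' modalities and writes paired 16-bit TIFF stacks (`gauss.tif`,
#' `bessel.tif`), 8-bit mask stacks (`truth_mask.tif`,
#' `brain_mask.tif`), and a JSON manifest (`manifest.json`) echoing the
#' configuration, the obstacle list and the per-slice ground-truth
#' fractions. Regenerating with the same phantom and configuration
#' reproduces the files byte for byte.
#'
#' @param phantom a [make_phantom()] result.
#' @param config an [acquisition_config()].
#' @param out_dir output directory (created if needed).
#' @param n_slices number of slices to render (default: all).
#' @return the manifest, invisibly (list).
#' @export
generate_dataset <- function(phantom, config, out_dir,
                             n_slices = dim(phantom$density)[3]) {
  stopifnot(inherits(phantom, "phantom"),
            inherits(config, "acquisition_config"),
            n_slices >= 0, n_slices <= dim(phantom$density)[3])
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  dims <- dim(phantom$density)
  px <- phantom$pixel_size

  truth_frac <- numeric(n_slices)
  shadow_frac <- numeric(n_slices)
  if (n_slices > 0) {
    gauss <- array(0, dim = c(dims[1], dims[2], n_slices))
    bessel <- gauss
    truth <- array(FALSE, dim = c(dims[1], dims[2], n_slices))
    brain <- truth
    for (k in seq_len(n_slices)) {
      sl <- render_slice(phantom, k, config)
      gauss[, , k] <- sl$gauss_image
      bessel[, , k] <- sl$bessel_image
      truth[, , k] <- sl$truth_stripe_mask
      brain[, , k] <- sl$brain_mask_slice
      ba <- sum(sl$brain_mask_slice)
      truth_frac[k] <- 100 * sum(sl$truth_stripe_mask) / ba
      shadow_frac[k] <- 100 * sum(sl$gauss_shadow_mask) / ba
    }
    write_stack(gauss, file.path(out_dir, "gauss.tif"))
    write_stack(bessel, file.path(out_dir, "bessel.tif"))
    write_mask_stack(truth, file.path(out_dir, "truth_mask.tif"))
    write_mask_stack(brain, file.path(out_dir, "brain_mask.tif"))
  }

  manifest <- list(
    pixel_size_um = px,
    dims = dims,
    n_slices = n_slices,
    scale = STACK_SCALE,
    seed = config$seed,
    acquisition = list(
      bidirectional = config$bidirectional,
      bessel_haze_fraction = config$bessel_haze_fraction,
      haze_sigma_um = config$haze_sigma_um,
      gain = config$gain,
      read_sd = config$read_sd,
      bulk_mu = config$bulk_mu,
      stripe_truth_threshold = config$stripe_truth_threshold,
      noise = config$noise,
      gaussian_beam = unclass(config$gaussian),
      bessel_beam = unclass(config$bessel)
    ),
    obstacles = as.data.frame(unclass(config$obstacles)),
    truth_fraction_pct = truth_frac,
    gauss_shadow_fraction_pct = shadow_frac
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Choose obstacles that stripe a target fraction of profile rows
#'
#' Places surface obstacles so that a requested percentage of the
#' brain-mask rows lies in a Gaussian shadow — the ground truth for the
#' line-profile bar-code metric, which flags whole rows. Returns the
#' obstacles with the achieved row fraction.
#'
#' @param phantom a [make_phantom()] result.
#' @param target_pct target percentage of mask rows shadowed.
#' @param radius_um obstacle radius (um); each obstacle shadows a band
#'   of about `2 radius / pixel_size` rows.
#' @param transmittance obstacle transmittance (shadow depth is
#'   `1 - transmittance`).
#' @param seed integer seed.
#' @return list with `obstacles` and `achieved_pct`.
#' @export
obstacles_for_row_fraction <- function(phantom, target_pct,
                                       radius_um = 20,
                                       transmittance = 0.7,
                                       seed = 1L) {
  stopifnot(target_pct >= 0, target_pct <= 100)
  px <- phantom$pixel_size
  mask <- phantom$brain_mask[, , 1]
  rows_ok <- which(apply(mask, 1, any))
  rows_per_obs <- max(1, length(unique(
    which(abs((seq_len(nrow(mask)) - 0.5) * px -
                (rows_ok[1] - 0.5) * px) <= radius_um))))
  n <- max(0L, round(target_pct / 100 * length(rows_ok) / rows_per_obs))
  obs <- place_edge_obstacles(phantom, n, radius_um, transmittance,
                              seed = seed, allow_fewer = TRUE)
  achieved <- row_shadow_fraction(phantom, obs)
  list(obstacles = obs, achieved_pct = achieved)
}

#' Percentage of brain-mask rows shadowed by an obstacle set
#'
#' @param phantom a [make_phantom()] result.
#' @param obstacles an [obstacle_set()].
#' @return percentage of rows with any mask pixel that intersect an
#'   obstacle's shadow band.
#' @export
row_shadow_fraction <- function(phantom, obstacles) {
  px <- phantom$pixel_size
  mask <- phantom$brain_mask[, , 1]
  rows_ok <- which(apply(mask, 1, any))
  if (!nrow(obstacles)) return(0)
  y_um <- (rows_ok - 0.5) * px
  hit <- rep(FALSE, length(rows_ok))
  for (o in seq_len(nrow(obstacles))) {
    hit <- hit | abs(y_um - obstacles$y_um[o]) <= obstacles$radius_um[o]
  }
  100 * mean(hit)
}
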