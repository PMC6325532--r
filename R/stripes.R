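#' Configuration of the Fourier-domain stripe filter
#'
#' Stripes run along the illumination direction (image rows), so their
#' spectral energy concentrates on the frequency axis orthogonal to them.
#' The filter zeroes a symmetric angular wedge about that axis, excluding
#' a disk around DC so smooth brightness gradients are untouched, with a
#' raised-cosine edge to limit ringing.
#'
#' @param wedge_half_angle_deg wedge half-angle (degrees), in (0, 45).
#' @param dc_exclusion_radius DC exclusion radius (cycles/image), >= 1.
#' @param edge_width raised-cosine transition width (cycles).
#' @param level binarization level: minimum relative shadow depth
#'   (stripe deficit as a fraction of the destriped local intensity) for
#'   a pixel to count as striped; 0.6 marks shadows that remove more
#'   than 60% of the local signal.
#' @param smooth_px along-stripe running-mean window (px) applied to the
#'   shadow-depth map before thresholding; stripes are coherent along
#'   the illumination axis while texture leakage is not, so this acts as
#'   a matched filter.
#' @param rim_px brain-mask erosion (px) applied to the detection mask,
#'   suppressing boundary ringing (the area denominator is unaffected).
#' @param min_run_px minimum run length (px) of a detection along the
#'   stripe axis; obstacle shadows under Gaussian illumination are
#'   semi-infinite (they persist to the midline), so runs shorter than a
#'   few hundred micrometres are texture, not stripes. Capped at half
#'   the analyzed field width for small images.
#' @param depth_floor floor of the depth denominator, as a fraction of
#'   the median brain intensity, stabilizing the ratio in dim tissue.
#' @param downsample_um working pixel pitch (um); slices are block-mean
#'   downsampled to this pitch before filtering.
#' @return list of class `stripe_filter_config`.
#' @export
stripe_filter_config <- function(wedge_half_angle_deg = 5,
                                 dc_exclusion_radius = 3,
                                 edge_width = 2,
                                 level = 0.6,
                                 smooth_px = 25L,
                                 rim_px = 1L,
                                 min_run_px = 30L,
                                 depth_floor = 0.1,
                                 downsample_um = 10.4) {
  stopifnot(wedge_half_angle_deg > 0, wedge_half_angle_deg < 45,
            dc_exclusion_radius >= 1, edge_width >= 0, level > 0,
            smooth_px >= 1, rim_px >= 0, min_run_px >= 1,
            depth_floor > 0, downsample_um > 0)
  structure(list(wedge_half_angle_deg = wedge_half_angle_deg,
                 dc_exclusion_radius = dc_exclusion_radius,
                 edge_width = edge_width,
                 level = level,
                 smooth_px = as.integer(smooth_px),
                 rim_px = as.integer(rim_px),
                 min_run_px = as.integer(min_run_px),
                 depth_floor = depth_floor,
                 downsample_um = downsample_um),
            class = "stripe_filter_config")
}

#' Block-mean downsampling to a coarser pixel pitch
#'
#' Area-average resampling: pixels are averaged in
#' `factor x factor` blocks where `factor = target_pixel / current_pixel`
#' (required to be an integer); trailing partial blocks are dropped.
#'
#' @param image numeric matrix.
#' @param current_pixel current pitch (um).
#' @param target_pixel target pitch (um), >= current.
#' @return downsampled matrix.
#' @export
downsample <- function(image, current_pixel, target_pixel) {
  stopifnot(is.matrix(image), current_pixel > 0)
  if (target_pixel < current_pixel) {
    stop("target pixel size must be >= current pixel size")
  }
  f <- target_pixel / current_pixel
  if (abs(f - round(f)) > 1e-6) {
    stop("target/current pixel ratio must be an integer (got ",
         signif(f, 4), ")")
  }
  f <- as.integer(round(f))
  if (f == 1L) return(image)
  ny <- (nrow(image) %/% f) * f
  nx <- (ncol(image) %/% f) * f
  if (ny < f || nx < f) stop("image smaller than one block")
  img <- image[seq_len(ny), seq_len(nx), drop = FALSE]
  # average rows then columns in blocks of f
  a <- array(img, dim = c(f, ny %/% f, nx))
  rowm <- apply(a, c(2, 3), mean)
  a2 <- array(t(rowm), dim = c(f, nx %/% f, ny %/% f))
  t(apply(a2, c(2, 3), mean))
}

#' Isolate stripe content by directional Fourier filtering
#'
#' Forward FFT, amplitude-zeroing of a symmetric angular wedge about the
#' stripe-energy axis (vertical frequency axis for `"parallel"`,
#' horizontal for `"perpendicular"`), inverse FFT. The removed content is
#' the stripe image; the retained content is the destriped image; their
#' sum reproduces the input exactly.
#'
#' @param image numeric matrix, finite.
#' @param direction `"parallel"` (stripes along rows, as illuminated) or
#'   `"perpendicular"` (the 90 degree control).
#' @param cfg a [stripe_filter_config()].
#' @return list with `stripe_image` and `destriped_image`.
#' @export
isolate_stripes <- function(image, direction = c("parallel",
                                                 "perpendicular"),
                            cfg = stripe_filter_config()) {
  direction <- match.arg(direction)
  if (!is.matrix(image)) stop("image must be a 2D matrix")
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  ny <- nrow(image); nx <- ncol(image)
  ky <- fft_freq(ny) * ny   # cycles per image
  kx <- fft_freq(nx) * nx
  KY <- matrix(abs(ky), ny, nx)
  KX <- matrix(abs(kx), ny, nx, byrow = TRUE)
  r <- sqrt(KX^2 + KY^2)
  # angle from the stripe-energy axis
  phi <- if (direction == "parallel") atan2(KX, KY) else atan2(KY, KX)
  a <- cfg$wedge_half_angle_deg * pi / 180
  # signed distance (cycles) inside the wedge boundary
  d <- r * (a - phi)
  ew <- max(cfg$edge_width, 1e-9)
  tt <- clamp((d + ew / 2) / ew, 0, 1)
  remove_w <- 0.5 * (1 - cos(pi * tt))
  remove_w[r < cfg$dc_exclusion_radius] <- 0
  keep <- 1 - remove_w
  F <- stats::fft(image)
  destriped <- Re(stats::fft(F * keep, inverse = TRUE)) / (ny * nx)
  list(stripe_image = image - destriped, destriped_image = destriped)
}

#' Binarize a stripe image by relative shadow depth
#'
#' Converts the stripe component into a shadow-depth map — the intensity
#' deficit `max(0, -stripe)` relative to the destriped local intensity
#' (`reference - stripe`), floored at `depth_floor x` the median brain
#' intensity — smooths it along the stripe axis (`smooth_px` running
#' mean), and marks brain pixels whose smoothed depth exceeds `level`.
#' Shadows are coherent along the illumination axis, so the along-stripe
#' smoothing separates them from texture and noise leaking through the
#' wedge, which has no such coherence. The returned depth map can be
#' thresholded at several levels; the mask shrinks monotonically as
#' `level` rises.
#'
#' @param stripe_image stripe component from [isolate_stripes()].
#' @param brain_mask logical matrix, nonempty.
#' @param reference_image the original slice (so the destriped local
#'   intensity is `reference - stripe`, exact by additivity).
#' @param level minimum smoothed relative shadow depth (> 0).
#' @param cfg a [stripe_filter_config()] supplying `smooth_px`,
#'   `rim_px` and `depth_floor`.
#' @param axis stripe axis for the smoothing: `"row"` for the parallel
#'   direction, `"col"` for the 90-degree rotated control.
#' @return logical matrix (subset of `brain_mask`).
#' @export
binarize_stripe_mask <- function(stripe_image, brain_mask,
                                 reference_image,
                                 level = NULL,
                                 cfg = stripe_filter_config(),
                                 axis = c("row", "col")) {
  axis <- match.arg(axis)
  if (is.null(level)) level <- cfg$level
  stopifnot(level > 0, is.matrix(stripe_image))
  if (!any(brain_mask)) stop("empty brain mask")
  S <- shadow_depth_map(stripe_image, brain_mask, reference_image, cfg,
                        axis)
  erode_mask(brain_mask, cfg$rim_px) & (S > level)
}

# smoothed relative shadow-depth map used by the binarization
shadow_depth_map <- function(stripe_image, brain_mask, reference_image,
                             cfg, axis) {
  scale <- stats::median(abs(reference_image[brain_mask]))
  destriped <- reference_image - stripe_image
  depth <- pmax(0, -stripe_image) /
    pmax(destriped, cfg$depth_floor * max(scale, .Machine$double.eps))
  smooth_along(depth, cfg$smooth_px, axis)
}

# centred running mean along rows ("row") or columns ("col"); windows
# shrink at the edges
smooth_along <- function(img, width, axis = c("row", "col")) {
  axis <- match.arg(axis)
  if (width <= 1) return(img)
  half <- width %/% 2
  runmean <- function(v) {
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(0L, seq_len(n) - half - 1L)
    hi <- pmin(n, seq_len(n) + half)
    (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  }
  if (axis == "row") {
    t(apply(img, 1, runmean))
  } else {
    apply(img, 2, runmean)
  }
}

# binary erosion with a plus-shaped structuring element, `iter` times
erode_mask <- function(mask, iter = 1L) {
  m <- mask
  for (i in seq_len(iter)) {
    m <- m & rbind(m[-1, , drop = FALSE], FALSE) &
      rbind(FALSE, m[-nrow(m), , drop = FALSE]) &
      cbind(m[, -1, drop = FALSE], FALSE) &
      cbind(FALSE, m[, -ncol(m), drop = FALSE])
  }
  m
}

# fill pixels outside the mask by replicating each row's first/last
# in-mask value (rows without mask pixels get the in-mask mean), so the
# mask boundary introduces no spurious step along the illumination axis
fill_outside_rows <- function(image, mask) {
  out <- image
  fallback <- mean(image[mask])
  for (i in seq_len(nrow(image))) {
    idx <- which(mask[i, ])
    if (!length(idx)) { out[i, ] <- fallback; next }
    lo <- idx[1]; hi <- idx[length(idx)]
    if (lo > 1) out[i, seq_len(lo - 1)] <- image[i, lo]
    if (hi < ncol(image)) out[i, (hi + 1):ncol(image)] <- image[i, hi]
  }
  out
}

#' Striped area as a percentage of brain area
#'
#' @param binary_mask logical stripe mask.
#' @param brain_mask logical brain mask (nonempty).
#' @return `100 * |mask & brain| / |brain|`.
#' @export
stripe_fraction <- function(binary_mask, brain_mask) {
  nb <- sum(brain_mask)
  if (nb == 0) stop("empty brain mask")
  100 * sum(binary_mask & brain_mask) / nb
}

#' Per-slice stripe quantification (bidirectional)
#'
#' Runs the directional Fourier estimator on one slice: the slice is
#' split at the brain-mask centroid column into its two illumination
#' halves; in each half, pixels outside the brain are filled by
#' replicating the row's entry value (so the mask boundary casts no
#' spurious spectral step), both directional stripe components are
#' extracted and converted to smoothed shadow-depth maps, and pixels
#' claimed by both directions are assigned to the one with the deeper
#' response. The merged masks are expressed as percentages of the brain
#' area; the perpendicular direction is the 90-degree rotated control.
#'
#' @param image numeric matrix (already at the working pixel pitch).
#' @param brain_mask logical matrix.
#' @param cfg a [stripe_filter_config()].
#' @param bidirectional analyze halves separately (default) or the full
#'   frame at once.
#' @return list with `fraction_parallel`, `fraction_perpendicular`,
#'   `mask_parallel`, `mask_perpendicular`.
#' @export
analyze_slice_stripes <- function(image, brain_mask,
                                  cfg = stripe_filter_config(),
                                  bidirectional = TRUE) {
  stopifnot(all(dim(image) == dim(brain_mask)))
  if (!any(brain_mask)) stop("empty brain mask")
  halves <- if (bidirectional) {
    split <- mask_split_column(brain_mask)
    split <- clamp(split, 1L, ncol(image) - 1L)
    list(seq_len(split), (split + 1L):ncol(image))
  } else {
    list(seq_len(ncol(image)))
  }
  masks <- list(parallel = brain_mask & FALSE,
                perpendicular = brain_mask & FALSE)
  for (cols in halves) {
    sub <- image[, cols, drop = FALSE]
    bm <- brain_mask[, cols, drop = FALSE]
    if (!any(bm)) next
    filled <- fill_outside_rows(sub, bm)
    core <- erode_mask(bm, cfg$rim_px)
    depth <- list()
    for (dir in c("parallel", "perpendicular")) {
      iso <- isolate_stripes(filled, dir, cfg)
      depth[[dir]] <- shadow_depth_map(iso$stripe_image, bm, filled, cfg,
                                       if (dir == "parallel") "row"
                                       else "col")
    }
    mp <- core & depth$parallel > cfg$level
    mq <- core & depth$perpendicular > cfg$level
    both <- mp & mq
    if (any(both)) {
      par_wins <- depth$parallel[both] >= depth$perpendicular[both]
      mp[both] <- par_wins
      mq[both] <- !par_wins
    }
    run_par <- min(cfg$min_run_px, max(1L, ncol(sub) %/% 2L))
    run_perp <- min(cfg$min_run_px, max(1L, nrow(sub) %/% 2L))
    masks$parallel[, cols] <- prune_short_runs(mp, run_par, "row")
    masks$perpendicular[, cols] <- prune_short_runs(mq, run_perp, "col")
  }
  list(fraction_parallel = stripe_fraction(masks$parallel, brain_mask),
       fraction_perpendicular = stripe_fraction(masks$perpendicular,
                                                brain_mask),
       mask_parallel = masks$parallel,
       mask_perpendicular = masks$perpendicular)
}

#' Stripe quantification over a stack
#'
#' Applies [analyze_slice_stripes()] to every slice, downsampling to the
#' configured working pitch first.
#'
#' @param stack an [image_stack()].
#' @param brain_mask 3D logical array congruent with the stack (or
#'   `NULL` for an automatic Otsu mask per slice).
#' @param cfg a [stripe_filter_config()].
#' @param bidirectional see [analyze_slice_stripes()].
#' @return data.frame with `slice`, `fraction_parallel`,
#'   `fraction_perpendicular` (class `stripe_report`).
#' @export
quantify_stripes <- function(stack, brain_mask = NULL,
                             cfg = stripe_filter_config(),
                             bidirectional = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack)[3]
  out <- data.frame(slice = seq_len(nz),
                    fraction_parallel = NA_real_,
                    fraction_perpendicular = NA_real_)
  for (k in seq_len(nz)) {
    img <- stack$data[, , k]
    bm <- if (is.null(brain_mask)) auto_brain_mask(img)
          else brain_mask[, , k]
    if (stack$pixel_size < cfg$downsample_um) {
      img <- downsample(img, stack$pixel_size, cfg$downsample_um)
      bm <- downsample(bm + 0, stack$pixel_size, cfg$downsample_um) > 0.5
    }
    res <- analyze_slice_stripes(img, bm, cfg, bidirectional)
    out$fraction_parallel[k] <- res$fraction_parallel
    out$fraction_perpendicular[k] <- res$fraction_perpendicular
  }
  class(out) <- c("stripe_report", "data.frame")
  out
}

#' Automatic brain mask (Otsu on a blurred slice)
#'
#' Fallback segmentation when no mask accompanies a stack.
#'
#' @param image numeric matrix.
#' @param blur_sigma Gaussian blur sigma (px) applied before
#'   thresholding.
#' @return logical matrix.
#' @export
auto_brain_mask <- function(image, blur_sigma = 2) {
  sm <- gaussian_blur(image, blur_sigma)
  sm > otsu_threshold(sm)
}

# Otsu's threshold by maximizing between-class variance on a 256-bin
# histogram
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2],
                                      length.out = n_bins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Gaussian-fit summary of per-slice stripe fractions
#'
#' Histograms the fractions (Freedman-Diaconis binning) and fits a
#' Gaussian `A exp(-(x - peak)^2 / (2 sd^2))` to the bin counts by least
#' squares, summarizing a whole volume by the fitted peak and SD.
#'
#' @param fractions per-slice stripe fractions (%), length >= 10.
#' @return list with `peak` and `sd` (both %), plus `fit` (`nls` object
#'   or `NULL` for the degenerate all-equal case, which warns and
#'   returns sd = 0).
#' @export
volume_striping_summary <- function(fractions) {
  x <- fractions[is.finite(fractions)]
  if (length(x) < 10) stop("need at least 10 slices for a volume summary")
  if (diff(range(x)) == 0) {
    warning("all fractions identical; returning sd = 0")
    return(list(peak = x[1], sd = 0, fit = NULL))
  }
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)
  start <- list(A = max(df$count), peak = mean(x), sd = stats::sd(x))
  fit <- minpack.lm::nlsLM(
    count ~ A * exp(-(mid - peak)^2 / (2 * sd^2)),
    data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 300)
  )
  p <- stats::coef(fit)
  list(peak = unname(p["peak"]), sd = unname(abs(p["sd"])), fit = fit)
}


# drop detection runs shorter than min_run along the stripe axis
prune_short_runs <- function(mask, min_run, axis = c("row", "col")) {
  axis <- match.arg(axis)
  if (min_run <= 1) return(mask)
  f <- function(v) {
    r <- rle(v)
    r$values[r$values & r$lengths < min_run] <- FALSE
    inverse.rle(r)
  }
  if (axis == "row") t(apply(mask, 1, f)) else apply(mask, 2, f)
}
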