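#' Colocalization configuration
#'
#' @param gamma gamma exponent applied to both stacks (> 0); 1.1 gently
#'   enhances dimmer structures.
#' @param registration_mode `"translation"`, `"rigid"` (translation +
#'   in-plane rotation) or `"none"`.
#' @param threshold_scope IsoData threshold computed once per stack
#'   (default) or per slice.
#' @param presence `"threshold"` counts a channel as present where it
#'   exceeds its IsoData threshold (default); `"nonzero"` counts any
#'   positive intensity.
#' @param max_rotation_deg rigid search range (+/- deg).
#' @return list of class `coloc_config`.
#' @export
coloc_config <- function(gamma = 1.1,
                         registration_mode = c("translation", "rigid",
                                               "none"),
                         threshold_scope = c("stack", "slice"),
                         presence = c("threshold", "nonzero"),
                         max_rotation_deg = 3) {
  stopifnot(gamma > 0, max_rotation_deg >= 0)
  structure(list(gamma = gamma,
                 registration_mode = match.arg(registration_mode),
                 threshold_scope = match.arg(threshold_scope),
                 presence = match.arg(presence),
                 max_rotation_deg = max_rotation_deg),
            class = "coloc_config")
}

#' Integer-pixel translation estimate by phase correlation
#'
#' @param fixed,moving numeric matrices, same size.
#' @return integer `c(dy, dx)` such that shifting `moving` by it aligns
#'   it onto `fixed`.
#' @export
phase_correlate <- function(fixed, moving) {
  stopifnot(all(dim(fixed) == dim(moving)))
  Fa <- stats::fft(fixed)
  Fb <- stats::fft(moving)
  cross <- Fa * Conj(Fb)
  mag <- Mod(cross)
  mag[mag < .Machine$double.eps] <- 1
  surf <- Re(stats::fft(cross / mag, inverse = TRUE))
  idx <- which.max(surf)
  ny <- nrow(fixed); nx <- ncol(fixed)
  dy <- (idx - 1) %% ny
  dx <- (idx - 1) %/% ny
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  c(dy = as.integer(dy), dx = as.integer(dx))
}

#' Translate an image with bilinear interpolation
#'
#' @param img numeric matrix.
#' @param dy,dx shift in rows/columns (may be fractional).
#' @return shifted matrix; pixels sampled outside the frame are `NA`.
#' @export
translate_image <- function(img, dy, dx) {
  resample_rigid(img, 0, dy, dx)
}

#' Rotate an image about its centre with bilinear interpolation
#'
#' @param img numeric matrix.
#' @param angle_deg counter-clockwise rotation (degrees).
#' @return rotated matrix; out-of-frame pixels are `NA`.
#' @export
rotate_image <- function(img, angle_deg) {
  resample_rigid(img, angle_deg, 0, 0)
}

# inverse-map rigid resampling: output(y, x) = input at the point that
# rotating by angle and shifting by (dy, dx) sends to (y, x)
resample_rigid <- function(img, angle_deg, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  if (angle_deg == 0 && dy == round(dy) && dx == round(dx)) {
    # fast integer path
    out <- matrix(NA_real_, ny, nx)
    ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
    okY <- ys >= 1 & ys <= ny; okX <- xs >= 1 & xs <= nx
    out[okY, okX] <- img[ys[okY], xs[okX]]
    return(out)
  }
  th <- angle_deg * pi / 180
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  Y <- matrix(seq_len(ny), ny, nx) - cy
  X <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  # inverse transform: undo shift, then rotate by -angle
  Ys <- Y - dy; Xs <- X - dx
  src_y <- cos(th) * Ys + sin(th) * Xs + cy
  src_x <- -sin(th) * Ys + cos(th) * Xs + cx
  bilinear_sample(img, src_y, src_x)
}

bilinear_sample <- function(img, src_y, src_x) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(src_y); x0 <- floor(src_x)
  fy <- src_y - y0; fx <- src_x - x0
  ok <- y0 >= 1 & y0 + 1 <= ny & x0 >= 1 & x0 + 1 <= nx
  out <- matrix(NA_real_, ny, nx)
  i00 <- (x0 - 1) * ny + y0
  v <- (1 - fy[ok]) * (1 - fx[ok]) * img[i00[ok]] +
    fy[ok] * (1 - fx[ok]) * img[i00[ok] + 1] +
    (1 - fy[ok]) * fx[ok] * img[i00[ok] + ny] +
    fy[ok] * fx[ok] * img[i00[ok] + ny + 1]
  out[ok] <- v
  out
}

#' Rigid per-slice registration of one stack onto another
#'
#' Translation is estimated by phase correlation; in `"rigid"` mode an
#' in-plane rotation is added by a coarse-to-fine search (0.5 degree
#' grid over the configured range, refined in 0.1 degree steps), scoring
#' each candidate by its phase-correlation peak. Featureless (flat)
#' slices get the identity transform with a warning. Resampling is
#' bilinear; pixels mapped from outside the frame are `NA` so downstream
#' sums can exclude them.
#'
#' @param moving_stack,fixed_stack [image_stack()]s of identical shape.
#' @param mode `"translation"` or `"rigid"`.
#' @param max_rotation_deg search range for `"rigid"` (+/- deg).
#' @return list with `transforms` (data.frame: slice, angle_deg, dy, dx)
#'   and `registered` (an [image_stack()] with `NA` outside the frame).
#' @export
rigid_register <- function(moving_stack, fixed_stack,
                           mode = c("translation", "rigid"),
                           max_rotation_deg = 3) {
  mode <- match.arg(mode)
  stopifnot(all(dim(moving_stack) == dim(fixed_stack)))
  nz <- dim(moving_stack)[3]
  reg <- moving_stack$data
  tf <- data.frame(slice = seq_len(nz), angle_deg = 0, dy = 0, dx = 0)
  for (k in seq_len(nz)) {
    mov <- moving_stack$data[, , k]
    fix <- fixed_stack$data[, , k]
    if (stats::sd(mov) == 0 || stats::sd(fix) == 0) {
      warning("slice ", k, " is featureless; using identity transform")
      next
    }
    if (mode == "translation") {
      sh <- phase_correlate(fix, mov)
      ang <- 0
    } else {
      score_angle <- function(a) {
        rot <- resample_rigid(mov, a, 0, 0)
        rot[is.na(rot)] <- mean(mov)
        Fa <- stats::fft(fix); Fb <- stats::fft(rot)
        cross <- Fa * Conj(Fb)
        mag <- Mod(cross); mag[mag < .Machine$double.eps] <- 1
        max(Re(stats::fft(cross / mag, inverse = TRUE)))
      }
      coarse <- seq(-max_rotation_deg, max_rotation_deg, by = 0.5)
      sc <- vapply(coarse, score_angle, numeric(1))
      a0 <- coarse[which.max(sc)]
      fine <- seq(a0 - 0.5, a0 + 0.5, by = 0.1)
      scf <- vapply(fine, score_angle, numeric(1))
      ang <- fine[which.max(scf)]
      rot <- resample_rigid(mov, ang, 0, 0)
      rot_f <- rot; rot_f[is.na(rot_f)] <- mean(mov)
      sh <- phase_correlate(fix, rot_f)
    }
    tf$angle_deg[k] <- ang
    tf$dy[k] <- sh["dy"]
    tf$dx[k] <- sh["dx"]
    reg[, , k] <- resample_rigid(mov, ang, sh["dy"], sh["dx"])
  }
  list(transforms = tf,
       registered = image_stack(reg, moving_stack$pixel_size))
}

#' Gamma adjustment over a whole stack
#'
#' Rescales intensities to `[0, 1]` over the entire array, raises them
#' to `gamma`, and rescales back to the original range; monotone and
#' order-preserving for any `gamma > 0`.
#'
#' @param x numeric array/matrix or [image_stack()].
#' @param gamma exponent (> 0).
#' @return same type as `x`.
#' @export
gamma_correct <- function(x, gamma) {
  stopifnot(gamma > 0)
  if (inherits(x, "image_stack")) {
    x$data <- gamma_correct(x$data, gamma)
    return(x)
  }
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) return(x)
  u <- (x - rng[1]) / diff(rng)
  u^gamma * diff(rng) + rng[1]
}

#' IsoData automatic threshold
#'
#' Iterates `t <- (mean(x below t) + mean(x above t)) / 2` from the
#' global mean until the update falls below `tol` (half a grey level by
#' default): the classic intermeans fixed point.
#'
#' @param x numeric vector/array with at least two distinct values
#'   (`NA` ignored).
#' @param tol convergence tolerance in grey levels.
#' @param max_iter iteration cap.
#' @return the threshold (pixels `> t` are foreground).
#' @export
isodata_threshold <- function(x, tol = 0.5, max_iter = 1000L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) {
    stop("constant image: IsoData threshold undefined")
  }
  t <- mean(x)
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) return(t_new)
    t <- t_new
  }
  t
}

#' Manders colocalization coefficient
#'
#' Fraction of channel A's total intensity lying in pixels where channel
#' B is present: `M = sum(A over mask_b) / sum(A)`. Lies in `[0, 1]` and
#' is invariant to positive rescaling of A. `NA` pixels (e.g. outside
#' the registered frame) are excluded from both sums.
#'
#' @param channel_a numeric matrix/array (non-negative where finite).
#' @param mask_b logical mask of pixels where channel B is present
#'   (above its threshold).
#' @return M_a_in_b.
#' @export
manders <- function(channel_a, mask_b) {
  stopifnot(all(dim(channel_a) == dim(mask_b)))
  valid <- is.finite(channel_a) & !is.na(mask_b)
  total <- sum(channel_a[valid])
  if (total <= 0) stop("undefined Manders coefficient: channel sum is 0")
  sum(channel_a[valid & mask_b]) / total
}

#' Gaussian-vs-Bessel colocalization pipeline
#'
#' Registers the Bessel stack onto the Gaussian stack, gamma-adjusts
#' both, applies a per-channel IsoData threshold, computes per-slice
#' Manders coefficients in both directions (intensity above each
#' channel's threshold counts as "present"), and summarizes with stack
#' means +/- SEM and a two-sided paired t test between the two
#' directions across slices.
#'
#' @param gauss_stack,bessel_stack [image_stack()]s, same shape.
#' @param cfg a [coloc_config()].
#' @return list of class `coloc_result`: `per_slice` (data.frame with
#'   `slice`, `M_gauss_in_bessel`, `M_bessel_in_gauss`), `mean_g_in_b`,
#'   `sem_g_in_b`, `mean_b_in_g`, `sem_b_in_g`, `t_statistic`,
#'   `p_value`, `n`, `thresholds`, `transforms`, `config`. A zero
#'   variance of the paired differences is flagged by `t_statistic = NA`
#'   with a warning.
#' @export
coloc_pipeline <- function(gauss_stack, bessel_stack,
                           cfg = coloc_config()) {
  stopifnot(inherits(gauss_stack, "image_stack"),
            inherits(bessel_stack, "image_stack"),
            all(dim(gauss_stack) == dim(bessel_stack)))
  transforms <- NULL
  bes <- bessel_stack
  if (cfg$registration_mode != "none") {
    reg <- rigid_register(bessel_stack, gauss_stack,
                          mode = cfg$registration_mode,
                          max_rotation_deg = cfg$max_rotation_deg)
    bes <- reg$registered
    transforms <- reg$transforms
  }
  # negative counts (read-noise undershoot) carry no signal and would
  # break the Manders bounds; clip at zero before the gamma step
  g <- gamma_correct(pmax(gauss_stack$data, 0), cfg$gamma)
  b <- gamma_correct(pmax(bes$data, 0), cfg$gamma)

  nz <- dim(g)[3]
  per_stack_tg <- per_stack_tb <- NULL
  if (cfg$presence == "threshold" && cfg$threshold_scope == "stack") {
    per_stack_tg <- isodata_threshold(g)
    per_stack_tb <- isodata_threshold(b)
  }
  res <- data.frame(slice = seq_len(nz),
                    M_gauss_in_bessel = NA_real_,
                    M_bessel_in_gauss = NA_real_)
  for (k in seq_len(nz)) {
    gk <- g[, , k]; bk <- b[, , k]
    if (cfg$presence == "threshold") {
      tg <- if (is.null(per_stack_tg)) isodata_threshold(gk) else per_stack_tg
      tb <- if (is.null(per_stack_tb)) isodata_threshold(bk) else per_stack_tb
    } else {
      tg <- 0; tb <- 0
    }
    valid <- is.finite(gk) & is.finite(bk)
    gk[!valid] <- NA; bk[!valid] <- NA
    res$M_gauss_in_bessel[k] <- manders(gk, !is.na(bk) & bk > tb)
    res$M_bessel_in_gauss[k] <- manders(bk, !is.na(gk) & gk > tg)
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  dvar <- stats::var(res$M_gauss_in_bessel - res$M_bessel_in_gauss)
  if (nz >= 2 && dvar > 0) {
    tt <- stats::t.test(res$M_gauss_in_bessel, res$M_bessel_in_gauss,
                        paired = TRUE)
    t_stat <- unname(tt$statistic); p_val <- tt$p.value
  } else {
    if (nz >= 2) warning("zero variance of paired differences; ",
                         "t statistic undefined")
    t_stat <- NA_real_; p_val <- NA_real_
  }
  structure(list(per_slice = res,
                 mean_g_in_b = mean(res$M_gauss_in_bessel),
                 sem_g_in_b = if (nz >= 2) sem(res$M_gauss_in_bessel) else NA_real_,
                 mean_b_in_g = mean(res$M_bessel_in_gauss),
                 sem_b_in_g = if (nz >= 2) sem(res$M_bessel_in_gauss) else NA_real_,
                 t_statistic = t_stat, p_value = p_val, n = nz,
                 thresholds = list(gauss = per_stack_tg,
                                   bessel = per_stack_tb),
                 transforms = transforms,
                 config = cfg),
            class = "coloc_result")
}
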