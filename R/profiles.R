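#' Mean line profile over masked rows
#'
#' Per-column mean intensity over the rows selected by `region_mask`,
#' the "line profile averaged over the entire height" of a region.
#' Columns without any masked row are dropped and flagged in the
#' `dropped` attribute.
#'
#' @param image numeric matrix.
#' @param region_mask logical matrix (default: all pixels).
#' @return list with `positions` (column indices) and `values`; columns
#'   with no masked rows are absent and listed in `attr(, "dropped")`.
#' @export
column_profile <- function(image, region_mask = NULL) {
  stopifnot(is.matrix(image))
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(image),
                                                  ncol(image))
  stopifnot(all(dim(region_mask) == dim(image)))
  counts <- colSums(region_mask)
  vals <- colSums(image * region_mask) / counts
  keep <- counts > 0
  out <- list(positions = which(keep), values = vals[keep])
  attr(out, "dropped") <- which(!keep)
  out
}

#' Paired Gaussian/Bessel line profiles
#'
#' Builds the two column profiles over a common region, co-registers
#' them by an integer shift maximizing their cross-correlation (the two
#' acquisitions are sequential), and restricts both to the overlapping
#' columns.
#'
#' @param gauss_image,bessel_image numeric matrices, same size.
#' @param region_mask logical matrix or `NULL`.
#' @param align co-register by integer shift (default `TRUE`).
#' @param max_shift largest shift searched (px).
#' @param min_support drop columns whose masked-row count falls below
#'   this fraction of the best-covered column; the thin ends of an
#'   elliptical mask average too few rows for a stable profile.
#' @return list of class `profile_pair` with `positions`,
#'   `gauss_profile`, `bessel_profile`, `shift` (applied to the Bessel
#'   profile) and `normalization` (`"mode-ratio"`, applied downstream).
#' @export
profile_pair <- function(gauss_image, bessel_image, region_mask = NULL,
                         align = TRUE, max_shift = 10L,
                         min_support = 0.25) {
  stopifnot(all(dim(gauss_image) == dim(bessel_image)))
  g <- column_profile(gauss_image, region_mask)
  b <- column_profile(bessel_image, region_mask)
  if (!is.null(region_mask) && min_support > 0) {
    counts <- colSums(region_mask)
    keep <- which(counts >= min_support * max(counts))
    sel <- g$positions %in% keep
    g$values <- g$values[sel]; g$positions <- g$positions[sel]
    sel <- b$positions %in% keep
    b$values <- b$values[sel]; b$positions <- b$positions[sel]
  }
  common <- intersect(g$positions, b$positions)
  gv <- g$values[match(common, g$positions)]
  bv <- b$values[match(common, b$positions)]
  shift <- 0L
  if (align && length(common) > 2 * max_shift + 2) {
    shift <- best_lag(gv, bv, max_shift)
  }
  if (shift != 0L) {
    n <- length(common)
    if (shift > 0) {
      gv <- gv[(1 + shift):n]; bv <- bv[1:(n - shift)]
      common <- common[(1 + shift):n]
    } else {
      gv <- gv[1:(n + shift)]; bv <- bv[(1 - shift):n]
      common <- common[1:(n + shift)]
    }
  }
  structure(list(positions = common, gauss_profile = gv,
                 bessel_profile = bv, shift = shift,
                 normalization = "mode-ratio"),
            class = "profile_pair")
}

# integer lag of b relative to a maximizing cross-correlation of the
# mean-subtracted profiles
best_lag <- function(a, b, max_shift) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  lags <- -max_shift:max_shift
  score <- vapply(lags, function(l) {
    n <- length(a0)
    if (l >= 0) sum(a0[(1 + l):n] * b0[1:(n - l)])
    else sum(a0[1:(n + l)] * b0[(1 - l):n])
  }, numeric(1))
  lags[which.max(score)]
}

#' Relative difference between paired profiles
#'
#' The two channels are gain-matched by the mode of their per-column
#' log-ratio (the densest cluster of columns defines the common gain, so
#' the estimate does not drift even when half the columns are striped,
#' unlike a median), then the per-column absolute difference is taken
#' relative to the brighter channel. The result is unit-free (0.05 = 5%
#' relative deviation) and exactly symmetric in the two channels.
#'
#' @param pair a [profile_pair()].
#' @param normalize gain-match first (default); `FALSE` skips the gain
#'   step and differs the raw profiles relative to the brighter one.
#' @return numeric vector of per-column relative differences.
#' @export
profile_difference <- function(pair, normalize = TRUE) {
  stopifnot(inherits(pair, "profile_pair"))
  g <- pair$gauss_profile; b <- pair$bessel_profile
  if (all(g == 0) || all(b == 0)) {
    stop("normalization error: a profile is identically zero")
  }
  if (normalize) {
    pos <- g > 0 & b > 0
    if (sum(pos) < 2) stop("normalization error: too few positive columns")
    lr <- log(g[pos]) - log(b[pos])
    gain <- exp(density_mode(lr))
    g <- g / gain
  }
  denom <- pmax(g, b)
  d <- abs(g - b) / denom
  d[denom == 0] <- 0
  d
}

# location of the highest kernel-density peak; degenerate spreads fall
# back to the median
density_mode <- function(x) {
  if (length(unique(x)) == 1) return(x[1])
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) return(stats::median(x))
  d <- stats::density(x, bw = bw)
  d$x[which.max(d$y)]
}

#' Binarize a profile difference into a bar code
#'
#' Columns whose relative difference exceeds the threshold are flagged;
#' the flagged share is the percentage of the area affected by streaks.
#'
#' @param diff per-column difference from [profile_difference()].
#' @param threshold positive relative threshold (0.05 = 5%).
#' @return list of class `barcode_result` with `threshold`, `barcode`
#'   (logical per column), `affected_percent`.
#' @export
barcode <- function(diff, threshold) {
  stopifnot(threshold > 0)
  bc <- diff > threshold
  structure(list(threshold = threshold, barcode = bc,
                 affected_percent = 100 * mean(bc)),
            class = "barcode_result")
}

#' Sensitivity of the affected area to the chosen threshold
#'
#' @param pair a [profile_pair()].
#' @param thresholds ascending positive thresholds.
#' @return data.frame with `threshold` and `affected_percent`
#'   (non-increasing).
#' @export
threshold_sweep <- function(pair, thresholds = seq(0.01, 0.30, by = 0.01)) {
  stopifnot(!is.unsorted(thresholds), all(thresholds > 0))
  d <- profile_difference(pair)
  data.frame(
    threshold = thresholds,
    affected_percent = vapply(thresholds,
                              function(t) barcode(d, t)$affected_percent,
                              numeric(1))
  )
}

#' Mean and SD of affected percentages over a slab
#'
#' @param per_slice_percents affected percentage per slice, length >= 2.
#' @return list with `mean` and `sd` (sample SD).
#' @export
slab_summary <- function(per_slice_percents) {
  x <- per_slice_percents[is.finite(per_slice_percents)]
  if (length(x) < 2) stop("need at least 2 slices (SD undefined)")
  list(mean = mean(x), sd = stats::sd(x))
}
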