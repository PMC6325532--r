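# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's
# random-number state afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Separable Gaussian blur of a 2D image
#'
#' Convolution with a truncated (+/- 3 sigma) Gaussian kernel, replicate
#' padding at the edges. Used for the out-of-focus haze model and the
#' auto-mask fallback.
#'
#' @param img numeric matrix.
#' @param sigma kernel standard deviation in pixels.
#' @return blurred matrix, same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  blur_axis <- function(m) {
    # replicate-pad rows, convolve each column
    padded <- m[c(rep(1L, half), seq_len(nrow(m)), rep(nrow(m), half)), ,
                drop = FALSE]
    out <- apply(padded, 2, function(col) {
      stats::filter(col, k, sides = 2)
    })
    out[(half + 1L):(half + nrow(m)), , drop = FALSE]
  }
  t(blur_axis(t(blur_axis(img))))
}

# integer-valued matrix check helper for mask I/O
as_mask <- function(m) {
  storage.mode(m) <- "logical"
  m
}
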