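#' Free-space angular-spectrum propagation
#'
#' Numerical scalar-wave oracle used to validate the closed-form beam
#' relations and the geometric shadow models: decompose a monochromatic
#' field into plane waves with a 2D FFT, advance each by its axial phase
#' `exp(i 2 pi z sqrt(1/lambda^2 - fx^2 - fy^2))`, and transform back.
#' Evanescent components (fx^2 + fy^2 > 1/lambda^2) are discarded.
#'
#' @param field square complex (or numeric) matrix of transverse field
#'   amplitude.
#' @param distance propagation distance (um); may be negative.
#' @param wavelength wavelength (um).
#' @param grid_spacing transverse sample pitch (um).
#' @param max_angle optional largest propagation angle (rad) expected in
#'   the field; if supplied, the sampling guard requires
#'   `grid_spacing <= wavelength / (4 sin(max_angle))` and errors
#'   otherwise.
#' @return complex matrix of the propagated field, same dimensions.
#' @export
propagate_field <- function(field, distance, wavelength, grid_spacing,
                            max_angle = NULL) {
  if (!is.matrix(field) || nrow(field) != ncol(field)) {
    stop("field must be a square matrix")
  }
  stopifnot(wavelength > 0, grid_spacing > 0)
  if (!is.null(max_angle)) {
    if (grid_spacing > wavelength / (4 * sin(max_angle))) {
      stop(sprintf(
        "sampling error: spacing %.4g um exceeds lambda/(4 sin theta_max) = %.4g um",
        grid_spacing, wavelength / (4 * sin(max_angle))))
    }
  }
  n <- nrow(field)
  f1 <- fft_freq(n, grid_spacing)
  fx <- matrix(f1, n, n, byrow = TRUE)
  fy <- matrix(f1, n, n)
  arg <- 1 / wavelength^2 - fx^2 - fy^2
  prop <- arg > 0
  kz <- matrix(0, n, n)
  kz[prop] <- 2 * pi * sqrt(arg[prop])
  H <- matrix(0 + 0i, n, n)
  H[prop] <- exp(1i * kz[prop] * distance)
  F <- stats::fft(field)
  stats::fft(F * H, inverse = TRUE) / (n * n)
}

#' FFT sample frequencies
#'
#' @param n number of samples.
#' @param d sample spacing.
#' @return length-`n` vector of cycles per unit, FFT ordering.
#' @keywords internal
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

#' Construct a focused Gaussian field at its waist
#'
#' @param n grid size (n x n).
#' @param grid_spacing pitch (um).
#' @param w0 1/e^2 intensity radius (um).
#' @return complex matrix, unit peak amplitude.
#' @export
gaussian_field <- function(n, grid_spacing, w0) {
  r2 <- radius_sq_grid(n, grid_spacing)
  matrix(as.complex(exp(-r2 / w0^2)), n, n)
}

#' Apply an axicon phase ramp to a field
#'
#' Multiplies by `exp(-i k sin(theta) r)`, the thin-axicon transmission
#' that tilts the wavefront onto a cone of half-angle `theta`.
#'
#' @param field complex matrix.
#' @param grid_spacing pitch (um).
#' @param wavelength wavelength (um).
#' @param theta cone angle (rad).
#' @return complex matrix.
#' @export
axicon_phase <- function(field, grid_spacing, wavelength, theta) {
  n <- nrow(field)
  r <- sqrt(radius_sq_grid(n, grid_spacing))
  field * exp(-1i * (2 * pi / wavelength) * sin(theta) * r)
}

#' Apply a centred circular obstacle to a field
#'
#' @param field complex matrix.
#' @param grid_spacing pitch (um).
#' @param radius obstacle radius (um).
#' @param transmittance amplitude transmittance inside the disk
#'   (0 = fully absorbing).
#' @return complex matrix.
#' @export
disk_obstacle <- function(field, grid_spacing, radius, transmittance = 0) {
  n <- nrow(field)
  r2 <- radius_sq_grid(n, grid_spacing)
  field * ifelse(r2 <= radius^2, transmittance, 1)
}

#' Total optical power of a field
#'
#' @param field complex matrix.
#' @param grid_spacing pitch (um).
#' @return sum of |field|^2 times the pixel area.
#' @export
field_power <- function(field, grid_spacing) {
  sum(Mod(field)^2) * grid_spacing^2
}

#' On-axis intensity of a field
#'
#' @param field complex matrix (centre taken at `floor(n/2) + 1`).
#' @return |field|^2 at the grid centre.
#' @export
on_axis_intensity <- function(field) {
  c0 <- floor(nrow(field) / 2) + 1L
  Mod(field[c0, c0])^2
}

#' Second-moment 1/e^2 radius of a field's intensity
#'
#' For a Gaussian intensity `exp(-2 r^2 / w^2)` the 2D second moment is
#' `<r^2> = w^2 / 2`, so `w = sqrt(2 <r^2>)`.
#'
#' @param field complex matrix.
#' @param grid_spacing pitch (um).
#' @return equivalent 1/e^2 radius (um).
#' @export
second_moment_radius <- function(field, grid_spacing) {
  n <- nrow(field)
  I <- Mod(field)^2
  r2 <- radius_sq_grid(n, grid_spacing)
  sqrt(2 * sum(I * r2) / sum(I))
}

#' Radial intensity profile along the central row
#'
#' @param field complex matrix.
#' @param grid_spacing pitch (um).
#' @return data.frame with `r` (um, >= 0) and `intensity`.
#' @export
transverse_profile <- function(field, grid_spacing) {
  n <- nrow(field)
  c0 <- floor(n / 2) + 1L
  idx <- c0:n
  data.frame(r = (idx - c0) * grid_spacing,
             intensity = Mod(field[c0, idx])^2)
}

# squared distance from the grid centre, centre at floor(n/2)+1
radius_sq_grid <- function(n, grid_spacing) {
  c0 <- floor(n / 2) + 1L
  ax <- ((seq_len(n) - c0) * grid_spacing)^2
  outer(ax, ax, "+")
}
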