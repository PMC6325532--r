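#' Beam parameter containers and closed-form beam optics
#'
#' Closed-form relations for Gaussian beams and for Bessel beams generated
#' by a conical lens (axicon): the cone angle, the depth of focus, the
#' central-core radius, and the hyperbolic width of a Gaussian beam.
#'
#' All lengths are micrometres and all angles radians unless noted.
#' Widths are stored internally as 1/e^2 intensity radii; full width at
#' half maximum (FWHM) is converted only at input/output boundaries via
#' `fwhm_to_w()` / `w_to_fwhm()`.
#'
#' @name beam-optics
NULL

FWHM_FACTOR <- sqrt(2 * log(2))  # intensity FWHM = w * sqrt(2 ln 2)

#' Convert between FWHM and 1/e^2 intensity radius
#'
#' @param fwhm,w numeric vectors (micrometres).
#' @return converted widths (micrometres).
#' @export
fwhm_to_w <- function(fwhm) fwhm / FWHM_FACTOR

#' @rdname fwhm_to_w
#' @export
w_to_fwhm <- function(w) w * FWHM_FACTOR

#' Gaussian beam specification
#'
#' @param wavelength excitation wavelength (um).
#' @param waist_w0 beam waist, 1/e^2 intensity radius at focus (um).
#' @param rayleigh_zR Rayleigh range (um); defaults to the paraxial value
#'   `pi * w0^2 / wavelength`.
#' @return object of class `gaussian_beam` with fields `wavelength`,
#'   `waist_w0`, `rayleigh_zR`, `confocal_b` (= 2 zR) and
#'   `numerical_aperture` (= wavelength / (pi w0), paraxial divergence).
#' @export
gaussian_beam <- function(wavelength, waist_w0,
                          rayleigh_zR = pi * waist_w0^2 / wavelength) {
  stopifnot(wavelength > 0, waist_w0 > 0, rayleigh_zR > 0)
  structure(list(
    wavelength = wavelength,
    waist_w0 = waist_w0,
    rayleigh_zR = rayleigh_zR,
    confocal_b = 2 * rayleigh_zR,
    numerical_aperture = wavelength / (pi * waist_w0)
  ), class = "gaussian_beam")
}

#' Bessel beam specification from axicon geometry
#'
#' Derives the dependent quantities of an axicon-generated Bessel beam:
#' cone angle `theta = (n - 1) alpha`, depth of focus `dZ = d / theta`,
#' and core radius `rc = 2.405 lambda / (2 pi sin theta)`.
#'
#' @param wavelength excitation wavelength (um).
#' @param axicon_alpha axicon apex-face angle (rad).
#' @param refractive_index_n axicon refractive index (> 1).
#' @param input_radius_d radius of the Gaussian beam impinging on the
#'   axicon (um).
#' @return object of class `bessel_beam` with the input fields plus
#'   `cone_angle_theta`, `depth_of_focus_dZ`, `core_radius_rc`.
#' @export
bessel_beam <- function(wavelength, axicon_alpha, refractive_index_n,
                        input_radius_d) {
  stopifnot(wavelength > 0, axicon_alpha > 0, input_radius_d > 0)
  theta <- cone_angle(axicon_alpha, refractive_index_n)
  structure(list(
    wavelength = wavelength,
    axicon_alpha = axicon_alpha,
    refractive_index_n = refractive_index_n,
    input_radius_d = input_radius_d,
    cone_angle_theta = theta,
    depth_of_focus_dZ = depth_of_focus(input_radius_d, theta),
    core_radius_rc = bessel_core_radius(wavelength, theta)
  ), class = "bessel_beam")
}

#' Cone angle of an axicon-generated Bessel beam
#'
#' @param alpha axicon angle (rad), >= 0.
#' @param n refractive index of the axicon material, > 1.
#' @return cone angle theta = (n - 1) * alpha (rad), small-angle regime.
#' @export
cone_angle <- function(alpha, n) {
  if (any(alpha < 0)) stop("axicon angle must be >= 0")
  if (any(n <= 1)) stop("invalid medium: refractive index must exceed 1")
  (n - 1) * alpha
}

#' Depth of focus of a Bessel beam
#'
#' @param d radius of the incoming Gaussian beam (um).
#' @param theta cone angle (rad), > 0.
#' @return depth of focus d / theta (um).
#' @export
depth_of_focus <- function(d, theta) {
  if (any(d < 0)) stop("input beam radius must be >= 0")
  if (any(theta <= 0)) stop("degenerate beam: cone angle must be > 0")
  d / theta
}

#' Radius of the central core of a Bessel beam
#'
#' First zero of the transverse J0 profile.
#'
#' @param wavelength excitation wavelength (um), > 0.
#' @param theta cone angle (rad), in (0, pi/2).
#' @return core radius 2.405 * wavelength / (2 pi sin(theta)) (um).
#' @export
bessel_core_radius <- function(wavelength, theta) {
  if (any(wavelength <= 0)) stop("wavelength must be > 0")
  if (any(theta <= 0 | theta >= pi / 2)) {
    stop("cone angle must lie in (0, pi/2)")
  }
  2.405 * wavelength / (2 * pi * sin(theta))
}

#' Gaussian beam 1/e^2 radius at axial position z
#'
#' Hyperbolic beam envelope w(z) = w0 * sqrt(1 + (z/zR)^2).
#'
#' @param z axial position(s) relative to the focus (um).
#' @param spec a [gaussian_beam()].
#' @param as_fwhm return the FWHM instead of the 1/e^2 radius.
#' @return beam width at `z` (um).
#' @export
gaussian_width <- function(z, spec, as_fwhm = FALSE) {
  stopifnot(inherits(spec, "gaussian_beam"))
  w <- spec$waist_w0 * sqrt(1 + (z / spec$rayleigh_zR)^2)
  if (as_fwhm) w_to_fwhm(w) else w
}

#' Fit a hyperbolic envelope to measured beam widths
#'
#' Least-squares fit of FWHM(z) = F0 * sqrt(1 + ((z - z0)/zR)^2) to
#' axial width samples, as used to characterize the excitation beam
#' (width vs. axial distance, fit to a hyperbolic function). The waist,
#' Rayleigh range and NA are extracted from the fit.
#'
#' @param axial_positions_z axial sample positions (um), >= 3 distinct.
#' @param widths_fwhm measured FWHM at each position (um), > 0.
#' @param wavelength excitation wavelength (um), used to derive the NA.
#' @return list with `spec` (a [gaussian_beam()]), `focus_z0` (um) and
#'   `fit` (the `nls` object).
#' @export
fit_beam_profile <- function(axial_positions_z, widths_fwhm, wavelength) {
  z <- as.numeric(axial_positions_z)
  f <- as.numeric(widths_fwhm)
  if (length(z) != length(f)) stop("positions and widths differ in length")
  if (length(unique(z)) < 3) stop("need at least 3 distinct axial positions")
  if (!all(is.finite(z)) || !all(is.finite(f)) || any(f <= 0)) {
    stop("widths must be finite and positive")
  }
  # start values: minimum width as waist, quarter-range as zR; the
  # focus start is nudged off the sample grid, where an exactly
  # symmetric design can make the initial Jacobian rank-deficient
  i0 <- which.min(f)
  span <- diff(range(z))
  make_start <- function(dz0) list(F0 = f[i0], z0 = z[i0] + dz0,
                                   zR = max(span / 4, 1e-6))
  fit <- NULL
  for (dz0 in c(0.01 * span, -0.01 * span, 0.1 * span)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ F0 * sqrt(1 + ((z - z0) / zR)^2),
        start = make_start(dz0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("beam-profile fit failed to converge")
  p <- stats::coef(fit)
  w0 <- fwhm_to_w(abs(p[["F0"]]))
  list(
    spec = gaussian_beam(wavelength, w0, rayleigh_zR = abs(p[["zR"]])),
    focus_z0 = p[["z0"]],
    fit = fit
  )
}

#' Shadow reconstruction distance behind an obstacle
#'
#' Axial distance over which the conical shadow cast by an obstacle in a
#' Bessel beam closes: the beam's ring system refills the core a distance
#' r / tan(theta) downstream of an obstacle of radius r.
#'
#' @param obstacle_radius obstacle radius (um), >= 0.
#' @param theta cone angle (rad), > 0.
#' @return reconstruction distance (um); monotone increasing in radius.
#' @export
shadow_reconstruction_distance <- function(obstacle_radius, theta) {
  if (any(obstacle_radius < 0)) stop("obstacle radius must be >= 0")
  if (any(theta <= 0)) stop("cone angle must be > 0")
  obstacle_radius / tan(theta)
}
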