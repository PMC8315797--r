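# Geometric/dynamic similarity metrics and normalized cross-correlation.

#' Similarity specification of a body
#'
#' @param mass Total mass (g), including any mass attached to the legs.
#' @param density Body density (g mm^-3).
#' @param lengths Optional named lengths (mm): length, width, thickness.
#' @export
similarity_spec <- function(mass, density, lengths = NULL) {
  if (!all(is.finite(c(mass, density))) || mass <= 0 || density <= 0) {
    rlang::abort("mass and density must be positive",
                 class = "selfright_domain_error")
  }
  structure(list(mass = mass, density = density, lengths = lengths),
            class = "similarity_spec")
}

#' Geometric-similarity scale factors between two bodies
#'
#' For geometrically similar bodies, length scales as `l ~ (m / rho)^(1/3)`,
#' so gravitational potential energy (mass times a length) scales as
#' `E ~ m^(4/3) rho^(-1/3)`. Returns the expected length and potential-energy
#' scale factors of `robot` relative to `animal`.
#'
#' @param animal,robot [similarity_spec()] objects.
#' @return Tibble with `mass_ratio`, `density_ratio`, `length_factor`,
#'   `energy_factor`.
#' @export
scale_factors <- function(animal, robot) {
  mr <- robot$mass / animal$mass
  dr <- robot$density / animal$density
  tibble::tibble(
    mass_ratio = mr,
    density_ratio = dr,
    length_factor = (mr / dr)^(1 / 3),
    energy_factor = mr^(4 / 3) * dr^(-1 / 3))
}

#' Froude number of leg flailing
#'
#' Ratio of the inertial (centrifugal) force from leg flailing to the
#' gravitational force on the leg: `Fr = v^2 / (r g)`, with the leg-tip
#' lateral translational speed `v` and leg length `r` converted internally
#' to SI units.
#'
#' @param v Leg lateral translational speed (mm/s).
#' @param r Leg length (mm).
#' @param g Gravitational acceleration (m/s^2).
#' @export
froude <- function(v, r, g = 9.81) {
  if (any(r <= 0) || g <= 0) {
    rlang::abort("leg length and gravity must be positive",
                 class = "selfright_domain_error")
  }
  if (any(v < 0)) {
    rlang::abort("speed must be non-negative", class = "selfright_domain_error")
  }
  (v * 1e-3)^2 / ((r * 1e-3) * g)
}

#' RMS lateral leg-tip speed over a flailing window
#'
#' Averaging convention used for the Froude number: the root-mean-square of
#' the body-frame lateral component of the leg-tip translational velocity.
#' @param vy Lateral velocity samples (mm/s).
#' @export
rms_speed <- function(vy) sqrt(mean(vy^2))

#' Normalized cross-correlation of two signals
#'
#' Discrete implementation of the energy-normalised cross-correlation
#' `h(t) = sum_tau f(tau - t) g(tau) / sqrt(sum |f|^2 sum |g|^2)`,
#' evaluated at every integer-sample lag `t`; `|h| <= 1` everywhere
#' (Cauchy-Schwarz) and the autocorrelation (`f = g`) peaks at exactly 1 at
#' zero lag.
#'
#' @param f,g Equal-length numeric vectors sampled at `rate`.
#' @param rate Sampling rate (samples per second); lags are reported in
#'   seconds.
#' @return Tibble with `lag_s` and `h`.
#' @export
xcorr_normalized <- function(f, g = f, rate = 1) {
  if (length(f) != length(g)) {
    rlang::abort("signals must have equal length",
                 class = "selfright_domain_error")
  }
  ef <- sum(f^2); eg <- sum(g^2)
  if (ef == 0 || eg == 0) {
    rlang::abort("zero-energy signal cannot be normalized",
                 class = "selfright_domain_error")
  }
  n <- length(f)
  # h[t] = sum_tau f(tau - t) g(tau): cross-correlation via full convolution
  # of g with the reversed f
  cc <- stats::convolve(g, f, conj = TRUE, type = "open")
  # convolve(..., type = "open") yields sum_tau f(tau - t) g(tau) ordered by
  # ascending lag t = -(n-1), ..., n-1
  lags <- -(n - 1):(n - 1)
  tibble::tibble(lag_s = lags / rate, h = cc / sqrt(ef * eg))
}
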