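#' Skin scattering model
#'
#' Fixed literature models for the wavelength dependence of skin scattering:
#' a power law for the reduced scattering coefficient,
#' `mus' = a * (lambda / 500 nm)^(-b)`, and a sixth-order polynomial fit for
#' the anisotropy factor `g(lambda)`. All attenuation coefficients are held
#' internally in mm^-1; the conventional `a` for skin is quoted in cm^-1 and
#' converted at construction.
#'
#' @param a_cm_inv reduced-scattering scale at 500 nm, cm^-1 (default 46).
#' @param b scattering power, dimensionless (default 1.421).
#' @param g_coeffs numeric length-7, polynomial coefficients of `g(lambda)`
#'   for degree 0..6 with `lambda` in nm.
#' @param valid_range wavelength validity window (nm) of the fits; the
#'   anisotropy polynomial diverges outside its fitted region.
#' @return object of class `otos_scattering_model`.
#' @export
scattering_model <- function(a_cm_inv = 46, b = 1.421,
                             g_coeffs = c(-5.603, 3.61e-2, -8.17e-5, 9.51e-8,
                                          -5.92e-11, 1.83e-14, -2.11e-18),
                             valid_range = c(450, 1000)) {
  if (!is.numeric(a_cm_inv) || a_cm_inv <= 0 || !is.numeric(b) || b <= 0) {
    otos_abort("scattering parameters a and b must be positive", "otos_config_error")
  }
  if (length(g_coeffs) != 7L || anyNA(g_coeffs)) {
    otos_abort("g_coeffs must be 7 finite polynomial coefficients", "otos_config_error")
  }
  if (length(valid_range) != 2L || valid_range[1] >= valid_range[2]) {
    otos_abort("valid_range must be an increasing pair of wavelengths", "otos_config_error")
  }
  model <- structure(list(a = a_cm_inv / 10, b = b, g_coeffs = g_coeffs,
                          valid_range = as.numeric(valid_range)),
                     class = "otos_scattering_model")
  # g must stay a physical anisotropy over the declared window
  gg <- horner(seq(valid_range[1], valid_range[2], by = 1), g_coeffs)
  if (any(gg <= 0 | gg >= 1)) {
    otos_abort("anisotropy polynomial leaves (0, 1) inside valid_range",
               "otos_model_validity_error")
  }
  model
}

horner <- function(x, coeffs) {
  acc <- rep(coeffs[length(coeffs)], length(x))
  for (k in rev(seq_len(length(coeffs) - 1L))) acc <- acc * x + coeffs[k]
  acc
}

check_in_range <- function(lambda_nm, model) {
  if (any(lambda_nm < model$valid_range[1] | lambda_nm > model$valid_range[2])) {
    otos_abort(sprintf("wavelength outside model validity range [%g, %g] nm",
                       model$valid_range[1], model$valid_range[2]),
               "otos_domain_error")
  }
}

#' Reduced scattering coefficient of skin
#'
#' `mus'(lambda) = a * (lambda / 500)^(-b)` in mm^-1, strictly decreasing in
#' wavelength.
#'
#' @param lambda_nm wavelength(s) in nm, within the model validity range.
#' @param model an [scattering_model()].
#' @return reduced scattering coefficient(s), mm^-1.
#' @export
reduced_scattering <- function(lambda_nm, model = scattering_model()) {
  stopifnot(inherits(model, "otos_scattering_model"))
  check_in_range(lambda_nm, model)
  model$a * (lambda_nm / 500)^(-model$b)
}

#' Anisotropy factor of skin
#'
#' Sixth-order polynomial fit `g(lambda)` evaluated by Horner recursion
#' (the coefficients span ~18 orders of magnitude in the powers of lambda).
#'
#' @inheritParams reduced_scattering
#' @return anisotropy factor(s) in (0, 1).
#' @export
anisotropy <- function(lambda_nm, model = scattering_model()) {
  stopifnot(inherits(model, "otos_scattering_model"))
  check_in_range(lambda_nm, model)
  g <- horner(lambda_nm, model$g_coeffs)
  if (any(g <= 0 | g >= 1)) {
    otos_abort("evaluated anisotropy outside (0, 1)", "otos_model_validity_error")
  }
  g
}

#' Scattering coefficient from reduced scattering and anisotropy
#'
#' `mus = mus' / (1 - g)`, the similarity relation between the reduced and
#' full scattering coefficients.
#'
#' @param mus_prime reduced scattering coefficient(s), mm^-1.
#' @param g anisotropy factor(s) in \[0, 1).
#' @return scattering coefficient(s), mm^-1.
#' @export
scattering_coefficient <- function(mus_prime, g) {
  if (any(g < 0 | g >= 1)) {
    otos_abort("anisotropy must lie in [0, 1) (g = 1 is singular)",
               "otos_singularity_error")
  }
  mus_prime / (1 - g)
}
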