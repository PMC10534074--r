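#' Integrating-sphere configuration
#'
#' Parameters of the reflectance normalization: the reflection factor of the
#' sphere plus reference standard (`rstd`), the sample refractive index used
#' for the specular term, and whether the specular (Fresnel) reflectance is
#' computed from `n_skin` or supplied as a fixed value.
#'
#' @param rstd reflection factor in (0, 1]; default 0.99, typical of a
#'   pressed-PTFE reflectance standard.
#' @param n_skin sample refractive index (>= 1); default 1.4, the usual
#'   tissue-optics value for skin.
#' @param r_fresnel_mode `"computed_from_n"` or `"fixed_value"`.
#' @param r_fresnel_value specular reflectance in \[0, 1) when mode is
#'   `"fixed_value"`.
#' @return object of class `otos_sphere_config`.
#' @export
sphere_config <- function(rstd = 0.99, n_skin = 1.4,
                          r_fresnel_mode = c("computed_from_n", "fixed_value"),
                          r_fresnel_value = NULL) {
  r_fresnel_mode <- match.arg(r_fresnel_mode)
  if (!is.numeric(rstd) || rstd <= 0 || rstd > 1) {
    otos_abort("rstd must lie in (0, 1]", "otos_config_error")
  }
  if (!is.numeric(n_skin) || n_skin < 1) {
    otos_abort("n_skin must be >= 1", "otos_config_error")
  }
  if (r_fresnel_mode == "fixed_value") {
    if (is.null(r_fresnel_value) || r_fresnel_value < 0 || r_fresnel_value >= 1) {
      otos_abort("fixed r_fresnel_value must lie in [0, 1)", "otos_config_error")
    }
  }
  structure(list(rstd = rstd, n_skin = n_skin,
                 r_fresnel_mode = r_fresnel_mode,
                 r_fresnel_value = r_fresnel_value),
            class = "otos_sphere_config")
}

#' Specular (Fresnel) reflectance at normal incidence
#'
#' `((n - 1) / (n + 1))^2` for an interface between air and a medium of
#' refractive index `n`.
#'
#' @param n refractive index, >= 1.
#' @return specular reflectance, dimensionless.
#' @export
fresnel_specular <- function(n) {
  if (!is.numeric(n) || any(n < 1)) {
    otos_abort("refractive index must be >= 1", "otos_domain_error")
  }
  ((n - 1) / (n + 1))^2
}

sphere_r_fresnel <- function(cfg) {
  if (cfg$r_fresnel_mode == "computed_from_n") fresnel_specular(cfg$n_skin)
  else cfg$r_fresnel_value
}

#' Reflectance spectrum container
#'
#' Total diffuse reflectance MR per wavelength. Values outside \[0, 1.05\]
#' are physically suspect (calibration drift) and are flagged, never
#' clamped, so that faults surface in reports.
#'
#' @param grid wavelengths (nm).
#' @param mr reflectance values.
#' @return object of class `otos_reflectance` with a logical `suspect` field.
#' @export
reflectance_spectrum <- function(grid, mr) {
  grid <- wavelength_grid(grid)
  mr <- as.numeric(mr)
  if (length(mr) != length(grid) || anyNA(mr)) {
    otos_abort("mr must match grid length and be free of NA", "otos_spectrum_error")
  }
  structure(list(grid = grid, mr = mr, suspect = mr < 0 | mr > 1.05),
            class = "otos_reflectance")
}

#' @export
print.otos_reflectance <- function(x, ...) {
  cat(sprintf("<otos_reflectance %d points, %.1f-%.1f nm, %d suspect>\n",
              length(x$grid), min(x$grid), max(x$grid), sum(x$suspect)))
  invisible(x)
}

#' Normalize raw spectra to total diffuse reflectance
#'
#' Applies the sphere calibration
#' `MR = rstd * (RR - R0) / (R1 - R0) + R_Fresnel`
#' pointwise, where `RR` is the sample reflection, `R0` the dark reading and
#' `R1` the reference-standard reading. The additive Fresnel term restores
#' the specular component lost at the sample port, making MR commensurate
#' with the forward solver's total reflectance.
#'
#' @param rr,r0,r1 `otos_spectrum` objects on identical grids.
#' @param cfg an [sphere_config()].
#' @return an `otos_reflectance`.
#' @export
compute_mr <- function(rr, r0, r1, cfg = sphere_config()) {
  stopifnot(inherits(rr, "otos_spectrum"), inherits(r0, "otos_spectrum"),
            inherits(r1, "otos_spectrum"), inherits(cfg, "otos_sphere_config"))
  g <- as.numeric(rr$grid)
  if (length(r0$grid) != length(g) || length(r1$grid) != length(g) ||
      any(as.numeric(r0$grid) != g) || any(as.numeric(r1$grid) != g)) {
    otos_abort("RR, R0 and R1 must share one wavelength grid",
               "otos_grid_mismatch_error")
  }
  denom <- r1$counts - r0$counts
  bad <- denom <= 0
  if (any(bad)) {
    otos_abort(sprintf(
      "reference does not exceed dark (R1 <= R0) at %d wavelength(s), e.g. %.1f nm",
      sum(bad), g[which(bad)[1L]]), "otos_calibration_error")
  }
  mr <- cfg$rstd * (rr$counts - r0$counts) / denom + sphere_r_fresnel(cfg)
  reflectance_spectrum(g, mr)
}
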