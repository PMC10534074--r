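#' Hemoglobin molar extinction table
#'
#' Loads a three-column text table `(wavelength_nm, eps_HbO2, eps_Hb)` of
#' molar extinction coefficients (base-10, L mol^-1 cm^-1) and wraps it
#' with linear interpolators. The bundled default is a synthetic
#' reconstruction of the canonical oxy/deoxy-hemoglobin compilation (see
#' `inst/extdata/hemoglobin_extinction_synthetic.tsv`), anchored to widely
#' quoted values and covering 450-1000 nm at 2 nm steps.
#'
#' @param path table file; default the bundled synthetic table.
#' @return object of class `otos_extinction` with fields `grid`,
#'   `eps_hbo2`, `eps_hb` and interpolation functions `f_hbo2`, `f_hb`.
#' @export
extinction_table <- function(path = system.file("extdata",
                                                "hemoglobin_extinction_synthetic.tsv",
                                                package = "otos")) {
  if (!nzchar(path) || !file.exists(path)) {
    otos_abort("extinction table file not found", "otos_io_error")
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("lambda", "eps_hbo2", "eps_hb"))
  if (anyNA(tab) || any(tab$eps_hbo2 <= 0) || any(tab$eps_hb <= 0)) {
    otos_abort("extinction coefficients must be positive and complete",
               "otos_parse_error")
  }
  ord <- order(tab$lambda)
  tab <- tab[ord, ]
  if (min(tab$lambda) > 450 || max(tab$lambda) < 1000) {
    otos_abort("extinction table must cover at least 450-1000 nm",
               "otos_parse_error")
  }
  structure(list(
    grid = wavelength_grid(tab$lambda),
    eps_hbo2 = tab$eps_hbo2,
    eps_hb = tab$eps_hb,
    f_hbo2 = stats::approxfun(tab$lambda, tab$eps_hbo2),
    f_hb = stats::approxfun(tab$lambda, tab$eps_hb)
  ), class = "otos_extinction")
}

#' @export
print.otos_extinction <- function(x, ...) {
  cat(sprintf("<otos_extinction %d points, %.0f-%.0f nm>\n",
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Melanin slope of an absorption spectrum
#'
#' Ordinary least-squares slope of `mua` versus wavelength restricted to
#' 630-700 nm. In this window hemoglobin absorption is low and flat, so the
#' slope tracks the epidermal melanin content and is the basis of the
#' skin-type classification.
#'
#' @param grid wavelengths, nm.
#' @param mua absorption coefficients, mm^-1 (NA entries are dropped).
#' @param range fit window, nm (default `c(630, 700)`).
#' @return OLS slope in mm^-1/nm.
#' @export
melanin_slope <- function(grid, mua, range = c(630, 700)) {
  grid <- as.numeric(grid)
  keep <- grid >= range[1] & grid <= range[2] & !is.na(mua)
  if (sum(keep) < 10L) {
    otos_abort(sprintf(
      "need at least 10 usable points in [%g, %g] nm for the melanin slope (have %d)",
      range[1], range[2], sum(keep)), "otos_insufficient_data_error")
  }
  unname(coef(lm(mua[keep] ~ grid[keep]))[2L])
}

#' Select analysis wavelengths from the melanin slope
#'
#' Implements the skin-type classification rule: the absolute value of the
#' 630-700 nm absorption slope maps to a group and a visible analysis
#' wavelength, with the infrared wavelength fixed at the 975 nm laser line.
#'
#' | group | skin | abs(slope) mm^-1/nm | lambda1 |
#' |-------|------|---------------------|---------|
#' | I     | fair | < 5e-4              | 622 nm  |
#' | II    | intermediate | 5e-4 .. 8e-4 | 624 nm |
#' | III   | brown | > 8e-4             | 626 nm  |
#'
#' Slopes exactly on a threshold are assigned to the lower group (the
#' published rule uses strict inequalities on both sides, leaving the
#' boundaries undefined; "<=" is the documented tie-break).
#'
#' @param slope melanin slope, mm^-1/nm (sign is ignored).
#' @param lambda2 infrared wavelength, nm; default 975.
#' @return object of class `otos_selection` with fields `slope`, `group`,
#'   `lambda1`, `lambda2`.
#' @export
select_wavelengths <- function(slope, lambda2 = 975) {
  if (!is.finite(slope)) otos_abort("slope must be finite", "otos_domain_error")
  s <- abs(slope)
  if (s <= 5e-4) {
    group <- "I_fair"; lambda1 <- 622
  } else if (s <= 8e-4) {
    group <- "II_intermediate"; lambda1 <- 624
  } else {
    group <- "III_brown"; lambda1 <- 626
  }
  structure(list(slope = slope, group = group,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "otos_selection")
}

#' Compose an absorption spectrum from chromophore concentrations
#'
#' `mua(lambda) = ln(10)/10 * sum_i eps_i(lambda) * C_i` in mm^-1, for
#' molar extinction in L mol^-1 cm^-1 (base 10) and concentrations in
#' mol/L: ln(10) converts decadic extinction to a natural-log absorption
#' coefficient and the factor 10 converts cm^-1 to mm^-1.
#'
#' @param eps list of extinction spectra (numeric vectors on one common
#'   grid, L mol^-1 cm^-1).
#' @param conc numeric concentrations, mol/L, one per spectrum.
#' @return absorption spectrum, mm^-1.
#' @export
compose_mua <- function(eps, conc) {
  if (!is.list(eps) || length(eps) != length(conc) || length(eps) == 0L) {
    otos_abort("need one concentration per extinction spectrum", "otos_domain_error")
  }
  len <- vapply(eps, length, 1L)
  if (any(len != len[1L])) {
    otos_abort("extinction spectra must share one grid", "otos_grid_mismatch_error")
  }
  mua <- numeric(len[1L])
  for (i in seq_along(eps)) mua <- mua + eps[[i]] * conc[i]
  log(10) * mua / 10
}

#' Two-wavelength hemoglobin solve
#'
#' Solves the 2x2 linear system relating the absorption coefficients at the
#' selected wavelength pair to the oxy- and deoxy-hemoglobin
#' concentrations:
#' \deqn{[HbO2] = (mua(l2) eHb(l1) - mua(l1) eHb(l2)) / D}
#' \deqn{[Hb]  = (mua(l1) eHbO2(l2) - mua(l2) eHbO2(l1)) / D}
#' with `D = eHb(l1) eHbO2(l2) - eHb(l2) eHbO2(l1)`. The pair must not be
#' isosbestic (`D` away from zero). Concentrations are reported in units
#' consistent with the extinction scaling; negative values (possible with
#' noisy absorption input) are flagged as out-of-model, not clamped.
#'
#' @param mua1,mua2 absorption coefficients at `lambda1`, `lambda2`, mm^-1.
#' @param table an [extinction_table()].
#' @param sel an [select_wavelengths()] result.
#' @return object of class `otos_chromophores` with `c_hbo2`, `c_hb`,
#'   `sto2` (percent, NA when out of model), `out_of_model`, `selection`.
#' @export
solve_concentrations <- function(mua1, mua2, table, sel) {
  stopifnot(inherits(table, "otos_extinction"), inherits(sel, "otos_selection"))
  e_hb1 <- table$f_hb(sel$lambda1); e_hb2 <- table$f_hb(sel$lambda2)
  e_o1 <- table$f_hbo2(sel$lambda1); e_o2 <- table$f_hbo2(sel$lambda2)
  if (anyNA(c(e_hb1, e_hb2, e_o1, e_o2))) {
    otos_abort("selected wavelengths outside extinction table coverage",
               "otos_domain_error")
  }
  D <- e_hb1 * e_o2 - e_hb2 * e_o1
  scale <- max(abs(c(e_hb1 * e_o2, e_hb2 * e_o1)))
  if (abs(D) < 1e-8 * scale) {
    otos_abort("ill-conditioned wavelength pair (isosbestic determinant)",
               "otos_illconditioned_error")
  }
  # undo the ln(10)/10 composition so concentrations come back in mol/L
  k <- 10 / log(10)
  c_hbo2 <- k * (mua2 * e_hb1 - mua1 * e_hb2) / D
  c_hb <- k * (mua1 * e_o2 - mua2 * e_o1) / D
  # a pure component recovered exactly leaves the other at round-off scale;
  # only genuinely negative concentrations are out of model
  eps <- 1e-10 * (abs(c_hbo2) + abs(c_hb))
  if (c_hbo2 < 0 && c_hbo2 >= -eps) c_hbo2 <- 0
  if (c_hb < 0 && c_hb >= -eps) c_hb <- 0
  out <- c_hbo2 < 0 || c_hb < 0
  sto2 <- if (!out && (c_hbo2 + c_hb) > 0) compute_sto2(c_hbo2, c_hb) else NA_real_
  structure(list(c_hbo2 = c_hbo2, c_hb = c_hb, sto2 = sto2,
                 out_of_model = out, selection = sel),
            class = "otos_chromophores")
}

#' Tissue oxygen saturation
#'
#' `StO2 = 100 * [HbO2] / ([HbO2] + [Hb])`, the oxygenated fraction of
#' total hemoglobin, in percent.
#'
#' @param c_hbo2,c_hb hemoglobin concentrations in any common unit.
#' @return StO2 in percent.
#' @export
compute_sto2 <- function(c_hbo2, c_hb) {
  total <- c_hbo2 + c_hb
  if (any(total <= 0)) {
    otos_abort("total hemoglobin must be positive to define a saturation",
               "otos_undefined_saturation_error")
  }
  100 * c_hbo2 / total
}
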