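#' Pipeline run configuration
#'
#' Collects every tunable of the StO2 workflow with its default. Arguments
#' override defaults; nested components accept their own constructors'
#' objects.
#'
#' @param sphere an [sphere_config()].
#' @param skin an [scattering_model()].
#' @param rte list of solver settings: `quadrature_order`,
#'   `convergence_tol`, `max_doublings`, `mua_bracket`, `tau_start`.
#' @param analysis list of analysis settings: `vis_range` (nm window
#'   inverted in the visible, default 600-700), `slope_range` (melanin fit
#'   window, default 630-700), `lambda_ir` (infrared point, default 975),
#'   `inversion_step_nm` (spacing of inverted wavelengths, default 2),
#'   `boxcar_half_width` (pixels, default 50).
#' @return object of class `otos_config`.
#' @export
otos_config <- function(sphere = sphere_config(), skin = scattering_model(),
                        rte = list(), analysis = list()) {
  stopifnot(inherits(sphere, "otos_sphere_config"),
            inherits(skin, "otos_scattering_model"))
  rte <- modifyList(list(quadrature_order = 8L, convergence_tol = 1e-6,
                         max_doublings = 60L, mua_bracket = c(1e-6, 50),
                         tau_start = 1e-5), rte)
  analysis <- modifyList(list(vis_range = c(600, 700),
                              slope_range = c(630, 700),
                              lambda_ir = 975, inversion_step_nm = 2,
                              boxcar_half_width = 50L), analysis)
  if (analysis$vis_range[1] < skin$valid_range[1] ||
      max(analysis$vis_range[2], analysis$lambda_ir) > skin$valid_range[2]) {
    otos_abort("analysis range must lie within the scattering-model validity range",
               "otos_config_error")
  }
  structure(list(sphere = sphere, skin = skin, rte = rte, analysis = analysis),
            class = "otos_config")
}

as_spectrum_input <- function(x, role, what) {
  if (inherits(x, "otos_spectrum")) return(x)
  if (is.character(x)) {
    missing <- !file.exists(x)
    if (any(missing)) {
      otos_abort(sprintf("%s file not found: %s", what, x[missing][1L]),
                 "otos_io_error")
    }
    specs <- lapply(x, read_spectrum, role = role)
    return(if (length(specs) == 1L) specs[[1L]] else average_spectra(specs))
  }
  if (is.list(x)) return(average_spectra(x))
  otos_abort(sprintf("%s must be a spectrum, a list of spectra, or file path(s)",
                     what), "otos_io_error")
}

#' Run the full StO2 pipeline on one measurement
#'
#' Executes, in order: read and average the raw spectra, boxcar-smooth
#' them, normalize to total diffuse reflectance MR, invert MR for the
#' absorption spectrum over the visible analysis window and at the
#' infrared point, fit the 630-700 nm melanin slope, select the analysis
#' wavelength pair from the slope, solve the two-wavelength hemoglobin
#' system, and compute StO2.
#'
#' @param rr,r0,r1 sample / dark / reference inputs: an `otos_spectrum`, a
#'   list of them (averaged), or file path(s) (read and averaged). The dark
#'   measurement is `r0`, the reference standard `r1`.
#' @param config an [otos_config()].
#' @param table an [extinction_table()].
#' @return object of class `otos_report`: StO2 (percent), the wavelength
#'   selection (slope, group, lambda1/lambda2), concentrations, absorption
#'   coefficients at the pair, MR summary, and quality flags.
#' @export
run_otos <- function(rr, r0, r1, config = otos_config(),
                     table = extinction_table()) {
  stopifnot(inherits(config, "otos_config"))
  rr <- as_spectrum_input(rr, "sample_RR", "sample (RR)")
  r0 <- as_spectrum_input(r0, "dark_R0", "dark (R0)")
  r1 <- as_spectrum_input(r1, "reference_R1", "reference (R1)")
  hw <- config$analysis$boxcar_half_width
  rr <- boxcar_smooth(rr, hw); r0 <- boxcar_smooth(r0, hw)
  r1 <- boxcar_smooth(r1, hw)

  mr <- compute_mr(rr, r0, r1, config$sphere)

  vis <- config$analysis$vis_range
  lam_inv <- seq(vis[1], vis[2], by = config$analysis$inversion_step_nm)
  lam_all <- sort(unique(c(lam_inv, config$analysis$lambda_ir)))
  g <- as.numeric(mr$grid)
  if (min(lam_all) < min(g) || max(lam_all) > max(g)) {
    otos_abort("measurement grid does not cover the analysis wavelengths",
               "otos_calibration_error")
  }
  mr_at <- stats::approx(g, mr$mr, xout = lam_all)$y
  mr_sub <- reflectance_spectrum(lam_all, mr_at)

  n <- config$sphere$n_skin
  quad <- make_quadrature(config$rte$quadrature_order, n)
  inv <- invert_spectrum(mr_sub, config$skin, n, quad,
                         bracket = config$rte$mua_bracket,
                         tol = config$rte$convergence_tol,
                         max_doublings = config$rte$max_doublings,
                         tau_start = config$rte$tau_start)

  sr <- config$analysis$slope_range
  slope <- melanin_slope(inv$grid, inv$mua, range = sr)
  sel <- select_wavelengths(slope, lambda2 = config$analysis$lambda_ir)

  mua_at <- function(lambda) {
    i <- which(inv$grid == lambda)
    if (length(i) != 1L || is.na(inv$mua[i])) {
      otos_abort(sprintf(
        "absorption at %g nm unavailable (out of gamut or not on the inversion grid)",
        lambda), "otos_gamut_error")
    }
    inv$mua[i]
  }
  mua1 <- mua_at(sel$lambda1)
  mua2 <- mua_at(sel$lambda2)
  chrom <- solve_concentrations(mua1, mua2, table, sel)

  structure(list(
    sto2 = chrom$sto2,
    selection = sel,
    c_hbo2 = chrom$c_hbo2, c_hb = chrom$c_hb,
    mua_lambda1 = mua1, mua_lambda2 = mua2,
    mua_spectrum = inv[c("grid", "mua", "flagged")],
    mr_summary = list(min = min(mr$mr), max = max(mr$mr),
                      n_suspect = sum(mr$suspect)),
    flags = list(out_of_gamut_nm = inv$grid[inv$flagged],
                 negative_concentrations = isTRUE(chrom$out_of_model),
                 suspect_mr = sum(mr$suspect) > 0L),
    config = config
  ), class = "otos_report")
}

#' @export
print.otos_report <- function(x, ...) {
  cat("StO2 report\n")
  cat(sprintf("  StO2            : %s %%\n",
              if (is.na(x$sto2)) "NA (out of model)" else sprintf("%.2f", x$sto2)))
  cat(sprintf("  melanin slope   : %.3e mm^-1/nm  (group %s)\n",
              x$selection$slope, x$selection$group))
  cat(sprintf("  wavelength pair : %g / %g nm\n",
              x$selection$lambda1, x$selection$lambda2))
  cat(sprintf("  mua(l1), mua(l2): %.4f, %.4f mm^-1\n",
              x$mua_lambda1, x$mua_lambda2))
  if (length(x$flags$out_of_gamut_nm)) {
    cat(sprintf("  flagged channels: %d out of gamut\n",
                length(x$flags$out_of_gamut_nm)))
  }
  if (x$flags$negative_concentrations) {
    cat("  WARNING: negative concentration(s), StO2 out of model\n")
  }
  invisible(x)
}

report_to_list <- function(report) {
  list(sto2_percent = report$sto2,
       slope_mm1_per_nm = report$selection$slope,
       group = report$selection$group,
       lambda1_nm = report$selection$lambda1,
       lambda2_nm = report$selection$lambda2,
       c_hbo2 = report$c_hbo2, c_hb = report$c_hb,
       mua_lambda1_mm1 = report$mua_lambda1,
       mua_lambda2_mm1 = report$mua_lambda2,
       mr_min = report$mr_summary$min, mr_max = report$mr_summary$max,
       n_suspect_mr = report$mr_summary$n_suspect,
       out_of_gamut_nm = report$flags$out_of_gamut_nm,
       negative_concentrations = report$flags$negative_concentrations)
}

#' Run the pipeline over a staged occlusion series
#'
#' Processes a fixture directory written by [write_occlusion_series()]
#' (spectra triples plus JSON sidecars) stage by stage and returns the
#' per-stage reports with a summary table of StO2 versus stage.
#'
#' @param series_dir directory of staged fixtures.
#' @param config an [otos_config()].
#' @param table an [extinction_table()].
#' @return list with `reports` (per stage) and `summary` (data.frame with
#'   stage, tag, pressure, true and recovered StO2).
#' @export
run_occlusion_batch <- function(series_dir, config = otos_config(),
                                table = extinction_table()) {
  sidecars <- sort(list.files(series_dir, pattern = "^stage_[0-9]+_.*\\.json$",
                              full.names = TRUE))
  if (length(sidecars) == 0L) {
    otos_abort(sprintf("no staged fixtures found in %s", series_dir),
               "otos_io_error")
  }
  reports <- list()
  rows <- list()
  for (sc in sidecars) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    stem <- sub("\\.json$", "", sc)
    rep <- run_otos(paste0(stem, "_RR.csv"), paste0(stem, "_R0.csv"),
                    paste0(stem, "_R1.csv"), config = config, table = table)
    reports[[meta$tag]] <- rep
    rows[[length(rows) + 1L]] <- data.frame(
      stage = meta$stage, tag = meta$tag,
      pressure_mmHg = meta$pressure_mmHg %||% NA_real_,
      true_sto2 = meta$true_sto2 %||% NA_real_,
      sto2 = rep$sto2)
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(summary$stage), ]
  rownames(summary) <- NULL
  list(reports = reports, summary = summary)
}
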