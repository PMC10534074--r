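#' Tissue phantom: ground-truth chromophore composition
#'
#' A homogeneous skin phantom described by oxy/deoxy-hemoglobin
#' concentrations, a melanin absorption scale, and a flat background
#' absorption. The melanin term follows the power law
#' `melanin_scale * (lambda/500)^(-3.46)` standard in the skin-optics
#' literature; the analysis pipeline never assumes this form (it only uses
#' the 630-700 nm slope), which keeps generator and analysis independent.
#'
#' @param c_hbo2,c_hb hemoglobin concentrations, mol/L.
#' @param melanin_scale melanin absorption at 500 nm, mm^-1.
#' @param baseline wavelength-independent background absorption, mm^-1.
#' @return object of class `otos_phantom` with derived `true_sto2`.
#' @export
tissue_phantom <- function(c_hbo2, c_hb, melanin_scale = 0, baseline = 0) {
  if (any(c(c_hbo2, c_hb, melanin_scale, baseline) < 0)) {
    otos_abort("phantom fields must be non-negative", "otos_domain_error")
  }
  if (c_hbo2 + c_hb <= 0) {
    otos_abort("phantom needs some hemoglobin", "otos_domain_error")
  }
  structure(list(c_hbo2 = c_hbo2, c_hb = c_hb,
                 melanin_scale = melanin_scale, baseline = baseline,
                 true_sto2 = 100 * c_hbo2 / (c_hbo2 + c_hb)),
            class = "otos_phantom")
}

#' Healthy-palm phantom defaults
#'
#' Ground truth for a healthy, well-perfused palm: total hemoglobin
#' 1e-4 mol/L (about 4 percent cutaneous blood volume), StO2 98 percent,
#' melanin 0.001 mm^-1 at 500 nm (glabrous palmar epidermis is nearly
#' melanin-free), and a residual non-heme background of 5e-4 mm^-1. See the
#' methods vignette for the sensitivity analysis behind these choices.
#'
#' @param sto2 true saturation, percent.
#' @param total_hb total hemoglobin, mol/L.
#' @param melanin_scale,baseline see [tissue_phantom()].
#' @return an `otos_phantom`.
#' @export
healthy_palm_phantom <- function(sto2 = 98, total_hb = 1e-4,
                                 melanin_scale = 0.001, baseline = 5e-4) {
  tissue_phantom(c_hbo2 = total_hb * sto2 / 100,
                 c_hb = total_hb * (1 - sto2 / 100),
                 melanin_scale = melanin_scale, baseline = baseline)
}

#' Absorption spectrum of a phantom
#'
#' Composes the ground-truth absorption: hemoglobin via [compose_mua()],
#' plus the melanin power law and the flat baseline.
#'
#' @param phantom an [tissue_phantom()].
#' @param grid wavelengths, nm, within the extinction table coverage.
#' @param table an [extinction_table()].
#' @return absorption spectrum, mm^-1.
#' @export
phantom_mua <- function(phantom, grid, table = extinction_table()) {
  stopifnot(inherits(phantom, "otos_phantom"), inherits(table, "otos_extinction"))
  grid <- as.numeric(grid)
  eo <- table$f_hbo2(grid); eh <- table$f_hb(grid)
  if (anyNA(eo) || anyNA(eh)) {
    otos_abort("grid outside extinction table coverage", "otos_domain_error")
  }
  compose_mua(list(eo, eh), c(phantom$c_hbo2, phantom$c_hb)) +
    phantom$melanin_scale * (grid / 500)^(-3.46) +
    phantom$baseline
}

# Smooth synthetic lamp spectrum (blackbody-like tungsten shape, counts).
lamp_spectrum <- function(grid, peak_counts = 52000, temp_K = 2850) {
  lam_m <- grid * 1e-9
  b <- 1 / (lam_m^5 * (exp(0.0143877688 / (lam_m * temp_K)) - 1))
  peak_counts * b / max(b)
}

#' Generate a synthetic RR/R0/R1 measurement triple
#'
#' Runs the forward radiative-transfer model on the phantom absorption
#' spectrum to get MR(lambda), then inverts the sphere normalization to
#' synthesize raw counts around a smooth tungsten-like lamp spectrum and a
#' constant dark floor:
#' `RR = R0 + (MR - RFresnel) * (R1 - R0) / rstd`.
#' Multiplicative Gaussian noise of relative sigma `noise_sigma` is applied
#' per pixel to all three spectra (shot/gain noise at high counts). The
#' default 0.25 nm pixel pitch matches the spectrometer the acquisition
#' emulates, so the pipeline's boxcar half-width of 50 px spans about
#' 12.5 nm. MR is computed exactly on a 1 nm subgrid and interpolated by
#' spline to the acquisition grid (MR is smooth; the interpolation error is
#' far below both the noise floor and the solver tolerance).
#'
#' @param phantom an [tissue_phantom()].
#' @param seed integer seed; output is bit-identical per seed.
#' @param noise_sigma relative noise standard deviation (>= 0).
#' @param cfg an [sphere_config()].
#' @param model an [scattering_model()].
#' @param table an [extinction_table()].
#' @param grid acquisition wavelength grid, nm.
#' @param quad_order adding-doubling quadrature order for the forward model.
#' @param dark_counts dark floor, counts.
#' @return list with `otos_spectrum` elements `rr`, `r0`, `r1`, plus
#'   `truth` (phantom, seed, noise_sigma).
#' @export
generate_measurement <- function(phantom, seed, noise_sigma = 0,
                                 cfg = sphere_config(),
                                 model = scattering_model(),
                                 table = extinction_table(),
                                 grid = seq(450, 1000, by = 0.25),
                                 quad_order = 8L,
                                 dark_counts = 1800) {
  stopifnot(inherits(phantom, "otos_phantom"))
  if (noise_sigma < 0) otos_abort("noise_sigma must be >= 0", "otos_domain_error")
  grid <- as.numeric(grid)
  coarse <- unique(c(seq(min(grid), max(grid), by = 1), max(grid)))
  mua <- phantom_mua(phantom, coarse, table)
  musp <- reduced_scattering(coarse, model)
  g <- anisotropy(coarse, model)
  mus <- scattering_coefficient(musp, g)
  n <- cfg$n_skin
  quad <- make_quadrature(quad_order, n)
  mr_coarse <- vapply(seq_along(coarse), function(i) {
    forward_mr_core(mua[i], mus[i], g[i], n, quad)
  }, numeric(1))
  if (any(mr_coarse < 0 | mr_coarse > 1)) {
    otos_abort("forward model produced reflectance outside [0, 1]",
               "otos_generator_error")
  }
  mr <- stats::spline(coarse, mr_coarse, xout = grid)$y
  rf <- sphere_r_fresnel(cfg)
  r1 <- lamp_spectrum(grid)
  r0 <- rep(dark_counts, length(grid))
  rr <- r0 + (mr - rf) * (r1 - r0) / cfg$rstd
  set.seed(as.integer(seed))
  noisy <- function(x) pmax(x * (1 + noise_sigma * rnorm(length(x))), 0)
  list(
    rr = intensity_spectrum(grid, noisy(rr), "sample_RR"),
    r0 = intensity_spectrum(grid, noisy(r0), "dark_R0"),
    r1 = intensity_spectrum(grid, noisy(r1), "reference_R1"),
    truth = list(phantom = phantom, seed = as.integer(seed),
                 noise_sigma = noise_sigma)
  )
}

#' Occlusion protocol description
#'
#' Cuff pressures applied during a vascular occlusion test, the target mean
#' StO2 at each pressure, and the recovery stages measured after cuff
#' release. Defaults follow the published group means of a stepped
#' 0/60/80/100 mmHg occlusion: 95.69, 94.78, 92.45 and 91.46 percent.
#'
#' @param pressures cuff pressures, mmHg, non-decreasing.
#' @param sto2_means target mean StO2 per pressure, percent, non-increasing.
#' @param recovery_points number of post-release measurements.
#' @param hyperemia_overshoot percent above baseline reached at the first
#'   recovery point (0 disables the reactive-hyperemia overshoot).
#' @return object of class `otos_protocol`.
#' @export
occlusion_protocol <- function(pressures = c(0, 60, 80, 100),
                               sto2_means = c(95.69, 94.78, 92.45, 91.46),
                               recovery_points = 2L,
                               hyperemia_overshoot = 0) {
  if (length(pressures) != length(sto2_means)) {
    otos_abort("one target StO2 per pressure", "otos_config_error")
  }
  if (is.unsorted(pressures)) {
    otos_abort("pressures must be non-decreasing", "otos_config_error")
  }
  if (is.unsorted(rev(sto2_means))) {
    otos_abort("sto2_means must be non-increasing during occlusion",
               "otos_config_error")
  }
  if (any(sto2_means <= 0 | sto2_means >= 100)) {
    otos_abort("target StO2 must lie in (0, 100)", "otos_domain_error")
  }
  structure(list(pressures = pressures, sto2_means = sto2_means,
                 recovery_points = as.integer(recovery_points),
                 hyperemia_overshoot = hyperemia_overshoot),
            class = "otos_protocol")
}

#' Simulate a stepped-pressure occlusion series
#'
#' For each stage, rescales the base phantom's oxy/deoxy split at fixed
#' total hemoglobin to hit the stage's target StO2 plus seeded
#' volunteer-level jitter (one common offset per series, sd
#' `jitter_series_sd`, plus small per-stage scatter, sd `jitter_stage_sd`),
#' then generates an RR/R0/R1 triple. Recovery stages climb back toward
#' (optionally above) the baseline value.
#'
#' @param protocol an [occlusion_protocol()].
#' @param phantom_base an [tissue_phantom()]; supplies total hemoglobin,
#'   melanin and baseline.
#' @param seed integer seed (controls jitter and measurement noise).
#' @param noise_sigma relative measurement noise.
#' @param jitter_series_sd,jitter_stage_sd jitter magnitudes, StO2 percent.
#' @param ... passed to [generate_measurement()].
#' @return list of stages, each with `tag`, `pressure_mmHg` (NA in
#'   recovery), `true_sto2`, and the measurement triple in `measurement`.
#' @export
simulate_occlusion_series <- function(protocol = occlusion_protocol(),
                                      phantom_base = healthy_palm_phantom(),
                                      seed = 1L, noise_sigma = 0,
                                      jitter_series_sd = 1.0,
                                      jitter_stage_sd = 0.1, ...) {
  stopifnot(inherits(protocol, "otos_protocol"),
            inherits(phantom_base, "otos_phantom"))
  total <- phantom_base$c_hbo2 + phantom_base$c_hb
  base <- protocol$sto2_means[1L]
  last <- protocol$sto2_means[length(protocol$sto2_means)]
  drop <- base - last
  ov <- protocol$hyperemia_overshoot
  rec <- if (protocol$recovery_points > 0L) {
    frac <- rev(seq_len(protocol$recovery_points)) / (protocol$recovery_points + 1)
    targets <- base - frac * 0.45 * drop
    if (ov > 0) targets[1L] <- base + ov
    targets
  } else numeric(0)
  tags <- c(sprintf("occlusion_%03.0fmmHg", protocol$pressures),
            if (length(rec)) sprintf("recovery_%d", seq_along(rec)))
  targets <- c(protocol$sto2_means, rec)
  set.seed(as.integer(seed))
  offset <- rnorm(1, 0, jitter_series_sd)
  stage_jit <- rnorm(length(targets), 0, jitter_stage_sd)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, length(targets))
  true_sto2 <- pmin(pmax(targets + offset + stage_jit, 0.5), 99.5)
  lapply(seq_along(targets), function(i) {
    ph <- tissue_phantom(total * true_sto2[i] / 100,
                         total * (1 - true_sto2[i] / 100),
                         melanin_scale = phantom_base$melanin_scale,
                         baseline = phantom_base$baseline)
    list(tag = tags[i],
         pressure_mmHg = if (i <= length(protocol$pressures))
           protocol$pressures[i] else NA_real_,
         true_sto2 = true_sto2[i],
         measurement = generate_measurement(ph, seed = stage_seeds[i],
                                            noise_sigma = noise_sigma, ...))
  })
}

#' Write an occlusion series to a fixture directory
#'
#' Emits, per stage, the three spectra in the two-column text format plus a
#' JSON sidecar with the ground truth (tag, pressure, true StO2, seed).
#'
#' @param series result of [simulate_occlusion_series()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_occlusion_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(series)) {
    st <- series[[i]]
    stem <- file.path(dir, sprintf("stage_%02d_%s", i, st$tag))
    write_spectrum(st$measurement$rr, paste0(stem, "_RR.csv"))
    write_spectrum(st$measurement$r0, paste0(stem, "_R0.csv"))
    write_spectrum(st$measurement$r1, paste0(stem, "_R1.csv"))
    jsonlite::write_json(
      list(stage = i, tag = st$tag, pressure_mmHg = st$pressure_mmHg,
           true_sto2 = st$true_sto2,
           seed = st$measurement$truth$seed,
           noise_sigma = st$measurement$truth$noise_sigma),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Monte-Carlo photon-transport oracle
#'
#' An MCML-style random walk, independent of the adding-doubling solver,
#' used to validate it: exponential step sampling with `mut = mua + mus`,
#' Henyey-Greenstein direction sampling, Fresnel reflection/refraction with
#' total internal reflection at the top boundary, survival-weight
#' absorption with Russian roulette. Returns the total reflectance
#' (specular plus escaping diffuse weight) and a standard error, and is
#' deterministic per seed. Photons still alive after `max_steps` scattering
#' events are dropped and their weight reported in `lost`; with the default
#' cap this truncation is far below the standard error.
#'
#' @param props an [slab_properties()] (semi-infinite regime).
#' @param n_photons number of photons, >= 1e4.
#' @param seed integer seed.
#' @param max_steps per-photon scattering-event cap.
#' @return list with `estimate` (total reflectance), `se`, `lost`,
#'   `n_photons`.
#' @export
mc_photon_oracle <- function(props, n_photons = 1e5, seed = 1L,
                             max_steps = 1e7) {
  stopifnot(inherits(props, "otos_slab"))
  if (props$regime != "semi_infinite") {
    otos_abort("the Monte-Carlo oracle models the semi-infinite regime",
               "otos_domain_error")
  }
  if (n_photons < 1e4) {
    otos_abort("use at least 1e4 photons", "otos_domain_error")
  }
  rs <- fresnel_specular(props$n)
  res <- mc_reflectance_cpp(props$mua, props$mus, props$g, props$n,
                            as.double(n_photons), as.double(seed),
                            as.double(max_steps))
  list(estimate = rs + (1 - rs) * res[1L],
       se = (1 - rs) * res[2L],
       lost = res[3L],
       n_photons = n_photons)
}
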