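test_that("phantom_mua reduces to its components", {
  grid <- seq(600, 700, by = 5)

  # hemoglobin only: matches compose_mua exactly
  ph <- tissue_phantom(6e-5, 4e-5)
  expected <- compose_mua(list(ext_tab$f_hbo2(grid), ext_tab$f_hb(grid)),
                          c(6e-5, 4e-5))
  expect_equal(phantom_mua(ph, grid, ext_tab), expected)

  # baseline only: flat
  ph2 <- tissue_phantom(1e-12, 1e-12, baseline = 0.01)
  expect_equal(phantom_mua(ph2, grid, ext_tab), rep(0.01, length(grid)),
               tolerance = 1e-6)

  # melanin-only: negative 630-700 slope, magnitude increasing with scale
  lam <- seq(630, 700, by = 1)
  slopes <- vapply(c(0.05, 0.2, 0.5), function(m)
    melanin_slope(lam, phantom_mua(tissue_phantom(1e-12, 1e-12,
                                                  melanin_scale = m),
                                   lam, ext_tab)), numeric(1))
  expect_true(all(slopes < 0))
  expect_true(all(diff(abs(slopes)) > 0))

  expect_error(phantom_mua(ph, seq(100, 200, by = 10), ext_tab),
               class = "otos_domain_error")
  expect_equal(tissue_phantom(0.98, 0.02)$true_sto2, 98)
})

test_that("generate_measurement is deterministic and invertible", {
  ph <- healthy_palm_phantom()
  grid <- seq(595, 1000, by = 0.5)  # smaller grid for test speed

  m1 <- generate_measurement(ph, seed = 5, noise_sigma = 0.01, grid = grid)
  m2 <- generate_measurement(ph, seed = 5, noise_sigma = 0.01, grid = grid)
  expect_identical(m1$rr$counts, m2$rr$counts)
  expect_identical(m1$r1$counts, m2$r1$counts)
  m3 <- generate_measurement(ph, seed = 6, noise_sigma = 0.01, grid = grid)
  expect_false(identical(m1$rr$counts, m3$rr$counts))

  # noiseless: normalization recovers the forward-model MR, and inversion
  # recovers the phantom absorption to 1e-3 relative
  m0 <- generate_measurement(ph, seed = 1, noise_sigma = 0, grid = grid)
  mr <- compute_mr(m0$rr, m0$r0, m0$r1, sphere_config())
  lam <- seq(620, 700, by = 10)
  mr_at <- reflectance_spectrum(lam, stats::approx(as.numeric(mr$grid), mr$mr,
                                                   xout = lam)$y)
  inv <- invert_spectrum(mr_at, scattering_model(), 1.4, q8_14)
  mua_true <- phantom_mua(ph, lam, ext_tab)
  expect_lt(max(abs(inv$mua - mua_true) / mua_true), 1e-3)
})

test_that("occlusion protocol validates and the series tracks its targets", {
  expect_error(occlusion_protocol(pressures = c(60, 0)),
               class = "otos_config_error")
  expect_error(occlusion_protocol(sto2_means = c(90, 95, 92, 91)),
               class = "otos_config_error")
  expect_error(occlusion_protocol(sto2_means = c(101, 95, 92, 91)),
               class = "otos_domain_error")

  grid <- seq(595, 1000, by = 1)
  ser <- simulate_occlusion_series(seed = 9, grid = grid)
  expect_length(ser, 6)  # 4 occlusion stages + 2 recovery points
  truths <- vapply(ser, `[[`, numeric(1), "true_sto2")
  # strictly decreasing over the occlusion stages
  expect_true(all(diff(truths[1:4]) < 0))
  # recovery climbs back toward baseline
  expect_true(all(truths[5:6] > truths[4]))

  # reactive-hyperemia overshoot exceeds the resting value
  ser_ov <- simulate_occlusion_series(
    occlusion_protocol(hyperemia_overshoot = 2), seed = 9, grid = grid)
  t_ov <- vapply(ser_ov, `[[`, numeric(1), "true_sto2")
  expect_gt(t_ov[5], t_ov[1])

  # determinism
  ser2 <- simulate_occlusion_series(seed = 9, grid = grid)
  expect_identical(vapply(ser2, `[[`, numeric(1), "true_sto2"), truths)
})

test_that("write_occlusion_series emits readable fixtures with sidecars", {
  dir <- withr::local_tempdir()
  grid <- seq(595, 1000, by = 1)
  ser <- simulate_occlusion_series(
    occlusion_protocol(pressures = c(0, 100), sto2_means = c(96, 91),
                       recovery_points = 0L),
    seed = 2, grid = grid)
  write_occlusion_series(ser, dir)
  files <- list.files(dir)
  expect_length(grep("_RR\\.csv$", files), 2)
  expect_length(grep("\\.json$", files), 2)
  meta <- jsonlite::read_json(file.path(dir, grep("01_.*json$", files, value = TRUE)))
  expect_equal(meta$pressure_mmHg, 0)
  sp <- read_spectrum(file.path(dir, grep("01_.*_RR", files, value = TRUE)))
  expect_length(sp$counts, length(grid))
})

test_that("mc_photon_oracle limits, determinism, and error scaling", {
  # no scattering, matched boundary: nothing returns
  mc0 <- mc_photon_oracle(slab_properties(1, 0, 0, 1), 1e4, seed = 1)
  expect_equal(mc0$estimate, 0)

  # determinism per seed
  p <- slab_properties(0.1, 16, 0.9, 1.4)
  a <- mc_photon_oracle(p, 1e4, seed = 7)
  b <- mc_photon_oracle(p, 1e4, seed = 7)
  expect_identical(a$estimate, b$estimate)

  # SE scales as 1/sqrt(n_photons)
  c10 <- mc_photon_oracle(p, 1e5, seed = 7)
  expect_equal(a$se / c10$se, sqrt(10), tolerance = 0.15)

  expect_error(mc_photon_oracle(p, 100, seed = 1), class = "otos_domain_error")
})

test_that("mc_photon_oracle conservative-medium limit", {
  # mua = 0, n = 1: every photon eventually returns; the step cap drops a
  # known weight (reported as `lost`), included in the tolerance
  mc <- mc_photon_oracle(slab_properties(0, 16, 0, 1), 2e4, seed = 5,
                         max_steps = 1e8)
  expect_lt(abs(mc$estimate - 1), 3 * mc$se + mc$lost)
  expect_lt(mc$lost, 1e-3)
})
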