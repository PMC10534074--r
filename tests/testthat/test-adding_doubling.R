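test_that("make_quadrature builds a normalized, critical-angle-aware scheme", {
  expect_equal(sum(q8_1$w), 1, tolerance = 1e-12)
  expect_equal(max(q8_1$nu), 1)  # collimated-beam node
  expect_true(all(q8_1$nu > 0 & q8_1$nu <= 1))

  nc <- sqrt(1 - 1 / 1.4^2)
  expect_true(any(q8_14$nu < nc))  # TIR cone resolved
  expect_equal(max(q8_14$nu), 1)

  # hemispheric moment of f(nu) = nu is exact
  expect_equal(sum(q8_1$w * q8_1$nu), 0.5, tolerance = 1e-10)
  expect_equal(sum(q8_14$w * q8_14$nu), 0.5, tolerance = 1e-10)

  expect_error(make_quadrature(7), class = "otos_quadrature_error")
  expect_error(make_quadrature(2), class = "otos_quadrature_error")
})

test_that("hg_redistribution is isotropic at g=0 and conserves energy", {
  h0 <- hg_redistribution(0, q8_1)
  expect_equal(h0$hp, matrix(1, 8, 8))
  expect_equal(h0$hm, matrix(1, 8, 8))

  for (g in c(0.3, 0.9)) {
    h <- hg_redistribution(g, q8_1)
    sums <- as.numeric(q8_1$w %*% (h$hp + h$hm))
    expect_equal(sums, rep(2, 8), tolerance = 1e-8)
  }
})

test_that("unnormalized redistribution matches direct azimuthal integration", {
  g <- 0.9
  h <- hg_redistribution(g, q8_1, normalize = FALSE)
  for (i in c(1, 4, 8)) for (j in c(2, 6, 8)) {
    expect_equal(h$hp[i, j], hg_direct(q8_1$nu[i], q8_1$nu[j], g),
                 tolerance = 1e-6)
    expect_equal(h$hm[i, j], hg_direct(-q8_1$nu[i], q8_1$nu[j], g),
                 tolerance = 1e-6)
  }
})

test_that("thin-layer initialization has the single-scattering limits", {
  # pure absorber: no reflection, diagonal transmission ~ exp(-tau/nu)
  abs_props <- slab_properties(1, 0, 0, 1)
  lay <- initialize_thin_layer(abs_props, q8_1, 1e-5)
  expect_equal(max(abs(lay$R)), 0, tolerance = 1e-12)
  expect_equal(diag(lay$T), exp(-1e-5 / q8_1$nu), tolerance = 1e-9)

  # conservative thin layer: flux deficit bounded by tau^2
  con <- slab_properties(0, 1, 0.5, 1)
  tau <- 1e-4
  lc <- initialize_thin_layer(con, q8_1, tau)
  expect_true(max(abs(colSums(lc$R + lc$T) - 1)) <= tau^2)

  expect_error(initialize_thin_layer(con, q8_1, 0), class = "otos_domain_error")
})

test_that("doubling is self-consistent under refinement", {
  props <- slab_properties(0.1, 10, 0.7, 1)
  tau <- 4e-6
  a <- initialize_thin_layer(props, q8_1, tau)
  b <- initialize_thin_layer(props, q8_1, tau / 4)
  b <- double_layer(double_layer(b))
  expect_equal(b$R, a$R, tolerance = 1e-8)
  expect_equal(b$T, a$T, tolerance = 1e-8)

  # one extra halving/doubling leaves a built slab unchanged
  k <- 10
  slab_a <- a; for (i in 1:k) slab_a <- double_layer(slab_a)
  slab_b <- b; for (i in 1:k) slab_b <- double_layer(slab_b)
  expect_equal(slab_b$R, slab_a$R, tolerance = 1e-8)
})

test_that("doubling identities: zero-thickness and pure absorber", {
  # zero-thickness layer (R = 0, T = identity transport) is a fixed point
  idl <- structure(list(R = matrix(0, 8, 8), T = diag(8), tau = 0, quad = q8_1),
                   class = "otos_layer")
  d <- double_layer(idl)
  expect_equal(d$R, idl$R)
  expect_equal(d$T, idl$T)

  # pure absorber: per-direction transmitted flux squares under doubling
  lay <- initialize_thin_layer(slab_properties(2, 0, 0, 1), q8_1, 0.01)
  dd <- double_layer(lay)
  expect_equal(diag(dd$T), diag(lay$T)^2, tolerance = 1e-12)
})

test_that("add_boundary handles matched and mismatched interfaces", {
  lay <- initialize_thin_layer(slab_properties(0.1, 10, 0.7, 1), q8_1, 1e-5)
  for (i in 1:18) lay <- double_layer(lay)
  expect_identical(add_boundary(lay, 1), lay)

  # conservative finite slab with lossless mismatched interfaces: all flux
  # leaves through one side or the other
  con <- initialize_thin_layer(slab_properties(0, 10, 0.5, 1.4), q8_14, 1e-5)
  for (i in 1:18) con <- double_layer(con)  # tau ~ 2.6
  bounded <- add_boundary(con, 1.4, bottom = TRUE)
  flux_out <- colSums(bounded$R + bounded$T)
  expect_equal(flux_out[q8_14$beam], 1, tolerance = 1e-5)

  # internal-reflection trapping: for an absorbing high-albedo slab the
  # mismatched boundary *lowers* total reflectance (trapped light gets
  # absorbed); both this solver and the MC oracle agree on the direction
  mr1 <- forward_reflectance(slab_properties(0.1, 16, 0.9, 1), q8_1)
  mr14 <- forward_reflectance(slab_properties(0.1, 16, 0.9, 1.4), q8_14)
  expect_true(mr14 < mr1)
})

test_that("forward_reflectance has the physical limits", {
  # pure absorber, matched boundary: nothing comes back
  expect_equal(forward_reflectance(slab_properties(1, 0, 0, 1), q8_1), 0)
  # conservative medium reflects everything (criterion tolerance 1e-3)
  expect_equal(forward_reflectance(slab_properties(0, 16, 0.9, 1), q8_1), 1,
               tolerance = 1e-3)
  # mismatched quadrature is rejected
  expect_error(forward_reflectance(slab_properties(1, 1, 0, 1.4), q8_1),
               class = "otos_quadrature_error")
})

test_that("forward_reflectance is strictly decreasing in absorption", {
  for (g in c(0, 0.9)) for (n in c(1, 1.4)) {
    quad <- make_quadrature(8L, n)
    mrs <- vapply(c(0.01, 0.05, 0.2, 1, 5),
                  function(mua) forward_reflectance(
                    slab_properties(mua, 16, g, n), quad), numeric(1))
    expect_true(all(diff(mrs) < 0))
  }
})

test_that("quadrature refinement converges", {
  # order 8 agrees with order 16 at the documented 2.5e-3 level, and
  # order 16 with order 32 at 5e-4: the scheme converges with order
  cases <- expand.grid(mua = c(0.1, 1), g = c(0, 0.9), n = c(1, 1.4))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    p <- slab_properties(cs$mua, 16, cs$g, cs$n)
    m8 <- forward_reflectance(p, make_quadrature(8L, cs$n))
    m16 <- forward_reflectance(p, make_quadrature(16L, cs$n))
    m32 <- forward_reflectance(p, make_quadrature(32L, cs$n))
    expect_lt(abs(m8 - m16), 2.5e-3)
    expect_lt(abs(m16 - m32), 5e-4)
  }
})

test_that("forward agrees with the Monte-Carlo oracle (spot check)", {
  # full 3x3x2 grid at 1e6 photons runs in the acceptance suite; here two
  # representative cases at 1e5 photons
  for (n in c(1, 1.4)) {
    p <- slab_properties(0.1, 16, 0.9, n)
    ad <- forward_reflectance(p, make_quadrature(16L, n))
    mc <- mc_photon_oracle(p, 1e5, seed = 42)
    expect_lt(abs(ad - mc$estimate), 3 * mc$se + 5e-4)
  }
})

test_that("invert_absorption recovers the forward model", {
  quad <- q8_14
  mr0 <- forward_reflectance(slab_properties(0, 16, 0.9, 1.4), quad)
  expect_equal(invert_absorption(mr0, 16, 0.9, 1.4, quad), 0)

  for (mua0 in c(0.005, 0.05, 0.5, 5)) {
    mr <- forward_reflectance(slab_properties(mua0, 16, 0.9, 1.4), quad)
    mua <- invert_absorption(mr, 16, 0.9, 1.4, quad)
    expect_lt(abs(mua - mua0) / mua0, 1e-4)
  }

  expect_error(invert_absorption(1.2, 16, 0.9, 1.4, quad),
               class = "otos_gamut_error")
  expect_error(invert_absorption(fresnel_specular(1.4) / 2, 16, 0.9, 1.4, quad),
               class = "otos_gamut_error")
})

test_that("invert_spectrum flags bad channels and recovers good ones", {
  model <- scattering_model()
  lam <- seq(620, 700, by = 8)
  musp <- reduced_scattering(lam, model)
  g <- anisotropy(lam, model)
  mus <- scattering_coefficient(musp, g)
  mua_true <- 0.02 + 0.0002 * (700 - lam)
  quad <- q8_14
  mr <- vapply(seq_along(lam), function(i) forward_reflectance(
    slab_properties(mua_true[i], mus[i], g[i], 1.4), quad), numeric(1))

  inv <- invert_spectrum(reflectance_spectrum(lam, mr), model, 1.4, quad)
  expect_false(any(inv$flagged))
  expect_lt(max(abs(inv$mua - mua_true) / mua_true), 1e-3)

  # one corrupted channel is isolated, the rest still recovered
  mr_bad <- replace(mr, 3, 1.5)
  inv2 <- invert_spectrum(reflectance_spectrum(lam, mr_bad), model, 1.4, quad)
  expect_true(inv2$flagged[3])
  expect_true(is.na(inv2$mua[3]))
  expect_lt(max(abs(inv2$mua[-3] - mua_true[-3]) / mua_true[-3]), 1e-3)

  # mostly-garbage spectrum is a calibration failure
  expect_error(
    invert_spectrum(reflectance_spectrum(lam, rep(1.5, length(lam))),
                    model, 1.4, quad),
    class = "otos_calibration_error")

  # constant MR varies recovered mua only through mus(lambda), g(lambda)
  inv3 <- invert_spectrum(reflectance_spectrum(lam, rep(mr[5], length(lam))),
                          model, 1.4, quad)
  expect_gt(diff(range(inv3$mua)), 0)
})

test_that("slab_properties rejects degenerate media", {
  expect_error(slab_properties(0, 0, 0, 1), class = "otos_domain_error")
  expect_error(slab_properties(1, 1, 1, 1), class = "otos_domain_error")
  expect_error(slab_properties(1, 1, 0, 0.9), class = "otos_domain_error")
  expect_error(slab_properties(1, 1, 0, 1.4, regime = "finite"),
               class = "otos_domain_error")
})
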