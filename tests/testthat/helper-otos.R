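# Shared fixtures built in code (the deliverable carries no binary data).

# quadratures reused across tests
q8_1 <- make_quadrature(8L, 1)
q8_14 <- make_quadrature(8L, 1.4)
q16_14 <- make_quadrature(16L, 1.4)

# one extinction table load per run
ext_tab <- extinction_table()

make_const_spectrum <- function(value, role = "other",
                                grid = seq(500, 509, by = 1)) {
  intensity_spectrum(grid, rep(value, length(grid)), role = role)
}

# direct numerical azimuthal average of the Henyey-Greenstein kernel,
# normalized so the isotropic case gives 1 (oracle for hg_redistribution)
hg_direct <- function(nu1, nu2, g) {
  f <- function(phi) {
    ct <- nu1 * nu2 + sqrt(1 - nu1^2) * sqrt(1 - nu2^2) * cos(phi)
    (1 - g^2) / (1 + g^2 - 2 * g * ct)^1.5 / (4 * pi)
  }
  2 * stats::integrate(f, 0, 2 * pi, rel.tol = 1e-12)$value
}

# fast settings for pipeline tests on the default 0.25 nm fixture grid
fast_config <- function(...) otos_config(...)
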