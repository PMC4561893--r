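test_that("silver model agrees with the embedded tabulation at 532 nm", {
  eps_fit <- permittivity(silver_drude_lorentz(), 532)
  eps_tab <- silver_permittivity_table(532)
  expect_lt(Re(eps_fit), -1)
  expect_gt(Im(eps_fit), 0)
  expect_lt(Im(eps_fit), 3)
  expect_lt(abs(Re(eps_fit) / Re(eps_tab) - 1), 0.05)
  expect_lt(abs(Im(eps_fit) / Im(eps_tab) - 1), 0.05)
})

test_that("silver model is passive and metallic across the optical window", {
  lam <- seq(300, 1100, length.out = 100)
  eps <- permittivity(silver_drude_lorentz(), lam)
  expect_true(all(Im(eps) >= 0))
  vis <- lam >= 400 & lam <= 900
  expect_true(all(Re(eps[vis]) < 0))
})

test_that("constant media and the pure-Drude limit behave", {
  expect_equal(permittivity(vacuum_medium(), 700), 1 + 0i)
  expect_equal(permittivity(water_medium(), 500), 1.77 + 0i)
  drude <- dielectric_model(eps_inf = 1, plasma_frequency = 1.4e16,
                            drude_damping = 1e14, validity_nm = c(0, Inf))
  re_long <- Re(permittivity(drude, c(1e4, 1e5, 1e6)))
  expect_true(all(diff(re_long) < 0))   # Re -> -Inf as wavelength grows
  expect_lt(re_long[1], -1e3)
})

test_that("permittivity validates and warns on its inputs", {
  expect_error(permittivity(silver_drude_lorentz(), -5), "wavelength")
  expect_error(permittivity(silver_drude_lorentz(), 0), "wavelength")
  expect_warning(permittivity(silver_drude_lorentz(), 200), "validity")
})

test_that("fresnel coefficients satisfy the classical limits", {
  eps_ag <- permittivity(silver_drude_lorentz(), 532)
  # normal incidence: both polarizations have the same magnitude
  expect_equal(abs(fresnel_reflection(0, "TM", 1, eps_ag)),
               abs(fresnel_reflection(0, "TE", 1, eps_ag)), tolerance = 1e-12)
  # perfect-conductor limit
  for (pol in c("TM", "TE")) {
    expect_equal(abs(fresnel_reflection(35, pol, 1, -1e9 + 0i)), 1,
                 tolerance = 1e-4)
  }
  # no interface
  expect_equal(fresnel_reflection(40, "TM", 1, 1 + 0i), 0 + 0i)
  expect_error(fresnel_reflection(90, "TM", 1, eps_ag), "theta")
  expect_error(fresnel_reflection(-1, "TE", 1, eps_ag), "theta")
})

test_that("fresnel energy bound holds over all incidence angles", {
  eps_ag <- permittivity(silver_drude_lorentz(), 532)
  for (th in seq(0, 89, by = 1)) {
    expect_lte(abs(fresnel_reflection(th, "TM", 1, eps_ag))^2, 1 + 1e-12)
    expect_lte(abs(fresnel_reflection(th, "TE", 1, eps_ag))^2, 1 + 1e-12)
  }
})

test_that("Mie polarizability converges to Clausius-Mossotti for small spheres", {
  eps_ag <- permittivity(silver_drude_lorentz(), 532)
  rel <- vapply(c(16, 8, 4, 2, 1), function(a) {
    am <- mie_dipole_polarizability(a, 532, eps_ag)
    aq <- quasistatic_polarizability(a, eps_ag)
    abs(am - aq) / abs(aq)
  }, numeric(1))
  expect_lt(rel[5], 0.01)               # 1 nm sphere within 1%
  expect_true(all(diff(rel) < 0))       # error shrinks monotonically
})

test_that("Mie polarizability matches an independent series evaluation", {
  eps_ag <- permittivity(silver_drude_lorentz(), 532)
  for (a in c(5, 25)) {
    a1_pkg <- mie_a1(a, 532, eps_ag)
    a1_orc <- mie_a1_oracle(a, 532, eps_ag)
    expect_lt(abs(a1_pkg - a1_orc) / abs(a1_orc), 1e-8)
  }
})

test_that("Mie polarizability edge cases and radiative-reaction bound", {
  eps_ag <- permittivity(silver_drude_lorentz(), 532)
  # index matching: essentially no response
  a_match <- mie_dipole_polarizability(20, 532, 1 + 0i, 1)
  a_ref <- mie_dipole_polarizability(20, 532, eps_ag, 1)
  expect_lt(abs(a_match) / abs(a_ref), 1e-6)
  expect_error(mie_dipole_polarizability(0, 532, eps_ag), "radius")
  expect_error(mie_dipole_polarizability(-3, 532, eps_ag), "radius")
  expect_warning(mie_dipole_polarizability(200, 532, eps_ag), "size parameter")
  # optical theorem: Im(1/alpha) bounded by the radiative-reaction term
  k <- 2 * pi / 532
  eps0 <- 8.8541878128e-21
  for (a in c(5, 15, 25)) {
    alpha <- mie_dipole_polarizability(a, 532, eps_ag)
    expect_lte(Im(1 / alpha), -k^3 / (6 * pi * eps0) + 1e-10)
  }
})

test_that("quasi-static polarizability has the closed-form behavior", {
  expect_equal(abs(quasistatic_polarizability(10, 1 + 0i, 1)), 0)
  # a^3 scaling
  r1 <- quasistatic_polarizability(10, 2.25 + 0i)
  r2 <- quasistatic_polarizability(20, 2.25 + 0i)
  expect_equal(r2 / r1, 8 + 0i, tolerance = 1e-12)
  # Frohlich resonance: |alpha| grows without bound approaching eps = -2
  seq_eps <- c(-2 + 0.1i, -2 + 0.01i, -2 + 0.001i)
  mags <- vapply(seq_eps, function(e) abs(quasistatic_polarizability(10, e)),
                 numeric(1))
  expect_true(all(diff(mags) > 0))
  expect_error(quasistatic_polarizability(10, -2 + 0i), "resonance")
  expect_error(quasistatic_polarizability(0, 2 + 0i), "radius")
})

test_that("material definitions round-trip through the config format", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_material(silver_drude_lorentz(), path)
  back <- read_material(path)
  lam <- c(400, 532, 800)
  expect_equal(permittivity(back, lam),
               permittivity(silver_drude_lorentz(), lam), tolerance = 1e-12)
  expect_equal(back$name, "silver (Drude-Lorentz fit)")
})
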