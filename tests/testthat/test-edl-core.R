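# Constitutive functions of the double-layer model, checked against values
# frozen from a 40-digit arbitrary-precision evaluation of the same
# closed-form expressions (mpmath), plus their structural properties.

# columns: x, L(x), F(x)
lf_oracle <- rbind(
  c(1e-8, 3.33333333333333331e-9, 3.33333333333333337e-9),
  c(1e-6, 3.33333333333311111e-7, 3.33333333333366667e-7),
  c(1e-4, 3.33333333111111111e-5, 3.33333333666666667e-5),
  c(1e-2, 0.00333331111132274921, 0.00333336666678571451),
  c(0.5,  0.163953413738652849,  0.170870708437772124),
  c(1,    0.313035285499331304,  0.367879441171442322),
  c(2,    0.537314720727548096,  0.974382743580061038),
  c(5,    0.800090803982019376,  11.8738612818460185),
  c(10,   0.900000004122307253,  991.19096326329838),
  c(50,   0.98,                  5.08101141801533101e19)
)

test_that("Langevin function matches the high-precision oracle across 10 decades", {
  expect_equal(langevin_L(lf_oracle[, 1]), lf_oracle[, 2], tolerance = 1e-10)
  expect_identical(langevin_L(0), 0)
})

test_that("Langevin function is odd and saturates below 1", {
  x <- c(1e-7, 1e-3, 0.3, 2, 7, 30)
  expect_equal(langevin_L(-x), -langevin_L(x))
  expect_true(all(abs(langevin_L(x)) < 1))
})

test_that("dipole ordering factor matches its oracle and known identities", {
  expect_equal(dipole_factor_F(lf_oracle[, 1]), lf_oracle[, 3],
               tolerance = 1e-10)
  # L(1) sinh(1) = cosh(1) - sinh(1) = exp(-1)
  expect_equal(dipole_factor_F(1), exp(-1), tolerance = 1e-14)
  expect_identical(dipole_factor_F(0), 0)
})

test_that("dipole ordering factor is x/3 at small argument, increasing, and finite past the overflow guard", {
  expect_equal(dipole_factor_F(1e-6), 1e-6 / 3, tolerance = 1e-6)
  x <- sort(c(10^seq(-6, 2, length.out = 40), 550, 650, 700))
  expect_true(all(diff(dipole_factor_F(x)) > 0))
  expect_true(is.finite(dipole_factor_F(650)))  # sinh(650) alone overflows
})

test_that("steric denominator equals the lattice density at zero field and potential", {
  m <- std_model()
  expect_equal(h_denominator(m, 0, 0), m$ns)
  # any orientation ordering of water increases it: sinh(u)/u > 1
  expect_true(h_denominator(m, 0, 1e7) > m$ns)
  # frozen direct evaluation at phi = 25.7 mV, E = 1e8 V/m
  expect_equal(h_denominator(m, 0.0257, 1e8), 3.4239538196458589e28,
               tolerance = 1e-12)
})

test_that("relative permittivity reproduces frozen saturation values and limits", {
  m <- std_model()
  expect_equal(relative_permittivity(m, 0, 1e8), 77.613541762221408,
               tolerance = 1e-10)
  expect_equal(relative_permittivity(m, 0, 1e9), 45.632638109806136,
               tolerance = 1e-10)
  # no dipoles: vacuum-relative baseline whatever the state
  m0 <- electrolyte_model(0.15, dipole_debye = 0)
  expect_equal(relative_permittivity(m0, c(0, 0.1), c(0, 1e9)), c(1, 1))
  # even in phi
  expect_equal(relative_permittivity(m, 0.05, 1e8),
               relative_permittivity(m, -0.05, 1e8))
})

test_that("relative permittivity is continuous at E -> 0 and non-increasing in E", {
  m <- std_model()
  # the analytic zero-field limit agrees with the formula at E = 1 V/m
  expect_equal(relative_permittivity(m, 0, 1), bulk_permittivity(m),
               tolerance = 1e-6)
  # continuity across the series switch-point
  u_switch_E <- 1e-2 / (m$p0 * m$beta)
  expect_equal(relative_permittivity(m, 0, u_switch_E * (1 - 1e-9)),
               relative_permittivity(m, 0, u_switch_E * (1 + 1e-9)),
               tolerance = 1e-7)
  E <- 10^seq(0, 9.5, length.out = 60)
  eps <- relative_permittivity(m, 0.02, E)
  expect_true(all(diff(eps) <= 1e-12))  # non-increasing to round-off
  expect_true(all(eps >= 1))
})

test_that("free charge density is odd in phi, opposes it, and saturates sterically", {
  m <- std_model()
  phi <- c(0.001, 0.01, 0.1, 0.5)
  expect_equal(free_charge_density(m, -phi, 0),
               -free_charge_density(m, phi, 0))
  expect_identical(free_charge_density(m, 0, 0), 0)
  expect_true(all(free_charge_density(m, phi, 0) < 0))
  # steric bound: magnitude below e0 * n_s even at 1 V
  e0 <- 1.602176634e-19
  expect_lt(abs(free_charge_density(m, 1, 0)), e0 * m$ns)
  # frozen direct evaluation at e0 phi beta = 1
  expect_equal(free_charge_density(m, 0.025679653121192629, 0),
               -33916977.455805824, tolerance = 1e-12)
})

test_that("bulk permittivity closed form reproduces frozen values and scales linearly in water content", {
  expect_equal(bulk_permittivity(std_model()), 78.370149066691287,
               tolerance = 1e-12)
  expect_equal(bulk_permittivity(electrolyte_model(0.15, water_mol_l = 27.5)),
               39.685074533345644, tolerance = 1e-12)
  expect_equal(bulk_permittivity(electrolyte_model(0.15, dipole_debye = 0)), 1)
})

test_that("Debye length matches the closed form and its scaling laws", {
  m <- std_model()
  expect_equal(m_to_nm(debye_length(m, 78.5)), 0.78525822571775334,
               tolerance = 1e-12)
  m4 <- electrolyte_model(0.6) # 4x the salt halves the screening length
  expect_equal(debye_length(m, 78.5) / debye_length(m4, 78.5), 2,
               tolerance = 1e-12)
  expect_equal(debye_length(m, 78.5) / debye_length(m, 1), sqrt(78.5),
               tolerance = 1e-12)
  expect_warning(out <- debye_length(electrolyte_model(0), 78.5), "no salt")
  expect_identical(out, Inf)
})

test_that("unit converters round-trip to machine precision", {
  x <- c(0.001, 0.15, 55)
  expect_equal(per_m3_to_mol_l(mol_l_to_per_m3(x)), x, tolerance = 1e-15)
  expect_equal(Cm_to_debye(debye_to_Cm(x)), x, tolerance = 1e-15)
  expect_equal(m_to_nm(nm_to_m(x)), x, tolerance = 1e-15)
})

test_that("electrolyte model derives the lattice density and rejects bad input", {
  m <- electrolyte_model(0.2, 50, 3, 310)
  expect_identical(m$ns, m$n0w + 2 * m$n0)
  expect_error(electrolyte_model(-0.1), "salt_mol_l")
  expect_error(electrolyte_model(0.1, water_mol_l = 0), "water_mol_l")
  expect_error(electrolyte_model(0.1, temperature_K = -5), "temperature_K")
})
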