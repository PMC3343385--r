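# Orientation-dependent bending energetics: closed forms, the composition
# identity, the analytic orientation optimum against a brute-force grid
# search, and the rigid-rod tube relation.

test_that("curvature seen by a rotated rod interpolates the principal curvatures", {
  cyl <- membrane_patch(0.1, 0)
  expect_equal(curvature_seen(cyl, 0), 0.1)
  expect_equal(curvature_seen(cyl, pi / 2), 0, tolerance = 1e-15)
  sph <- membrane_patch(0.05, 0.05)
  expect_equal(curvature_seen(sph, seq(0, pi, by = 0.3)),
               rep(0.05, 11))
})

test_that("curvature seen stays within [H - D, H + D] on random patches", {
  set.seed(42)
  for (i in 1:200) {
    p <- membrane_patch(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3))
    C <- curvature_seen(p, runif(5, 0, 2 * pi))
    expect_true(all(C >= p$H - p$D - 1e-12 & C <= p$H + p$D + 1e-12))
  }
})

test_that("flexible-rod energy is a quadratic penalty around the intrinsic curvature", {
  p <- rod_protein(c_p = 0.05, k_p = 10, l0 = 20)
  expect_equal(protein_energy(p, 0.05), 0)
  # (10 * 20 / 2) * 0.05^2 = 0.25 kT
  expect_equal(protein_energy(p, 0.1), 0.25)
  expect_equal(protein_energy(p, 0.15), 4 * protein_energy(p, 0.1))
  expect_true(all(protein_energy(p, seq(-1, 1, 0.1)) >= 0))
})

test_that("orientation-resolved energy is exactly the composition of curvature and bending", {
  set.seed(7)
  for (i in 1:300) {
    prot <- rod_protein(c_p = runif(1, -0.2, 0.2), k_p = runif(1, 0.1, 50),
                        l0 = runif(1, 5, 40))
    patch <- membrane_patch(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3))
    om <- runif(1, 0, 2 * pi)
    expect_equal(protein_energy_orient(prot, patch, om),
                 protein_energy(prot, curvature_seen(patch, om)),
                 tolerance = 1e-12)
  }
  # isotropic patch: no orientation dependence
  prot <- rod_protein(0.05)
  sph <- membrane_patch(0.1, 0.1)
  expect_equal(diff(range(protein_energy_orient(prot, sph,
                                                seq(0, pi, 0.1)))), 0)
})

test_that("analytic optimal orientation matches a dense grid search", {
  set.seed(11)
  grid <- seq(0, pi / 2, length.out = 10001)
  for (i in 1:300) {
    prot <- rod_protein(c_p = runif(1, -0.25, 0.25), k_p = 10, l0 = 20)
    patch <- membrane_patch(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3))
    opt <- optimal_orientation(prot, patch)
    e_grid <- min(protein_energy_orient(prot, patch, grid))
    tol <- 1e-10 * prot$k_p * prot$l0 * max(patch$D^2, 1e-6)
    expect_lt(opt$E_min_kT - e_grid, tol + 1e-12)
    expect_gte(opt$E_min_kT, 0)
    expect_true(opt$omega_opt >= 0 && opt$omega_opt <= pi / 2)
  }
})

test_that("orientation optimum hits the documented closed-form cases", {
  # rod can match its curvature on the cylinder: cos(2 w*) = (cp - H)/D
  opt <- optimal_orientation(rod_protein(0.05), membrane_patch(0.1, 0))
  expect_equal(opt$omega_opt, pi / 4)
  expect_equal(opt$E_min_kT, 0, tolerance = 1e-20)
  # curvature demand beyond reach: boundary minima
  expect_equal(optimal_orientation(rod_protein(0.3),
                                   membrane_patch(0.1, 0))$omega_opt, 0)
  expect_equal(optimal_orientation(rod_protein(-0.1),
                                   membrane_patch(0.1, 0))$omega_opt, pi / 2)
  # isotropic convention
  sph <- membrane_patch(0.1, 0.1)
  opt <- optimal_orientation(rod_protein(0.05), sph)
  expect_equal(opt$omega_opt, 0)
  expect_equal(opt$E_min_kT, protein_energy(rod_protein(0.05), 0.1))
})

test_that("rigid-rod tube curvature inverts C_p = C1 cos^2(omega)", {
  expect_equal(rigid_tube_c1(0.05, 0), 0.05)
  expect_equal(rigid_tube_c1(0.05, pi / 4), 0.1)
  expect_equal(rigid_tube_c1(0.05, pi / 3), 0.2)
  set.seed(3)
  om <- runif(50, 0, pi / 2 - 0.01)
  c1 <- rigid_tube_c1(0.07, om)
  expect_equal(c1 * cos(om)^2, rep(0.07, 50))
  expect_true(all(c1 >= 0.07))
  expect_error(rigid_tube_c1(0.05, pi / 2), "tube axis")
})

test_that("bilayer energies of spheres and cylinders match their closed forms", {
  mat <- membrane_material(k_c = 20, k_g = -16, m0 = 1.67, d_eff = 1, l2 = 1)
  sph <- membrane_energy(parametric_shape("sphere", radius_nm = 37), mat)
  expect_equal(sph$energy_kT[sph$term == "bending"], 8 * pi * 20)
  expect_equal(sph$energy_kT[sph$term == "gaussian"], 4 * pi * -16)
  # sphere is isotropic: deviatoric term is the D = 0 baseline
  expect_equal(sph$energy_kT[sph$term == "deviatoric"],
               -2 * 1.67 * log(2) * 4 * pi * 37^2)
  # bending of a sphere is radius-independent
  sph2 <- membrane_energy(parametric_shape("sphere", radius_nm = 500), mat)
  expect_equal(sph2$energy_kT[sph2$term == "bending"], 8 * pi * 20)

  cyl <- membrane_energy(parametric_shape("cylinder", 10, length_nm = 50), mat)
  expect_equal(cyl$energy_kT[cyl$term == "bending"], pi * 20 * 50 / 10)
  expect_equal(cyl$energy_kT[cyl$term == "gaussian"], 0)
  expect_equal(cyl$energy_kT[cyl$term == "deviatoric"],
               -2 * 1.67 * log(2 * cosh(1 / 20)) * 2 * pi * 10 * 50)
  expect_equal(cyl$energy_kT[cyl$term == "total"],
               sum(cyl$energy_kT[cyl$term != "total"]))
  # joule column is the kT column scaled by thermal energy
  expect_equal(cyl$energy_J, cyl$energy_kT * thermal_energy(298))
})

test_that("without lipid anisotropy the deviatoric term is the pure mixing baseline", {
  mat <- membrane_material(d_eff = 0)
  for (shape in list(parametric_shape("cylinder", 5, 30),
                     parametric_shape("sphere", 12))) {
    en <- membrane_energy(shape, mat)
    expect_equal(en$energy_kT[en$term == "deviatoric"],
                 -2 * mat$m0 * log(2) * shape$area)
  }
})

test_that("constructors validate their physical preconditions", {
  expect_error(rod_protein(0.05, k_p = -1), "k_p")
  expect_error(rod_protein(0.05, l0 = 0), "l0")
  expect_error(membrane_material(k_c = 0), "k_c")
  expect_error(membrane_material(l2 = 0), "l2")
  expect_error(parametric_shape("cylinder", 5), "length_nm")
  expect_error(parametric_shape("sphere", -2), "radius_nm")
  # omega is stored modulo pi
  expect_equal(rod_protein(0.05, omega = pi + 0.3)$omega, 0.3)
})
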