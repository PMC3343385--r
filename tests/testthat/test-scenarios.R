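# Scenario configuration handling and end-to-end runs.

test_that("reference fixtures carry the standard parameter set with assumed flags", {
  fx <- reference_fixtures()
  expect_named(fx, c("planar_wall", "arc_scan"))
  expect_equal(fx$planar_wall$geometry$sigma, 0.2)
  expect_equal(fx$planar_wall$electrolyte$salt_mol_l, 0.15)
  expect_equal(fx$planar_wall$electrolyte$water_mol_l, 55)
  expect_equal(fx$planar_wall$electrolyte$dipole_debye, 4.79)
  expect_equal(fx$arc_scan$geometry$eps_ord, 54.5)
  expect_equal(fx$arc_scan$geometry$eps_b, 78.5)
  expect_equal(fx$arc_scan$geometry$layer_nm, 0.32)
  expect_true(is.unsorted(rev(fx$arc_scan$geometry$radii_nm)))
  # modelling defaults (not part of the reference description) are flagged
  expect_true("electrolyte.temperature_K" %in% fx$planar_wall$assumed)
  expect_true(all(c("geometry.arc_length_nm", "geometry.point_distance_nm")
                  %in% fx$arc_scan$assumed))
})

test_that("YAML round-trip of a config is idempotent", {
  fx <- reference_fixtures()$arc_scan
  p1 <- withr::local_tempfile(fileext = ".yaml")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(fx, p1)
  c1 <- read_scenario_config(p1)
  write_scenario_config(c1, p2)
  c2 <- read_scenario_config(p2)
  expect_identical(unclass(c1), unclass(c2))
  expect_equal(c1$geometry$radii_nm, fx$geometry$radii_nm)
})

test_that("schema violations name the offending field", {
  bad <- reference_fixtures()$planar_wall
  bad$electrolyte$salt_mol_l <- -0.1
  expect_error(validate_scenario_config(bad), "electrolyte.salt_mol_l",
               class = "barmem_schema_error")
  bad2 <- reference_fixtures()$arc_scan
  bad2$geometry$radii_nm <- c(8, 4)
  expect_error(validate_scenario_config(bad2), "geometry.radii_nm")
  bad3 <- reference_fixtures()$planar_wall
  bad3$geometry$sigma <- 5
  expect_error(validate_scenario_config(bad3), "geometry.sigma")
  bad4 <- reference_fixtures()$planar_wall
  bad4$geometry$kind <- "spherical"
  expect_error(validate_scenario_config(bad4), "geometry.kind")
})

test_that("a planar scenario run writes outputs, a complete manifest, and is byte-reproducible", {
  cfg <- reference_fixtures()$planar_wall
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res <- suppressMessages(run_scenario(cfg, d1))
  expect_true(file.exists(res$outputs$planar_profile))
  expect_true(file.exists(res$outputs$manifest))
  # permittivity is depressed at the surface and recovers into the bulk
  prof <- utils::read.csv(res$outputs$planar_profile)
  expect_lt(prof$eps_r[1], 60)
  expect_true(all(diff(prof$eps_r) >= -1e-9))
  # manifest lists every consumed parameter and the assumed flags
  man <- jsonlite::read_json(res$outputs$manifest)
  for (key in c("electrolyte.salt_mol_l", "electrolyte.dipole_debye",
                "electrolyte.temperature_K", "geometry.sigma",
                "run.outer_tol", "run.newton_tol"))
    expect_true(key %in% names(man$parameters))
  expect_true("electrolyte.temperature_K" %in% unlist(man$assumed))
  # determinism: a second run reproduces the CSV byte for byte
  res2 <- suppressMessages(run_scenario(cfg, d2))
  expect_identical(readLines(res$outputs$planar_profile),
                   readLines(res2$outputs$planar_profile))
})

test_that("a bending block adds a tube-equilibrium stage", {
  cfg <- reference_fixtures()$planar_wall
  cfg$bending <- list(protein = list(c_p = 0.08, k_p = 100, l0 = 20),
                      coverage = 1)
  d <- withr::local_tempdir()
  res <- suppressMessages(run_scenario(cfg, d))
  expect_true(file.exists(res$outputs$tube_energy_scan))
  man <- jsonlite::read_json(res$outputs$manifest)
  expect_equal(man$tube_equilibrium$r_opt_nm, res$results$tube$r_opt_nm,
               tolerance = 1e-12)
})
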