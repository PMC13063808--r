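test_that("titration CSV round-trips, sorts and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pH,zeta_mV,zeta_sd_mV",
               "7.5,-14.0,1.0", "3.0,4.5,2.0", "10.0,-90.0,3.0"), path)
  cur <- read_titration_csv(path)
  expect_s3_class(cur, "titration_curve")
  expect_equal(nrow(cur), 3)
  expect_equal(cur$pH, c(3, 7.5, 10))          # sorted
  expect_equal(cur$zeta, c(4.5, -14, -90))
  out <- withr::local_tempfile(fileext = ".csv")
  write_titration_csv(cur, out)
  expect_equal(read_titration_csv(out), cur)

  # out-of-range pH rejected with the offending line
  writeLines(c("pH,zeta_mV", "7,-10", "15,-2"), path)
  expect_error(read_titration_csv(path), "outside \\[0, 14\\]")
  # malformed rows rejected
  writeLines(c("pH,zeta_mV", "7,-10", "8,abc"), path)
  expect_error(read_titration_csv(path), "malformed")
  # duplicates averaged with a warning
  writeLines(c("pH,zeta_mV", "7,-10", "7,-12", "8,-20"), path)
  expect_warning(cur2 <- read_titration_csv(path), "duplicate")
  expect_equal(cur2$zeta, c(-11, -20))
  expect_error(read_titration_csv("no/such/file.csv"), "no such file")
})

test_that("QCM CSV parsing matches the export dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,f1_Hz,f3_Hz,d1,d3",
               "0,0,0,0,0", "1,-5,-15.6,0.1,0.3", "2,-5.1,-15.5,0.1,0.3"),
             path)
  tr <- read_qcm_csv(path)
  expect_s3_class(tr, "qcm_trace")
  expect_equal(tr$overtones, c(1L, 3L))
  expect_equal(tr$delta_f$f3[2], -15.6)
  expect_equal(tr$delta_D$d1[2], 0.1)
  writeLines(c("time_s,x", "0,1"), path)
  expect_error(read_qcm_csv(path), "frequency")
})

test_that("profile export writes nm / mV columns", {
  prof <- pb_solve_fixed_charge(-0.002, salt_composition(0.01),
                                fast_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  df <- utils::read.csv(path)
  expect_named(df, c("x_nm", "psi_mV"))
  expect_equal(df$psi_mV[1], 1e3 * prof$psi0, tolerance = 1e-6)
})

test_that("YAML run configs parse into package objects", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "buffer:",
    "  name: Tris",
    "  total_mM: 10",
    "  pK: 8.07",
    "surface:",
    "  label: MSN",
    "  sites:",
    "    - {kind: acid_silanol, pK: 7.6, density_per_nm2: 0.0769}",
    "    - {kind: base_silanol, pK: 2.2, density_per_nm2: 0.0769}",
    "solver:",
    "  n_grid: 400",
    "fit:",
    "  free_parameters: [pK_acid, N_acid]",
    "  seed: 7"), path)
  rc <- read_run_config(path)
  expect_equal(rc$buffer_spec$total, 0.010)
  expect_s3_class(rc$surface, "surface_model")
  expect_equal(rc$surface$sites$acid_silanol$pK, 7.6)
  expect_equal(rc$config$n_grid, 400L)
  expect_equal(rc$fit$seed, 7)
  expect_match(rc$config_hash, "^[0-9a-f]{8}$")
  # hash is stable across re-reads
  expect_identical(rc$config_hash, read_run_config(path)$config_hash)

  writeLines(c("buffer:", "  total_mM: 10", "bogus: 1"), path)
  expect_error(read_run_config(path), "unknown config keys")
})

test_that("fit results serialize to reproducible JSON", {
  cfg <- fast_config()
  scn <- titration_scenario(msn_model(), pH_points = seq(4, 9, by = 1),
                            noise_sd = 1, seed = 2, config = cfg)
  g <- generate_titration(scn)
  fit <- fit_charge_regulation(g$curve, msn_model(), "N_acid",
                               config = cfg, n_starts = 2, seed = 6)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, p1, config_hash = "deadbeef")
  fit2 <- fit_charge_regulation(g$curve, msn_model(), "N_acid",
                                config = cfg, n_starts = 2, seed = 6)
  write_fit_json(fit2, p2, config_hash = "deadbeef")
  expect_identical(readLines(p1), readLines(p2))
  obj <- jsonlite::read_json(p1)
  expect_equal(obj$seed, 6)
  expect_true(is.numeric(obj$parameters$N_acid))
})
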