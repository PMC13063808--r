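test_that("zeta is the interpolated potential at the slipping plane", {
  # synthetic Debye-Hueckel profile: zeta = psi0 * exp(-slip/lD)
  lD <- 3.04e-9
  x <- seq(0, 45e-9, length.out = 2000)
  prof <- structure(list(x = x, psi = -0.020 * exp(-x / lD), psi0 = -0.020,
                         sigma = -0.001), class = "potential_profile")
  expect_equal(zeta_from_profile(prof, 0.7e-9),
               -20 * exp(-0.7 / 3.04), tolerance = 1e-4)
  expect_equal(zeta_from_profile(prof, 0.7e-9), -15.9, tolerance = 1e-2)
  # slip at zero returns psi0 in mV exactly
  expect_equal(zeta_from_profile(prof, 0), -20)
  expect_error(zeta_from_profile(prof, 1), "outside")
  # zero profile -> zero zeta
  prof0 <- structure(list(x = x, psi = rep(0, length(x)), psi0 = 0,
                          sigma = 0), class = "potential_profile")
  expect_equal(zeta_from_profile(prof0, 0.7e-9), 0)
})

test_that("predicted titrations have the expected sign structure", {
  cfg <- fast_config()
  buf <- tris_buffer()
  pHs <- seq(3, 10, by = 1)
  # all-zero site model: zeta identically zero
  z0 <- predict_titration(surface_model(surface_site("amine", 9, 0)),
                          buf, pHs, cfg)
  expect_true(all(z0$zeta == 0))
  # acid-only surface: never positive, strictly negative above pK - 2
  za <- predict_titration(surface_model(surface_site("acid_silanol", 7, 0.1)),
                          buf, pHs, cfg)
  expect_true(all(za$zeta <= 0))
  expect_true(all(za$zeta[za$pH > 5] < 0))
  # amphoteric bare-silica model: one sign change, + at 3, - at 10
  zm <- predict_titration(msn_model(), buf, pHs, cfg)
  expect_gt(zm$zeta[1], 0)
  expect_lt(zm$zeta[length(pHs)], 0)
  expect_equal(sum(diff(sign(zm$zeta)) != 0), 1)
  # monotone decreasing over the titration range
  expect_true(all(diff(zm$zeta) < 0))
})

test_that("isoelectric point of a symmetric amphoteric surface is exact", {
  m <- surface_model(surface_site("acid_silanol", 4, 1),
                     surface_site("base_silanol", 6, 1))
  iep <- isoelectric_point(m, tris_buffer(), fast_config())
  expect_lt(abs(iep - 5.00), 0.011)
})

test_that("acid-only surface reports no IEP in range", {
  m <- surface_model(surface_site("acid_silanol", 7, 0.1))
  iep <- isoelectric_point(m, tris_buffer(), fast_config(), c(3, 10))
  expect_true(is.na(iep))
  expect_equal(attr(iep, "reason"), "no sign change")
})

test_that("adding amine density raises the IEP", {
  cfg <- fast_config()
  buf <- tris_buffer()
  base <- isoelectric_point(msn_model(), buf, cfg)
  ieps <- vapply(c(0.05, 0.1, 0.2), function(NN) {
    m <- surface_model(surface_site("acid_silanol", 7.6, 0.0769),
                       surface_site("base_silanol", 2.2, 0.0769),
                       surface_site("amine", 7.05, NN))
    isoelectric_point(m, buf, cfg, c(3, 12))
  }, numeric(1))
  expect_true(all(diff(c(base, ieps)) > 0))
})

test_that("noiseless fits recover the generating parameters", {
  cfg <- fast_config()
  scn <- titration_scenario(msn_nh2_model(), tris_buffer(),
                            pH_points = seq(3, 10, length.out = 16),
                            noise_sd = 0, seed = 5, config = cfg)
  g <- generate_titration(scn)
  fit <- fit_charge_regulation(g$curve, msn_nh2_model(),
                               free_parameters = c("pK_amine", "N_amine",
                                                   "N_acid"),
                               config = cfg, n_starts = 5, seed = 3)
  expect_true(fit$converged)
  expect_lt(abs(fit$parameters["pK_amine"] - 7.05), 1e-3)
  expect_lt(abs(fit$parameters["N_amine"] / 0.206 - 1), 1e-3)
  expect_lt(abs(fit$parameters["N_acid"] / 0.0384 - 1), 1e-3)
  # residual at the optimum cannot exceed the generator's noise-free zero
  expect_lt(fit$residual_norm, 1e-8)
})

test_that("fits are deterministic given a seed and invariant to data order", {
  cfg <- fast_config()
  scn <- titration_scenario(msn_nh2_model(), tris_buffer(),
                            pH_points = seq(4, 9.5, length.out = 8),
                            noise_sd = 1.5, seed = 9, config = cfg)
  g <- generate_titration(scn)
  f1 <- fit_charge_regulation(g$curve, msn_nh2_model(), "N_amine",
                              config = cfg, n_starts = 2, seed = 4)
  f2 <- fit_charge_regulation(g$curve, msn_nh2_model(), "N_amine",
                              config = cfg, n_starts = 2, seed = 4)
  expect_identical(f1$parameters, f2$parameters)
  # reordering data points does not change the objective
  rev_curve <- titration_curve(g$curve$pH, g$curve$zeta)  # already sorted
  f3 <- fit_charge_regulation(rev_curve, msn_nh2_model(), "N_amine",
                              config = cfg, n_starts = 2, seed = 4)
  expect_equal(f3$parameters, f1$parameters, tolerance = 1e-10)
})

test_that("titration curve validation rejects malformed input", {
  expect_error(titration_curve(c(3, 2), c(1, 2)), "increasing")
  expect_error(titration_curve(c(3, 15), c(1, 2)), "0, 14")
  expect_error(titration_curve(c(3, 4), c(1, NaN)), "finite")
  expect_error(fit_charge_regulation(titration_curve(5, -3), msn_model(),
                                     c("pK_acid", "N_acid")),
               "at least as many data points")
})
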