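test_that("dispersion potential has the B/x^3 form with saturation", {
  expect_equal(dispersion_potential(0, c(0, 1e-9, 5e-9)), c(0, 0, 0))
  expect_equal(dispersion_potential(1e-50, 1e-9), 1e-23)
  # x^-3 scaling above the cutoff
  expect_equal(dispersion_potential(3e-50, 2e-9),
               dispersion_potential(3e-50, 1e-9) / 8)
  # saturation below the cutoff
  expect_equal(dispersion_potential(1e-50, 1e-10, cutoff = 2e-10),
               dispersion_potential(1e-50, 2e-10, cutoff = 2e-10))
  expect_error(dispersion_potential(1e-50, 1e-9, cutoff = 0), "positive")
})

test_that("uncharged surface gives an identically zero field", {
  comp <- salt_composition(0.010)
  prof <- pb_solve_fixed_charge(0, comp, fast_config())
  expect_true(all(prof$psi == 0))
  expect_equal(prof$sigma, 0)
  m0 <- surface_model(surface_site("acid_silanol", 7, 0))
  prof2 <- pb_solve(m0, comp, fast_config())
  expect_true(all(prof2$psi == 0))
})

test_that("fixed-charge solutions reproduce the Grahame equation", {
  cfg <- solver_config()
  for (c_molar in c(0.001, 0.010, 0.100)) {
    comp <- salt_composition(c_molar)
    for (psi_t in c(-0.1, -0.05, 0.025, 0.1)) {
      sigma <- grahame_sigma(psi_t, c_molar)
      prof <- pb_solve_fixed_charge(sigma, comp, cfg)
      expect_lt(abs(prof$psi0 - psi_t) / abs(psi_t), 1e-3,
                label = sprintf("Grahame %g M, %g mV", c_molar, 1e3 * psi_t))
    }
  }
})

test_that("low-potential profiles decay as Debye-Hueckel", {
  comp <- salt_composition(0.010)
  cfg <- solver_config()
  lD <- debye_length(comp)
  sigma <- grahame_sigma(-0.004, 0.010)
  prof <- pb_solve_fixed_charge(sigma, comp, cfg)
  expect_lte(abs(prof$psi0), 5e-3)
  sel <- prof$x > 0 & prof$x <= 10 * lD
  dh <- dh_profile(prof$psi0, prof$x, lD)
  expect_lt(max(abs(prof$psi[sel] - dh[sel]) / abs(dh[sel])), 0.01)
})

test_that("linearized capacitor formula holds at very low charge", {
  comp <- salt_composition(0.010)
  prof <- pb_solve_fixed_charge(-0.001, comp, solver_config())
  eps <- 78.36 * CONST$eps0
  expect_equal(prof$psi0, -0.001 * debye_length(comp) / eps,
               tolerance = 0.02)
})

test_that("psi0 and sigma share a sign; |psi| decays monotonically", {
  comp <- salt_composition(0.010)
  cfg <- fast_config()
  for (sigma in c(-0.02, -0.001, 0.005, 0.03)) {
    prof <- pb_solve_fixed_charge(sigma, comp, cfg)
    expect_gt(prof$psi0 * sigma, 0)
    expect_true(all(diff(abs(prof$psi)) <= 1e-15))
    # far boundary is effectively zero
    expect_lt(abs(prof$psi[length(prof$psi)]) / abs(prof$psi0), 1e-6)
  }
})

test_that("charge-regulated solution is self-consistent", {
  comp <- tris_composition(0.010, 7.5)
  cfg <- solver_config()
  for (m in list(msn_model(), msn_nh2_model())) {
    prof <- pb_solve(m, comp, cfg)
    sig_chem <- surface_charge_density(m, prof$psi0, comp)
    # field charge from the one-sided surface derivative
    eps <- 78.36 * CONST$eps0
    h1 <- prof$x[2] - prof$x[1]; h2 <- prof$x[3] - prof$x[2]
    dpsi0 <- prof$psi[1] * (-(2 * h1 + h2) / (h1 * (h1 + h2))) +
      prof$psi[2] * ((h1 + h2) / (h1 * h2)) +
      prof$psi[3] * (-h1 / (h2 * (h1 + h2)))
    expect_equal(-eps * dpsi0, sig_chem, tolerance = 1e-5)
    expect_equal(prof$sigma, sig_chem, tolerance = 1e-12)
  }
})

test_that("grid refinement changes psi0 by less than 0.1%", {
  comp <- tris_composition(0.010, 7.5)
  m <- msn_model()
  p1 <- pb_solve(m, comp, solver_config(n_grid = 2000))
  p2 <- pb_solve(m, comp, solver_config(n_grid = 4000))
  expect_lt(abs(p2$psi0 / p1$psi0 - 1), 1e-3)
})

test_that("spherical solution approaches planar for kappa*R >> 1", {
  # the leading curvature correction at fixed charge is ~ lD/R, so the
  # deviation must track 1/R and fall below 1% once R >> 100 lD
  comp <- salt_composition(0.010)   # lD ~ 3 nm
  sigma <- -0.005
  pl <- pb_solve_fixed_charge(sigma, comp, solver_config())
  dev <- vapply(c(75e-9, 300e-9, 1200e-9), function(R) {
    sp <- pb_solve_fixed_charge(sigma, comp,
                                solver_config(geometry = "spherical",
                                              radius = R))
    # curvature lowers the potential magnitude at fixed charge
    expect_lt(abs(sp$psi0), abs(pl$psi0))
    abs(sp$psi0 / pl$psi0 - 1)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[1], 0.05)      # ~ lD/R = 4% at R = 75 nm
  expect_lt(dev[3], 0.01)
})

test_that("dispersion off and all-zero B coefficients agree to machine level", {
  comp <- tris_composition(0.010, 7.5)
  m <- msn_nh2_model()
  off <- pb_solve(m, comp, fast_config(dispersion_enabled = FALSE))
  on0 <- pb_solve(m, comp, fast_config(dispersion_enabled = TRUE))
  expect_equal(on0$psi0, off$psi0, tolerance = 1e-12)
  expect_equal(on0$psi, off$psi, tolerance = 1e-12)
})

test_that("attractive counterion dispersion shifts the surface potential", {
  # negative B on the counterion draws it to the surface, screening more
  B <- c("Cl-" = -2e-50, "Na+" = -2e-50, "TrisH+" = -2e-50)
  comp_cl <- tris_composition(0.010, 7.5, dispersion_B = B)
  m <- msn_model()
  cl <- pb_solve(m, comp_cl, fast_config(dispersion_enabled = TRUE))
  off <- pb_solve(m, comp_cl, fast_config(dispersion_enabled = FALSE))
  expect_false(isTRUE(all.equal(cl$psi0, off$psi0, tolerance = 1e-6)))
})

test_that("solver rejects non-electroneutral input", {
  sp <- rbind(ion_species("Na+", 1, 0.010), ion_species("Cl-", -1, 0.005))
  comp <- list(species = as.data.frame(sp), pH = 7, temperature = 298.15,
               rel_permittivity = 78.36)
  class(comp) <- "electrolyte_composition"
  expect_error(pb_solve_fixed_charge(-0.01, comp, fast_config()),
               "electroneutral")
})
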