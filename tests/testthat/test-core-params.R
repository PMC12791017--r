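test_that("conversion factors match dimensional analysis", {
  # wt% -> g per cm^3 porewater -> mol -> mM, / 1.7 mol OC per mol sulfate
  expect_equal(oc_conversion_factor(0.75, 2.65),
               2.65 * 0.25 / 0.75 * 1e4 / (12.011 * 1.7),
               tolerance = 1e-12)
  expect_equal(round(oc_conversion_factor(0.75, 2.65)), 433)
  expect_equal(fe_conversion_factor(0.75, 2.65),
               2.65 * 0.25 / 0.75 * 2e4 / 55.845, tolerance = 1e-12)
  expect_equal(round(fe_conversion_factor(0.75, 2.65)), 316)
  # f_F / f_P is the FeS2-to-Fe mass ratio: 1 wt% Fe -> 2.148 wt% FeS2
  expect_equal(fe_conversion_factor(0.6, 2.65) /
                 pyrite_conversion_factor(0.6, 2.65),
               119.98 / 55.845, tolerance = 1e-12)
  expect_equal(oc_conversion_factor(0.5, 0), 0)
})

test_that("degenerate porosity is rejected, not clamped", {
  expect_error(oc_conversion_factor(0, 2.65), "porosity")
  expect_error(oc_conversion_factor(1, 2.65), "porosity")
  expect_error(fe_conversion_factor(1.2, 2.65), "porosity")
  expect_error(diffusivity(4, 0), "porosity")
})

test_that("sweeping printed input ranges reproduces the governing-variable ranges", {
  # OC 0.2-1.4 wt%, porosity 0.6-0.9, 28 mM sulfate -> Gamma0 ~ 1 to 40
  grid <- expand.grid(oc = seq(0.2, 1.4, length.out = 7),
                      phi = seq(0.6, 0.9, length.out = 7))
  gamma0 <- oc_conversion_factor(grid$phi, 2.65) * grid$oc / 28
  expect_gt(min(gamma0), 0.7)
  expect_lt(min(gamma0), 1.5)
  expect_gt(max(gamma0), 30)
  expect_lt(max(gamma0), 50)
  # Fe_HR 0.3-3.0 wt% -> Psi0 of order 1 to 50
  fe_grid <- expand.grid(fe = seq(0.3, 3, length.out = 7),
                         phi = seq(0.6, 0.9, length.out = 7))
  psi0 <- fe_conversion_factor(fe_grid$phi, 2.65) * fe_grid$fe / 28
  expect_lt(min(psi0), 3)
  expect_gt(max(psi0), 30)
})

test_that("diffusivity has the right magnitude, temperature trend and ratio", {
  d4 <- diffusivity(4, 0.7, "sulfate")
  expect_gt(d4, 50)   # order 1e2 cm^2/yr at median conditions
  expect_lt(d4, 300)
  expect_gt(diffusivity(9, 0.7, "sulfate"), d4)        # monotone in T
  expect_gt(diffusivity(4, 0.9, "sulfate"), d4)        # less tortuous
  expect_error(diffusivity(60, 0.7), "plausible")
  expect_error(diffusivity(4, 0.7, "thiosulfate"))
  # same coefficients for both species would give Delta = 1
  cfg <- sed_config(diffusivity = list(sulfide = list(m0 = 4.88, m1 = 0.232)))
  expect_equal(diffusivity(4, 0.7, "sulfide", cfg),
               diffusivity(4, 0.7, "sulfate", cfg))
})

test_that("equilibrium fractionation sits in the low-temperature band and weakens with warming", {
  eps4 <- 1000 * (equilibrium_alpha(4) - 1)
  expect_lt(eps4, -60)
  expect_gt(eps4, -72)
  expect_lt(equilibrium_alpha(4), 1)
  expect_gt(abs(1000 * log(equilibrium_alpha(4))),
            abs(1000 * log(equilibrium_alpha(25))))
})

test_that("decay to the onset depth shifts the power-law origin", {
  # z0 = 0 is the identity
  out <- decay_to_onset(1.2, 1e-3, 0.125, 0.05, 0)
  expect_equal(out$content, 1.2)
  expect_equal(out$k, 1e-3)
  # deeper onset strictly decreases both content and reactivity
  d1 <- decay_to_onset(1.2, 1e-3, 0.125, 0.05, 5)
  d2 <- decay_to_onset(1.2, 1e-3, 0.125, 0.05, 50)
  expect_lt(d1$content, 1.2)
  expect_lt(d2$content, d1$content)
  expect_lt(d2$k, d1$k)
  expect_error(decay_to_onset(1, 1e-3, 0.125, 0.05, -1))
})

test_that("nondimensionalization reproduces the hand-derived parameter set", {
  # sqrt(D_S k_G0) / w with the printed median constants
  expect_equal(sqrt(103 * 6.2e-7) / 0.008, 1.0, tolerance = 0.01)
  site <- example_site()
  p <- nondimensionalize(site)
  f_G <- oc_conversion_factor(site$porosity, site$solid_density)
  oc0 <- decay_to_onset(site$oc_swi, site$oc_reactivity_swi, 0.125,
                        site$sed_rate, site$onset_depth)
  expect_equal(p$gamma0, f_G * oc0$content / site$sulfate, tolerance = 1e-12)
  expect_equal(p$da_star, sqrt(p$D_S * oc0$k) / site$sed_rate,
               tolerance = 1e-12)
  expect_equal(p$kappa_S, 1 / 28, tolerance = 1e-12)
  # euxinic boundary like the Black Sea: 0.4 mM sulfide against 28 mM sulfate
  site$sulfide <- 0.4
  expect_equal(nondimensionalize(site)$eta0, 0.4 / 28, tolerance = 1e-12)
  site$sulfate <- 0
  expect_error(nondimensionalize(site), "S0")
})

test_that("boundary isotope ratios invert the delta notation exactly", {
  p <- nondim_params(1, 1, 1, d34S_sulfate = 28)
  expect_equal((p$R_sulfate0 / 0.0441626 - 1) * 1000, 28, tolerance = 1e-10)
  p0 <- nondim_params(1, 1, 1, d34S_sulfate = 0)
  expect_equal(p0$R_sulfate0, 0.0441626)
})
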