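test_that("grid synthesis is deterministic and leaves the caller's RNG alone", {
  g1 <- synthesize_grid(seed = 7, n_cells = 80)
  set.seed(99)
  marker <- runif(1)
  g2 <- synthesize_grid(seed = 7, n_cells = 80)
  expect_identical(g1, g2)
  set.seed(99)
  expect_identical(runif(1), marker)
})

test_that("synthetic grids reproduce the intended area shares and parameter ranges", {
  g <- synthesize_grid(seed = 3, n_cells = 10000)
  ab <- sum(g$area[g$regime == "abyss"]) / sum(g$area)
  expect_gt(ab, 0.83)
  expect_lt(ab, 0.87)
  expect_true(all(g$porosity > 0.59 & g$porosity < 0.91))
  expect_true(all(g$sed_rate > 0))
  # non-dimensionalized OC delivery spans the modern-ocean range
  sub <- g[sample.int(nrow(g), 400), ]
  gamma0 <- vapply(seq_len(nrow(sub)),
                   function(i) nondimensionalize(sub[i, ])$gamma0, 0)
  expect_lt(quantile(gamma0, 0.05), 3)
  expect_gt(quantile(gamma0, 0.95), 15)
  expect_gt(min(gamma0), 0.05)
  expect_lt(max(gamma0), 400)
})

test_that("masked cells are excluded and totals respect permutation invariance", {
  g <- fixture_grid()
  gr <- run_global(g, fast_config())
  expect_equal(gr$totals$n_active + gr$totals$n_masked, nrow(g))
  # order of cells must not change the totals
  g_perm <- g[rev(seq_len(nrow(g))), ]
  gr_perm <- run_global(g_perm, fast_config())
  expect_equal(gr_perm$totals$J_S_mol_yr, gr$totals$J_S_mol_yr,
               tolerance = 1e-12)
  expect_equal(gr_perm$totals$d34S_mean, gr$totals$d34S_mean,
               tolerance = 1e-12)
  # regional fluxes sum to the total
  expect_equal(sum(gr$regional$J_S_mol_yr), gr$totals$J_S_mol_yr,
               tolerance = 1e-10 * gr$totals$J_S_mol_yr)
  expect_equal(sum(gr$regional$flux_fraction), 1, tolerance = 1e-10)
  # all cells masked -> zero burial
  g_masked <- dplyr::mutate(g, mask = "oxic_to_basement")
  gr0 <- run_global(g_masked, fast_config())
  expect_equal(gr0$totals$J_S_mol_yr, 0)
  expect_true(is.na(gr0$totals$d34S_mean))
})

test_that("shallow margins dominate burial despite their small area", {
  gr <- run_global(fixture_grid(), fast_config())
  reg <- gr$regional
  shelf_slope <- sum(reg$flux_fraction[reg$regime != "abyss"])
  expect_gt(shelf_slope, 0.5)
  area_frac <- sum(fixture_grid()$area[fixture_grid()$regime != "abyss"]) /
    sum(fixture_grid()$area)
  expect_lt(area_frac, 0.25)
})

test_that("sensitivity tests perturb one variable at a time", {
  g <- fixture_grid(n_cells = 40)
  cfg <- fast_config()
  base <- run_global(g, cfg)
  # a zero-magnitude perturbation reproduces the baseline exactly
  same <- run_sensitivity(g, "oc_swi", "increase", magnitude = 1,
                          config = cfg)
  expect_equal(same$totals$J_S_mol_yr, base$totals$J_S_mol_yr,
               tolerance = 1e-12)
  # the porosity test applies the stated uniform decrease
  g_dec <- g
  g_dec$porosity <- g$porosity * (1 - 0.077)
  por <- run_sensitivity(g, "porosity", "decrease", config = cfg)
  expect_equal(por$totals$J_S_mol_yr,
               run_global(g_dec, cfg)$totals$J_S_mol_yr, tolerance = 1e-12)
  expect_error(run_sensitivity(g, "salinity", config = cfg), "unknown")
})

test_that("iron delivery moves burial flux much more than its isotopic composition", {
  g <- fixture_grid(n_cells = 40)
  cfg <- fast_config()
  base <- run_global(g, cfg)
  up <- run_sensitivity(g, "fe_swi", "increase", magnitude = 2, config = cfg)
  flux_resp <- abs(log(up$totals$J_S_mol_yr / base$totals$J_S_mol_yr))
  d34_resp <- abs(up$totals$d34S_mean - base$totals$d34S_mean) /
    abs(1000 * (equilibrium_alpha(4) - 1))
  expect_gt(flux_resp, 5 * d34_resp)
})

test_that("sedimentation-rate test supports both dependent-parameter modes", {
  g <- fixture_grid(n_cells = 30)
  cfg <- fast_config()
  held <- run_sensitivity(g, "sed_rate", "increase", magnitude = 1.5,
                          recompute_dependent = FALSE, config = cfg)
  recomp <- run_sensitivity(g, "sed_rate", "increase", magnitude = 1.5,
                            recompute_dependent = TRUE, config = cfg)
  expect_false(isTRUE(all.equal(held$totals$J_S_mol_yr,
                                recomp$totals$J_S_mol_yr)))
})

test_that("representative scenarios cover both OC levels in all three regimes", {
  sc <- representative_scenarios(fixture_grid(n_cells = 400))
  expect_equal(nrow(sc), 6)
  expect_setequal(
    sc$scenario,
    c("shelf_high", "shelf_low", "slope_high", "slope_low",
      "abyss_high", "abyss_low")
  )
  wide <- tidyr::pivot_wider(sc[, c("scenario", "oc_swi")],
                             names_from = "scenario",
                             values_from = "oc_swi")
  expect_gt(wide$shelf_high, wide$shelf_low)
  expect_gt(wide$abyss_high, wide$abyss_low)
})
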