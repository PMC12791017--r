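#' Synthesize a global boundary-condition grid
#'
#' Generates a reproducible set of ocean grid cells emulating globally
#' gridded boundary-condition maps: bathymetric regimes drawn with
#' realistic area shares (abyssal ocean about 85 % of sea floor),
#' depth-dependent lognormal sedimentation rate, organic-carbon contents of
#' roughly 0.2-1.4 wt%, reactive iron 0.3-3 wt%, porosity 0.6-0.9, a
#' temperature-depth law, an oxygen-penetration-depth law in sedimentation
#' rate, and an `oxic_to_basement` mask for deep low-flux cells where oxygen
#' reaches the basement and no pyrite forms. Same seed, same grid,
#' bit for bit.
#'
#' @param seed Integer seed.
#' @param n_cells Number of cells.
#' @param regime_mix Named area shares for `shelf` (0-200 mbsl), `slope`
#'   (200-2000) and `abyss` (>= 2000); default c(0.07, 0.08, 0.85).
#' @param euxinic_fraction Fraction of shelf cells given sulfidic bottom
#'   water (0.4 mM, like restricted euxinic basins); default 0.
#' @param ocean_area_cm2 Total ocean area represented (default 3.6e18 cm^2).
#' @param config Model configuration.
#' @return A tibble with one row per cell: `cell_id`, `regime`,
#'   `water_depth`, `area`, the site-condition fields, and `mask`
#'   (`"active"` or `"oxic_to_basement"`).
#' @examples
#' g <- synthesize_grid(seed = 1, n_cells = 50)
#' table(g$regime)
#' @export
synthesize_grid <- function(seed, n_cells = 1000,
                            regime_mix = c(shelf = 0.07, slope = 0.08,
                                           abyss = 0.85),
                            euxinic_fraction = 0,
                            ocean_area_cm2 = 3.6e18,
                            config = sed_config()) {
  stopifnot(n_cells >= 1, abs(sum(regime_mix) - 1) < 1e-8)
  with_local_seed(seed, {
    regime <- sample(names(regime_mix), n_cells, replace = TRUE,
                     prob = regime_mix)
    depth <- dplyr::case_when(
      regime == "shelf" ~ runif(n_cells, 10, 200),
      regime == "slope" ~ exp(runif(n_cells, log(200), log(2000))),
      TRUE ~ runif(n_cells, 2000, 6000)
    )
    w_med <- c(shelf = 0.05, slope = 0.01, abyss = 0.003)[regime]
    w <- rlnorm(n_cells, log(w_med), 0.5)
    oc_med <- c(shelf = 1.0, slope = 0.6, abyss = 0.3)[regime]
    oc <- pmin(pmax(rlnorm(n_cells, log(oc_med), 0.4), 0.05), 3)
    fe_med <- c(shelf = 1.0, slope = 0.8, abyss = 0.5)[regime]
    fe <- pmin(pmax(rlnorm(n_cells, log(fe_med), 0.4), 0.1), 4)
    phi_lo <- c(shelf = 0.60, slope = 0.65, abyss = 0.70)[regime]
    phi <- runif(n_cells, phi_lo, phi_lo + 0.2)
    temp <- pmax(-1.5, 2 + 12 * exp(-depth / 250) + rnorm(n_cells, 0, 0.8))
    # oxygen-penetration depth deepens as sedimentation rate drops
    z0 <- pmin(2 * (0.01 / w)^0.9 * exp(rnorm(n_cells, 0, 0.5)), 500)
    # deep, slowly accumulating cells where oxygen reaches basement
    p_mask <- ifelse(regime == "abyss",
                     pmin(0.35, pmax(0, (depth - 3500) / 8000)), 0)
    mask <- ifelse(runif(n_cells) < p_mask, "oxic_to_basement", "active")
    h0 <- ifelse(regime == "shelf" & runif(n_cells) < euxinic_fraction,
                 0.4, 0)
    thick <- rlnorm(n_cells,
                    log(c(shelf = 1e5, slope = 6e4, abyss = 24300)[regime]),
                    0.6)
    tibble::tibble(
      cell_id = seq_len(n_cells),
      regime = regime,
      water_depth = depth,
      area = ocean_area_cm2 / n_cells,
      temperature = temp,
      porosity = phi,
      solid_density = 2.65,
      sed_rate = w,
      oc_swi = oc,
      oc_reactivity_swi = oc_reactivity_sw(w, config),
      fe_swi = fe,
      onset_depth = z0,
      sulfate = config$boundary$S0,
      sulfide = h0,
      d34S_sulfate_sw = config$boundary$d34S_sulfate,
      d34S_sulfide_sw = config$boundary$d34S_sulfide,
      sediment_thickness = thick,
      pixel_area = ocean_area_cm2 / n_cells,
      mask = mask
    )
  })
}

regime_bins <- function(depth) {
  cut(depth, breaks = c(-Inf, 200, 2000, Inf),
      labels = c("shelf", "slope", "abyss"))
}

#' Run the diagenetic model over a grid
#'
#' Solves every active cell independently (results do not depend on
#' evaluation order), aggregates pyrite burial to global totals in
#' mol S yr^-1, computes the flux-weighted mean delta-34S of buried pyrite
#' and the global `Delta_pyrite`, and partitions burial across bathymetric
#' regimes (shelf 0-200 mbsl, slope 200-2000 mbsl, abyss >= 2000 mbsl).
#' Cells whose solve fails are reported as a failure fraction, never
#' silently dropped.
#'
#' @param grid Tibble from [synthesize_grid()] (or a compatible reader).
#' @param config Model configuration.
#' @return A `pyrite_global` object: list with `cells` (per-cell burial
#'   results), `totals` (one-row tibble: `J_S_mol_yr`, `d34S_mean`,
#'   `delta_pyrite`, `n_active`, `n_failed`, `failure_fraction`), and
#'   `regional` (per-regime fluxes and fractions).
#' @export
run_global <- function(grid, config = sed_config()) {
  active <- grid$mask == "active"
  res <- purrr::map(which(active), function(i) {
    site <- grid[i, ]
    tryCatch({
      fit <- solve_site(site, config)
      dplyr::mutate(fit$burial, cell_id = site$cell_id, .before = 1)
    }, error = function(e) {
      tibble::tibble(cell_id = site$cell_id, z_max_cm = NA_real_,
                     n_P_mol = NA_real_, J_P_mol_yr = NA_real_,
                     J_S_mol_yr = NA_real_, d34S_pyrite = NA_real_,
                     delta_pyrite = NA_real_)
    })
  })
  empty <- tibble::tibble(
    cell_id = integer(), z_max_cm = numeric(), n_P_mol = numeric(),
    J_P_mol_yr = numeric(), J_S_mol_yr = numeric(),
    d34S_pyrite = numeric(), delta_pyrite = numeric()
  )
  cells <- dplyr::bind_rows(empty, res) %>%
    dplyr::left_join(
      dplyr::select(grid, "cell_id", "regime", "water_depth", "area"),
      by = "cell_id"
    )
  failed <- if (nrow(cells) > 0) !is.finite(cells$J_S_mol_yr) else logical(0)
  ok <- cells[!failed, ]
  d34S_mean <- if (nrow(ok) > 0 && any(ok$J_P_mol_yr > 0)) {
    weighted_mean_d34S(ok$d34S_pyrite, ok$J_P_mol_yr)
  } else {
    NA_real_
  }
  totals <- tibble::tibble(
    J_S_mol_yr = sum(ok$J_S_mol_yr),
    d34S_mean = d34S_mean,
    delta_pyrite = config$boundary$d34S_sulfate - d34S_mean,
    n_active = sum(grid$mask == "active"),
    n_masked = sum(grid$mask != "active"),
    n_failed = sum(failed),
    failure_fraction = mean(failed)
  )
  regional <- ok %>%
    dplyr::mutate(regime = regime_bins(.data$water_depth)) %>%
    dplyr::group_by(.data$regime) %>%
    dplyr::summarise(J_S_mol_yr = sum(.data$J_S_mol_yr),
                     n_cells = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(flux_fraction = .data$J_S_mol_yr / sum(.data$J_S_mol_yr))
  structure(list(cells = cells, totals = totals, regional = regional,
                 config_hash = config_hash(config)),
            class = "pyrite_global")
}

#' @export
print.pyrite_global <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "<pyrite_global> %d active cells (%d failed): J = %.3g mol S yr^-1\n",
    t$n_active, t$n_failed, t$J_S_mol_yr
  ))
  cat(sprintf("  d34S_mean = %.1f permil, Delta_pyrite = %.1f permil\n",
              t$d34S_mean, t$delta_pyrite))
  print(x$regional)
  invisible(x)
}

#' One-at-a-time sensitivity test on a grid
#'
#' Perturbs a single boundary condition across the whole grid and reruns
#' the global model. Available tests mirror the standard suite:
#' \describe{
#'   \item{porosity}{uniform decrease by 7.7 % (maximum compaction
#'     estimate); `magnitude` overrides.}
#'   \item{sed_rate}{multiply/divide by `magnitude` (default 2). With
#'     `recompute_dependent = TRUE` the OC reactivity and
#'     oxygen-penetration depth are recomputed from the perturbed rate;
#'     otherwise they are held at baseline.}
#'   \item{oc_swi, fe_swi}{multiply/divide contents by `magnitude`
#'     (default 2).}
#'   \item{diffusivity}{shift seafloor temperature by `magnitude` degC
#'     (default 2), changing both diffusivities and the fractionation
#'     factor's temperature.}
#'   \item{onset_depth}{multiply the onset depth by `magnitude`
#'     (default 10: oxygen-penetration depth vs mixed-layer depth).}
#'   \item{chi}{multiply/divide the iron-to-OC reactivity ratio.}
#'   \item{oc_reactivity}{multiply/divide the interface OC reactivity.}
#' }
#'
#' @param grid Grid tibble.
#' @param test Test name (see above).
#' @param direction `"increase"` or `"decrease"`.
#' @param magnitude Perturbation size; defaults per test.
#' @param recompute_dependent For `sed_rate`: recompute rate-dependent
#'   parameters (reactivity, onset depth) from the perturbed rate.
#' @param config Model configuration.
#' @return A `pyrite_global` for the perturbed grid, with attributes
#'   `test`, `direction`, `magnitude`.
#' @export
run_sensitivity <- function(grid, test, direction = c("increase", "decrease"),
                            magnitude = NULL, recompute_dependent = TRUE,
                            config = sed_config()) {
  direction <- match.arg(direction)
  sgn <- if (direction == "increase") 1 else -1
  g <- grid
  cfg <- config
  switch(test,
    porosity = {
      magnitude <- magnitude %||% 0.077
      g$porosity <- pmin(g$porosity * (1 + sgn * abs(magnitude)), 0.99)
    },
    sed_rate = {
      magnitude <- magnitude %||% 2
      fac <- magnitude^sgn
      g$sed_rate <- g$sed_rate * fac
      if (recompute_dependent) {
        g$oc_reactivity_swi <- oc_reactivity_sw(g$sed_rate, cfg)
        g$onset_depth <- pmin(g$onset_depth * fac^(-0.9), 500)
      }
    },
    oc_swi = {
      magnitude <- magnitude %||% 2
      g$oc_swi <- g$oc_swi * magnitude^sgn
    },
    fe_swi = {
      magnitude <- magnitude %||% 2
      g$fe_swi <- g$fe_swi * magnitude^sgn
    },
    diffusivity = {
      magnitude <- magnitude %||% 2
      g$temperature <- pmax(-1.9, pmin(39, g$temperature + sgn * magnitude))
    },
    onset_depth = {
      magnitude <- magnitude %||% 10
      g$onset_depth <- g$onset_depth * magnitude^sgn
    },
    chi = {
      magnitude <- magnitude %||% 2
      cfg <- modify_config(cfg, list(kinetics = list(
        chi = cfg$kinetics$chi * magnitude^sgn
      )))
    },
    oc_reactivity = {
      magnitude <- magnitude %||% 2
      g$oc_reactivity_swi <- g$oc_reactivity_swi * magnitude^sgn
    },
    stop("unknown sensitivity test: ", test, call. = FALSE)
  )
  out <- run_global(g, cfg)
  attr(out, "test") <- test
  attr(out, "direction") <- direction
  attr(out, "magnitude") <- magnitude
  out
}

#' Representative high/low organic-carbon scenarios per bathymetric regime
#'
#' Builds six site records from a grid: cells are split into high and low
#' OC (> 1 and < 1 wt%) within each regime; the high scenarios take the
#' 95th-percentile OC (low: 5th percentile) together with the mean of all
#' other boundary conditions in the batch. Used for threshold-stability
#' checks. Falls back to the whole regime when a batch is too small.
#'
#' @param grid Grid tibble.
#' @return A tibble of six site records with `scenario` labels.
#' @export
representative_scenarios <- function(grid) {
  active <- dplyr::filter(grid, .data$mask == "active")
  purrr::map_dfr(c("shelf", "slope", "abyss"), function(rg) {
    batch_all <- dplyr::filter(active, .data$regime == rg)
    purrr::map_dfr(c("high", "low"), function(lev) {
      batch <- if (lev == "high") {
        dplyr::filter(batch_all, .data$oc_swi > 1)
      } else {
        dplyr::filter(batch_all, .data$oc_swi < 1)
      }
      if (nrow(batch) < 3) batch <- batch_all
      oc <- stats::quantile(batch$oc_swi, if (lev == "high") 0.95 else 0.05,
                            names = FALSE)
      means <- dplyr::summarise(batch, dplyr::across(
        c("water_depth", "temperature", "porosity", "solid_density",
          "sed_rate", "oc_reactivity_swi", "fe_swi", "onset_depth",
          "sulfate", "sulfide", "d34S_sulfate_sw", "d34S_sulfide_sw",
          "sediment_thickness"),
        mean
      ))
      dplyr::mutate(means, oc_swi = oc, pixel_area = 1,
                    scenario = paste(rg, lev, sep = "_"),
                    site_id = paste(rg, lev, sep = "_"), .before = 1)
    })
  })
}
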