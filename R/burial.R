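#' Solve one dimensional site record end to end
#'
#' Non-dimensionalizes a site record, solves the isotopologue problem, and
#' re-dimensionalizes the outputs: depth in cm below the onset of the
#' sulfidic anoxic zone (`z = sqrt(D_S / k_G0) * zeta`), porewater
#' concentrations in mM, solid contents in wt%, plus the burial quantities
#' for the site's pixel area.
#'
#' @param site One-row data frame of site conditions (see
#'   [nondimensionalize()]; [example_site()] for the expected fields).
#' @param config Model configuration.
#' @return A `pyrite_site` object: the underlying `pyrite_profile` fit plus
#'   `site`, a dimensional `profile` tibble (`z_cm`, `sulfate_mM`,
#'   `sulfide_mM`, `oc_wtpct`, `fehr_wtpct`, `pyrite_wtpct`, delta curves)
#'   and a one-row `burial` tibble ([burial_result()]).
#' @examples
#' \donttest{
#' fit <- solve_site(example_site())
#' fit$burial
#' }
#' @export
solve_site <- function(site, config = sed_config()) {
  params <- nondimensionalize(site, config)
  fit <- solve_profile(params, config)
  pr <- fit$profile
  lscale <- sqrt(params$D_S / params$k_G0)
  dim_profile <- tibble::tibble(
    z_cm = pr$zeta * lscale,
    sulfate_mM = pr$sigma * params$S0,
    sulfide_mM = pr$eta * params$S0,
    oc_wtpct = pr$gamma * params$S0 / params$f_G,
    fehr_wtpct = pr$psi * params$S0 / params$f_F,
    pyrite_wtpct = pr$pi * params$S0 / params$f_P,
    d34S_sulfate = pr$d34S_sulfate,
    d34S_sulfide = pr$d34S_sulfide,
    d34S_pyrite = pr$d34S_pyrite
  )
  out <- c(
    unclass(fit),
    list(site = tibble::as_tibble(site),
         dim_profile = dim_profile,
         z_max_cm = fit$zeta_max * lscale,
         burial = burial_result(fit, site, config))
  )
  class(out) <- c("pyrite_site", "pyrite_profile")
  out
}

#' Burial outputs for one solved site
#'
#' Converts a converged non-dimensional solution into the per-pixel burial
#' quantities: `z_max` (cm), `n_P` (depth-integrated mol FeS2 in the
#' formation zone), `J_P` (mol FeS2 yr^-1), the burial flux in mol S yr^-1
#' (2 mol S per mol FeS2), the delta-34S of buried pyrite and the paired
#' offset `delta_pyrite`.
#'
#' @param fit A `pyrite_profile` from [solve_profile()].
#' @param site The site record that produced `fit` (needs `porosity`,
#'   `solid_density`, `sed_rate`, `pixel_area`).
#' @param config Model configuration.
#' @return A one-row tibble.
#' @export
burial_result <- function(fit, site, config = sed_config()) {
  site <- as.list(site)
  params <- fit$params
  lscale <- sqrt(params$D_S / params$k_G0)
  pr <- fit$profile
  p_wt <- pr$pi * params$S0 / params$f_P
  in_zone <- pr$zeta <= fit$zeta_max
  z_cm <- pr$zeta * lscale
  n_P <- pyrite_inventory(z_cm[in_zone], p_wt[in_zone],
                          phi = site$porosity, rho_sol = site$solid_density,
                          area = site$pixel_area, config = config)
  izmax <- which.min(abs(pr$zeta - fit$zeta_max))
  J_P <- burial_flux(p_wt[izmax], w = site$sed_rate, phi = site$porosity,
                     rho_sol = site$solid_density, area = site$pixel_area,
                     config = config)
  tibble::tibble(
    z_max_cm = fit$zeta_max * lscale,
    n_P_mol = n_P,
    J_P_mol_yr = J_P,
    J_S_mol_yr = 2 * J_P,
    d34S_pyrite = fit$d34S_pyrite_buried,
    delta_pyrite = fit$delta_pyrite
  )
}

#' Depth-integrated pyrite inventory
#'
#' Quadrature of the dimensional pyrite profile over the formation zone:
#' `n_P = (1/100) rho_sol (1 - phi) A / 119.98 * integral P(z) dz`,
#' in mol FeS2 per pixel (`A` in cm^2, `P` in wt%, `z` in cm).
#'
#' @param z_cm Depth grid, cm.
#' @param p_wtpct Pyrite content on the grid, wt% FeS2.
#' @param phi Porosity.
#' @param rho_sol Solid density, g cm^-3.
#' @param area Pixel area, cm^2.
#' @param config Model configuration (FeS2 molar mass).
#' @return mol FeS2 (scalar).
#' @examples
#' # 1 wt% over 100 cm, rho 2.65, phi 0.75, 1 cm^2 -> ~5.52e-3 mol
#' pyrite_inventory(seq(0, 100, 10), rep(1, 11), 0.75, 2.65, 1)
#' @export
pyrite_inventory <- function(z_cm, p_wtpct, phi, rho_sol, area,
                             config = sed_config()) {
  if (is.null(area) || is.na(area)) stop("pixel area is required", call. = FALSE)
  if (length(z_cm) < 2) return(0)
  pref <- rho_sol * (1 - phi) * area / (100 * config$constants$M_FeS2)
  pref * utils::tail(cumtrapz(z_cm, p_wtpct), 1)
}

#' Pyrite burial flux
#'
#' At steady state the pyrite formed in the sulfidic anoxic zone equals the
#' flux advected out of it:
#' `J_P = w (1/100) rho_sol (1 - phi) A / 119.98 * P(z_max)`,
#' in mol FeS2 yr^-1 per pixel.
#'
#' @param p_zmax Pyrite content at the base of the formation zone, wt%.
#' @param w Sedimentation rate, cm yr^-1.
#' @inheritParams pyrite_inventory
#' @return mol FeS2 yr^-1 (scalar).
#' @export
burial_flux <- function(p_zmax, w, phi, rho_sol, area,
                        config = sed_config()) {
  w * rho_sol * (1 - phi) * area * p_zmax / (100 * config$constants$M_FeS2)
}

#' Flux-weighted mean delta-34S of buried pyrite
#'
#' `sum(J_P * d34S) / sum(J_P)` over cells or sites with positive flux.
#'
#' @param d34S Per-cell delta-34S of buried pyrite, permil.
#' @param flux Per-cell burial flux (any consistent unit).
#' @return Weighted mean, permil.
#' @export
weighted_mean_d34S <- function(d34S, flux) {
  keep <- is.finite(d34S) & is.finite(flux) & flux > 0
  if (!any(keep)) stop("no cells with positive burial flux", call. = FALSE)
  sum(flux[keep] * d34S[keep]) / sum(flux[keep])
}

#' Model-data misfit for measured site profiles
#'
#' Interpolates modelled profiles onto the depths of a measured-site table
#' (monotone piecewise-cubic in depth) and reports per-site, per-variable
#' RMSE and residual summaries. Observations deeper than the model domain
#' are excluded from the RMSE and counted.
#'
#' @param fit A `pyrite_site` from [solve_site()].
#' @param measured Long-format tibble with columns `site_id`, `depth_cm`,
#'   `variable`, `value`; `variable` in `pyrite_wtpct`, `d34S_pyrite`,
#'   `sulfate_mM`, `sulfide_mM`, `d34S_sulfate`, `oc_wtpct`, `fehr_wtpct`.
#' @return A tibble with one row per variable: `n_used`, `n_excluded`,
#'   `rmse`, `residual_median` (model minus data).
#' @export
misfit <- function(fit, measured) {
  stopifnot(inherits(fit, "pyrite_site"))
  vars <- intersect(unique(measured$variable), names(fit$dim_profile))
  if (length(vars) == 0) stop("no overlapping variables", call. = FALSE)
  zmax_dom <- max(fit$dim_profile$z_cm)
  purrr::map_dfr(vars, function(v) {
    obs <- dplyr::filter(measured, .data$variable == v, is.finite(.data$value))
    inside <- obs$depth_cm <= zmax_dom & obs$depth_cm >= 0
    obs_in <- obs[inside, ]
    mod <- fit$dim_profile[[v]]
    ok <- is.finite(mod)
    if (nrow(obs_in) == 0 || sum(ok) < 2) {
      return(tibble::tibble(variable = v, n_used = 0L,
                            n_excluded = sum(!inside), rmse = NA_real_,
                            residual_median = NA_real_))
    }
    f <- stats::splinefun(fit$dim_profile$z_cm[ok], mod[ok],
                          method = "monoH.FC")
    resid <- f(obs_in$depth_cm) - obs_in$value
    tibble::tibble(
      variable = v,
      n_used = nrow(obs_in),
      n_excluded = sum(!inside),
      rmse = sqrt(mean(resid^2)),
      residual_median = stats::median(resid)
    )
  })
}

#' Pooled misfit report across sites
#'
#' Runs [solve_site()] + [misfit()] over a table of sites and a pooled
#' measured table, returning per-site rows plus per-variable median RMSE
#' (the headline validation statistic) and pooled residual summaries.
#'
#' @param sites Tibble of site records with a `site_id` column.
#' @param measured Long-format measured table (see [misfit()]).
#' @param config Model configuration.
#' @return A list with `per_site` (tibble) and `medians` (tibble of median
#'   RMSE per variable).
#' @export
misfit_report <- function(sites, measured, config = sed_config()) {
  per_site <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    site <- sites[i, ]
    res <- tryCatch({
      fit <- solve_site(site, config)
      misfit(fit, dplyr::filter(measured, .data$site_id == site$site_id))
    }, error = function(e) {
      tibble::tibble(variable = NA_character_, n_used = 0L, n_excluded = 0L,
                     rmse = NA_real_, residual_median = NA_real_)
    })
    dplyr::mutate(res, site_id = site$site_id, .before = 1)
  })
  medians <- per_site %>%
    dplyr::filter(is.finite(.data$rmse)) %>%
    dplyr::group_by(.data$variable) %>%
    dplyr::summarise(
      median_rmse = stats::median(.data$rmse),
      median_residual = stats::median(.data$residual_median),
      n_sites = dplyr::n(),
      .groups = "drop"
    )
  list(per_site = per_site, medians = medians)
}
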