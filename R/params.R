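#' Unit-conversion factors between solid contents and porewater solutes
#'
#' Sediment solids are measured in wt% of dry mass while porewater solutes
#' are in mM, so source/sink terms need a conversion through the sediment
#' matrix: 1 wt% of solid corresponds to
#' `rho_sol * (1 - phi) / phi / 100` grams of solid per cm^3 of porewater.
#'
#' * `oc_conversion_factor()`: mM sulfate reduced per wt% organic carbon
#'   respired (divides by the molar mass of C and the 1.7 mol OC per mol
#'   sulfate stoichiometry of microbial sulfate reduction).
#' * `fe_conversion_factor()`: mM sulfide consumed per wt% reactive iron
#'   pyritized (2 mol S per mol Fe in FeS2).
#' * `pyrite_conversion_factor()`: mM sulfide consumed per wt% pyrite formed
#'   (2 mol S per mol FeS2); the ratio `f_F / f_P` is then the FeS2-to-Fe
#'   mass ratio that turns a wt% iron loss into the stoichiometric wt%
#'   pyrite gain.
#'
#' @param phi Porosity (fraction, strictly between 0 and 1).
#' @param rho_sol Dry solid density, g cm^-3.
#' @param config Model configuration, see [sed_config()].
#' @return The conversion factor in mM per wt% (numeric scalar or vector).
#' @examples
#' oc_conversion_factor(0.75, 2.65) # ~ 4.3e2
#' fe_conversion_factor(0.75, 2.65) # ~ 3.2e2
#' @export
oc_conversion_factor <- function(phi, rho_sol, config = sed_config()) {
  check_porosity(phi)
  stopifnot(all(rho_sol >= 0))
  rho_sol * (1 - phi) / phi * 1e4 /
    (config$constants$M_C * config$kinetics$stoich_oc_per_sulfate)
}

#' @rdname oc_conversion_factor
#' @export
fe_conversion_factor <- function(phi, rho_sol, config = sed_config()) {
  check_porosity(phi)
  stopifnot(all(rho_sol >= 0))
  rho_sol * (1 - phi) / phi * 2e4 / config$constants$M_Fe
}

#' @rdname oc_conversion_factor
#' @export
pyrite_conversion_factor <- function(phi, rho_sol, config = sed_config()) {
  check_porosity(phi)
  stopifnot(all(rho_sol >= 0))
  rho_sol * (1 - phi) / phi * 2e4 / config$constants$M_FeS2
}

check_porosity <- function(phi) {
  if (any(!is.finite(phi)) || any(phi <= 0) || any(phi >= 1)) {
    stop("degenerate porosity: phi must lie strictly in (0, 1)", call. = FALSE)
  }
  invisible(phi)
}

#' Porewater diffusivity of sulfate and sulfide
#'
#' Free-solution diffusivity follows a linear law in temperature,
#' `D0 = (m0 + m1 * T) * 1e-6` cm^2 s^-1 (coefficients per species in the
#' config), corrected for sediment tortuosity as `D = D0 / (1 - 2 ln phi)`
#' and converted to cm^2 yr^-1. At globally median conditions (T ~ 2-4 degC,
#' phi ~ 0.7) sulfate diffusivity is of order 1e2 cm^2 yr^-1.
#'
#' @param temperature Seafloor temperature, degC (plausible range -2 to 40).
#' @param phi Porosity (fraction).
#' @param species `"sulfate"` or `"sulfide"`.
#' @param config Model configuration.
#' @return Diffusivity in cm^2 yr^-1.
#' @examples
#' diffusivity(4, 0.7, "sulfate")
#' @export
diffusivity <- function(temperature, phi, species = c("sulfate", "sulfide"),
                        config = sed_config()) {
  species <- match.arg(species)
  if (any(temperature < -2 | temperature > 40)) {
    stop("temperature outside plausible seafloor range (-2 to 40 degC)",
         call. = FALSE)
  }
  check_porosity(phi)
  co <- config$diffusivity[[species]]
  d0 <- (co$m0 + co$m1 * temperature) * 1e-6 * 3.1536e7 # cm^2 s^-1 -> cm^2 yr^-1
  d0 / (1 - 2 * log(phi))
}

#' Equilibrium sulfur isotope fractionation factor of sulfate reduction
#'
#' Microbial sulfate reduction in natural sediments operates close to the
#' thermodynamic limit and expresses the equilibrium sulfide/sulfate
#' fractionation, around -65 to -70 permil at low temperatures and weakening
#' with warming. The default is a linearization of published equilibrium
#' curves over 0-40 degC, `eps_eq(T) = -(eps0 - eps_slope * T)` permil, with
#' coefficients in the config so the factor can be pinned exactly.
#'
#' @inheritParams diffusivity
#' @return `alpha34`, the 34S/32S fractionation factor sulfide/sulfate
#'   (dimensionless, < 1). Use `1000 * (alpha34 - 1)` for the epsilon form.
#' @examples
#' 1000 * log(equilibrium_alpha(4)) # about -66 permil
#' @export
equilibrium_alpha <- function(temperature, config = sed_config()) {
  eps <- -(config$alpha$eps0 - config$alpha$eps_slope * temperature)
  exp(eps / 1000)
}

#' Organic-carbon reactivity at the sediment-water interface
#'
#' Empirical power law in sedimentation rate, `k_G_sw = c * w^d` (yr^-1, w in
#' cm yr^-1), with coefficients exposed in the config. Used when building
#' synthetic grids and dimensional site records; site tables may also carry a
#' measured `oc_reactivity_swi` directly.
#'
#' @param w Sedimentation rate, cm yr^-1 (> 0).
#' @param config Model configuration.
#' @return Rate coefficient, yr^-1.
#' @export
oc_reactivity_sw <- function(w, config = sed_config()) {
  stopifnot(all(w > 0))
  config$kinetics$k_gsw_c * w^config$kinetics$k_gsw_d
}

#' Decay solid content and reactivity from the interface to the onset depth
#'
#' Solids deposited at the sediment-water interface degrade aerobically (or
#' within the mixed layer) before reaching the top of the sulfidic anoxic
#' zone at depth `z0`. Under the reactive-continuum power law the content and
#' the apparent rate coefficient at `z0` are an origin shift of the same law:
#' `G0 = G_sw * (a w / (a w + k_G_sw z0))^a` and
#' `k_G0 = k_G_sw * a w / (a w + k_G_sw z0)`. `z0 = 0` is the identity.
#'
#' @param content_sw Content at the interface, wt%.
#' @param k_sw Rate coefficient at the interface, yr^-1.
#' @param a Power-law exponent (dimensionless, > 0).
#' @param w Sedimentation rate, cm yr^-1.
#' @param z0 Onset depth of the sulfidic anoxic zone, cm (>= 0).
#' @return A list with `content` (wt%) and `k` (yr^-1) at the onset depth.
#' @examples
#' decay_to_onset(1, 1e-3, 0.125, 0.1, 10)
#' @export
decay_to_onset <- function(content_sw, k_sw, a, w, z0) {
  stopifnot(all(content_sw >= 0), all(k_sw >= 0), all(a > 0), all(w > 0),
            all(z0 >= 0))
  shift <- a * w / (a * w + k_sw * z0)
  list(content = content_sw * shift^a, k = k_sw * shift)
}

#' Collapse a site record onto the non-dimensional governing parameters
#'
#' Reduces the dimensional boundary conditions of one site to the parameter
#' set the non-dimensional model is solved with: the OC-to-sulfate ratio
#' `Gamma0 = f_G G0 / S0`, the modified Damkohler number
#' `Da* = sqrt(D_S k_G0) / w`, reactive-iron delivery `Psi0 = f_F F0 / S0`,
#' the scaled Monod constants `kappa_S = K_S / S0` and `kappa_H = K_H / S0`,
#' the diffusivity ratio `Delta = D_H / D_S`, the scaled bottom-water sulfide
#' `eta0 = H0 / S0`, the equilibrium fractionation factor, and the 34S/32S
#' boundary ratios implied by the seawater delta-34S values.
#'
#' @param site A one-row data frame (or list) of site conditions with fields
#'   `temperature` (degC), `porosity`, `solid_density` (g cm^-3), `sed_rate`
#'   (cm yr^-1), `oc_swi` (wt%), `oc_reactivity_swi` (yr^-1; computed from
#'   `sed_rate` via [oc_reactivity_sw()] when absent), `fe_swi` (wt%),
#'   `onset_depth` (cm), `sulfate` (mM), `sulfide` (mM), `d34S_sulfate_sw`
#'   and `d34S_sulfide_sw` (permil VCDT). Missing boundary fields fall back
#'   to `config$boundary`.
#' @param config Model configuration.
#' @return A list of class `nondim_params` with elements `gamma0`, `da_star`,
#'   `psi0`, `kappa_S`, `kappa_H`, `Delta`, `chi`, `a`, `b`, `alpha34`,
#'   `eta0`, `R_sulfate0`, `R_sulfide0`, plus the dimensional scales needed
#'   to re-dimensionalize (`S0`, `w`, `D_S`, `k_G0`, `f_G`, `f_F`, `f_P`,
#'   `G0`, `F0`).
#' @examples
#' site <- example_site()
#' p <- nondimensionalize(site)
#' c(p$gamma0, p$da_star, p$psi0)
#' @export
nondimensionalize <- function(site, config = sed_config()) {
  site <- as.list(site)
  bnd <- config$boundary
  kin <- config$kinetics
  get <- function(nm, default = NULL) {
    v <- site[[nm]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) default else v
  }
  S0 <- get("sulfate", bnd$S0)
  if (!is.numeric(S0) || S0 <= 0) {
    stop("sulfate concentration S0 must be > 0 (model validity requires ",
         "a few mM at least)", call. = FALSE)
  }
  H0 <- get("sulfide", bnd$H0)
  temperature <- get("temperature", bnd$temperature)
  phi <- site$porosity
  rho <- site$solid_density
  w <- site$sed_rate
  if (is.null(w) || w <= 0) stop("sedimentation rate must be > 0", call. = FALSE)
  z0 <- get("onset_depth", 0)

  k_gsw <- get("oc_reactivity_swi", oc_reactivity_sw(w, config))
  oc <- decay_to_onset(site$oc_swi, k_gsw, kin$a, w, z0)
  fe <- decay_to_onset(site$fe_swi, kin$chi * k_gsw, kin$b, w, z0)

  f_G <- oc_conversion_factor(phi, rho, config)
  f_F <- fe_conversion_factor(phi, rho, config)
  f_P <- pyrite_conversion_factor(phi, rho, config)
  D_S <- diffusivity(temperature, phi, "sulfate", config)
  D_H <- diffusivity(temperature, phi, "sulfide", config)

  d34S_SO4 <- get("d34S_sulfate_sw", bnd$d34S_sulfate)
  d34S_H2S <- get("d34S_sulfide_sw", bnd$d34S_sulfide)
  R_V <- config$constants$R_VCDT

  p <- list(
    gamma0 = f_G * oc$content / S0,
    da_star = sqrt(D_S * oc$k) / w,
    psi0 = f_F * fe$content / S0,
    kappa_S = kin$K_S / S0,
    kappa_H = kin$K_H / S0,
    Delta = D_H / D_S,
    chi = kin$chi,
    a = kin$a,
    b = kin$b,
    alpha34 = equilibrium_alpha(temperature, config),
    eta0 = H0 / S0,
    R_sulfate0 = (d34S_SO4 / 1000 + 1) * R_V,
    R_sulfide0 = (d34S_H2S / 1000 + 1) * R_V,
    S0 = S0, w = w, D_S = D_S, k_G0 = oc$k,
    f_G = f_G, f_F = f_F, f_P = f_P,
    G0 = oc$content, F0 = fe$content
  )
  structure(p, class = "nondim_params")
}

#' Assemble non-dimensional parameters directly
#'
#' Builds the solver parameter set from the governing variables themselves
#' (no dimensional site record), as used for heat maps, parameter sweeps and
#' the worked shelf example.
#'
#' @param gamma0 OC-to-sulfate ratio at the onset depth (dimensionless >= 0).
#' @param da_star Modified Damkohler number (> 0).
#' @param psi0 Reactive-iron delivery (dimensionless >= 0).
#' @param eta0 Bottom-water sulfide / sulfate ratio (>= 0; euxinic when > 0).
#' @param temperature Seafloor temperature, degC (sets `alpha34` and
#'   `Delta` through the configured laws).
#' @param alpha34 Optional override of the fractionation factor.
#' @param d34S_sulfate,d34S_sulfide Seawater boundary delta-34S, permil VCDT.
#' @param config Model configuration.
#' @return A `nondim_params` list (see [nondimensionalize()]).
#' @examples
#' nondim_params(gamma0 = 3.9, da_star = 3.7, psi0 = 10)
#' @export
nondim_params <- function(gamma0, da_star, psi0, eta0 = 0,
                          temperature = NULL, alpha34 = NULL,
                          d34S_sulfate = NULL, d34S_sulfide = NULL,
                          config = sed_config()) {
  stopifnot(gamma0 >= 0, da_star > 0, psi0 >= 0, eta0 >= 0)
  bnd <- config$boundary
  kin <- config$kinetics
  temperature <- temperature %||% bnd$temperature
  d34S_sulfate <- d34S_sulfate %||% bnd$d34S_sulfate
  d34S_sulfide <- d34S_sulfide %||% bnd$d34S_sulfide
  R_V <- config$constants$R_VCDT
  S0 <- bnd$S0
  phi_ref <- 0.7
  p <- list(
    gamma0 = gamma0, da_star = da_star, psi0 = psi0,
    kappa_S = kin$K_S / S0,
    kappa_H = kin$K_H / S0,
    Delta = diffusivity(temperature, phi_ref, "sulfide", config) /
      diffusivity(temperature, phi_ref, "sulfate", config),
    chi = kin$chi, a = kin$a, b = kin$b,
    alpha34 = alpha34 %||% equilibrium_alpha(temperature, config),
    eta0 = eta0,
    R_sulfate0 = (d34S_sulfate / 1000 + 1) * R_V,
    R_sulfide0 = (d34S_sulfide / 1000 + 1) * R_V,
    S0 = S0, w = NA_real_, D_S = NA_real_, k_G0 = NA_real_,
    f_G = NA_real_, f_F = NA_real_, f_P = NA_real_,
    G0 = NA_real_, F0 = NA_real_
  )
  structure(p, class = "nondim_params")
}

#' @export
print.nondim_params <- function(x, ...) {
  cat(sprintf(
    "<nondim_params> Gamma0 = %.3g, Da* = %.3g, Psi0 = %.3g, eta0 = %.3g\n",
    x$gamma0, x$da_star, x$psi0, x$eta0
  ))
  cat(sprintf("  kappa_S = %.3g, kappa_H = %.3g, Delta = %.3g, alpha34 = %.5f\n",
              x$kappa_S, x$kappa_H, x$Delta, x$alpha34))
  invisible(x)
}

#' A bundled example site record
#'
#' A continental-shelf-like set of boundary conditions used in examples and
#' smoke tests (not measured data).
#'
#' @return A one-row tibble of site conditions.
#' @export
example_site <- function() {
  tibble::tibble(
    site_id = "example-shelf",
    water_depth = 120,
    temperature = 8,
    porosity = 0.8,
    solid_density = 2.65,
    sed_rate = 0.1,
    oc_swi = 1.2,
    oc_reactivity_swi = oc_reactivity_sw(0.1),
    fe_swi = 1.0,
    onset_depth = 1,
    sulfate = 28,
    sulfide = 0,
    d34S_sulfate_sw = 28,
    d34S_sulfide_sw = 0,
    sediment_thickness = 24300,
    pixel_area = 1
  )
}
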