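#' Model configuration
#'
#' All tunable constants of the model live in a single nested list so that no
#' silent constants exist: kinetic parameters, unit-conversion constants, the
#' equilibrium-fractionation and diffusivity laws, solver controls and the
#' pyrite formation-zone threshold. Every solver entry point accepts a
#' `config` argument; [sed_config()] builds the default.
#'
#' Components:
#' \describe{
#'   \item{kinetics}{`a`, `b`: reactive-continuum power-law exponents for
#'     organic carbon and reactive iron (dimensionless); `chi`: ratio of
#'     reactive-iron to OC initial rate coefficients; `K_S`, `K_H`: Monod
#'     half-velocity constants (mM); `stoich_oc_per_sulfate`: mol OC respired
#'     per mol sulfate reduced (1.7); `k_gsw_c`, `k_gsw_d`: coefficients of
#'     the empirical OC-reactivity vs sedimentation-rate power law
#'     `k_G_sw = c * w^d` (yr^-1 with w in cm yr^-1).}
#'   \item{constants}{molar masses (g mol^-1), the VCDT 34S/32S ratio, and the
#'     Earth radius used for spherical cell areas (km).}
#'   \item{alpha}{coefficients of the equilibrium fractionation law
#'     `eps_eq(T) = -(eps0 - eps_slope * T)` in permil (T in degC).}
#'   \item{diffusivity}{linear free-solution diffusivity coefficients
#'     `D0 = (m0 + m1 * T) * 1e-6` cm^2 s^-1 per species, with tortuosity
#'     correction `theta2 = 1 - 2 ln(phi)`.}
#'   \item{solver}{mesh size `n`, domain cap `zeta_max`, grading exponent
#'     `grading`, Newton tolerance `tol`, `max_iter`, `max_restarts`,
#'     negative-undershoot tolerance `undershoot_tol`, and the formation-zone
#'     threshold `beta`.}
#'   \item{boundary}{default seawater state: `S0` (mM), `H0` (mM),
#'     `d34S_sulfate` and `d34S_sulfide` (permil VCDT), temperature (degC).}
#' }
#'
#' @param ... Named overrides, e.g. `sed_config(kinetics = list(chi = 5))`.
#'   Overrides are merged recursively into the defaults.
#' @return A named list of class `sed_config`.
#' @examples
#' cfg <- sed_config(solver = list(n = 201))
#' cfg$solver$n
#' @export
sed_config <- function(...) {
  cfg <- list(
    kinetics = list(
      a = 0.125,
      b = 0.25,
      chi = 25,
      K_S = 1.0,
      K_H = 1.0,
      stoich_oc_per_sulfate = 1.7,
      k_gsw_c = 0.057,
      k_gsw_d = 1.94
    ),
    constants = list(
      M_C = 12.011,
      M_Fe = 55.845,
      M_FeS2 = 119.98,
      R_VCDT = 0.0441626,
      earth_radius_km = 6371
    ),
    alpha = list(
      eps0 = 67.0,
      eps_slope = 0.15
    ),
    diffusivity = list(
      sulfate = list(m0 = 4.88, m1 = 0.232),
      sulfide = list(m0 = 10.4, m1 = 0.273)
    ),
    solver = list(
      n = 401,
      zeta_max = 5,
      grading = 1.6,
      tol = 1e-10,
      max_iter = 40,
      max_restarts = 5,
      undershoot_tol = 1e-10,
      beta = 5e-4
    ),
    boundary = list(
      S0 = 28,
      H0 = 0,
      d34S_sulfate = 28,
      d34S_sulfide = 0,
      temperature = 4
    )
  )
  modify_config(cfg, list(...))
}

modify_config <- function(cfg, over) {
  out <- merge_lists(unclass(cfg), over)
  class(out) <- "sed_config"
  out
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read / write a configuration as YAML
#'
#' @param path File path.
#' @param config A `sed_config` list.
#' @return `read_sed_config()` returns a `sed_config`; `write_sed_config()`
#'   returns `path` invisibly.
#' @export
read_sed_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(sed_config, over)
}

#' @rdname read_sed_config
#' @export
write_sed_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash a configuration for provenance
#'
#' Every result object carries the hash of the configuration that produced
#' it, so any artifact can be regenerated from its provenance record.
#'
#' @param config A `sed_config` list.
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' @export
print.sed_config <- function(x, ...) {
  cat("<sed_config> hash:", config_hash(x), "\n")
  str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
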