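#' Solver verification by the method of manufactured solutions
#'
#' A smooth sulfate/sulfide pair satisfying the boundary conditions exactly,
#' `Sigma*(zeta) = 1 - c_S (1 - exp(-zeta) - zeta exp(-zeta_max))` and
#' `eta*(zeta) = eta0 + c_H (1 - exp(-zeta) - zeta exp(-zeta_max))`,
#' is substituted into the bulk governing equations; the residual becomes an
#' analytic forcing term handed to the same Newton solver used in
#' production. The discrete solution is compared with the manufactured truth
#' under mesh refinement: the discretization is second order, so halving the
#' node spacing should reduce the L2 error about fourfold.
#'
#' @param params A `nondim_params` object (defines the coefficients the
#'   manufactured problem inherits).
#' @param config Model configuration.
#' @param n_levels Number of refinement levels (>= 3).
#' @param n0 Nodes on the coarsest mesh.
#' @param c_S,c_H Amplitudes of the manufactured fields.
#' @return A tibble with one row per level: `n`, `h` (mean spacing),
#'   `l2_error`, `max_error`, and `order` (observed convergence order
#'   between successive levels, NA on the first).
#' @examples
#' \donttest{
#' verify_mms(nondim_params(3.9, 3.7, 10))
#' }
#' @export
verify_mms <- function(params, config = sed_config(), n_levels = 4,
                       n0 = 51, c_S = 0.4, c_H = 0.2) {
  stopifnot(n_levels >= 2)
  zmax <- config$solver$zeta_max
  e5 <- exp(-zmax)
  man <- function(zeta, c0, base, sgn) {
    g <- 1 - exp(-zeta) - zeta * e5
    gp <- exp(-zeta) - e5
    gpp <- -exp(-zeta)
    list(u = base + sgn * c0 * g, up = sgn * c0 * gp, upp = sgn * c0 * gpp)
  }
  out <- purrr::map_dfr(seq_len(n_levels), function(lev) {
    n <- (n0 - 1) * 2^(lev - 1) + 1
    zeta <- zeta_grid(n, zmax, config$solver$grading)
    mS <- man(zeta, c_S, 1, -1)
    mH <- man(zeta, c_H, params$eta0, +1)
    gp <- oc_profile_deriv(params$gamma0, params$da_star, params$a, zeta)
    pp <- fe_profile_deriv(params$psi0, params$da_star, params$chi, params$b,
                           zeta)
    src <- bulk_source(gp, pp, params$kappa_S, params$kappa_H)
    # forcing = -(operator applied to the manufactured pair)
    R_man <- src(cbind(mS$u, mH$u))$R
    res_S <- params$da_star * mS$upp - mS$up + R_man[, 1]
    res_H <- params$Delta * params$da_star * mH$upp - mH$up + R_man[, 2]
    forcing <- -cbind(res_S, res_H)
    sol <- newton_bvp(
      zeta,
      c2 = c(params$da_star, params$Delta * params$da_star),
      bc0 = c(1, params$eta0),
      source_fn = src,
      Y0 = cbind(rep(1, n), rep(params$eta0, n)),
      tol = config$solver$tol,
      max_iter = config$solver$max_iter,
      forcing = forcing
    )
    if (!sol$converged) {
      stop("manufactured-solution solve failed to converge", call. = FALSE)
    }
    err <- cbind(sol$Y[, 1] - mS$u, sol$Y[, 2] - mH$u)
    tibble::tibble(
      n = n,
      h = zmax / (n - 1),
      l2_error = sqrt(sum(err^2) / length(err)),
      max_error = max(abs(err))
    )
  })
  out$order <- c(NA, log2(utils::head(out$l2_error, -1) /
                            utils::tail(out$l2_error, -1)))
  out
}
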