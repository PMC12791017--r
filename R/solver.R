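# Finite-difference Newton solver for the steady advection-diffusion-reaction
# system on the non-dimensional depth grid. Transport is linear; all
# nonlinearity sits in node-local Monod and isotopologue-fraction source
# terms, so the Jacobian is block-tridiagonal and assembled analytically.

# second-order FD transport operator c2 * u'' - u' with Dirichlet top row and
# second-order one-sided Neumann bottom row; returned as triplets
transport_triplets <- function(zeta, c2) {
  n <- length(zeta)
  i <- 2:(n - 1)
  hL <- zeta[i] - zeta[i - 1]
  hR <- zeta[i + 1] - zeta[i]
  w2m <- 2 / (hL * (hL + hR))
  w2p <- 2 / (hR * (hL + hR))
  w2c <- -2 / (hL * hR)
  d1m <- -hR / (hL * (hL + hR))
  d1c <- (hR - hL) / (hL * hR)
  d1p <- hL / (hR * (hL + hR))
  h1 <- zeta[n] - zeta[n - 1]
  h2 <- zeta[n - 1] - zeta[n - 2]
  list(
    i = c(1, rep(i, 3), n, n, n),
    j = c(1, i - 1, i, i + 1, n, n - 1, n - 2),
    x = c(
      1,
      c2 * w2m - d1m, c2 * w2c - d1c, c2 * w2p - d1p,
      (2 * h1 + h2) / (h1 * (h1 + h2)),
      -(h1 + h2) / (h1 * h2),
      h1 / (h2 * (h1 + h2))
    )
  )
}

# one-sided second-order first derivative at the top node
top_gradient <- function(zeta, u) {
  h1 <- zeta[2] - zeta[1]
  h2 <- zeta[3] - zeta[2]
  -(2 * h1 + h2) / (h1 * (h1 + h2)) * u[1] +
    (h1 + h2) / (h1 * h2) * u[2] -
    h1 / (h2 * (h1 + h2)) * u[3]
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Damped Newton on the coupled m-field system.
#   zeta: grid; c2: per-field diffusion coefficients; bc0: per-field Dirichlet
#   values at zeta = 0; source_fn(Y): list(R = n x m, dR = n x m x m array of
#   node-local partials); Y0: initial iterate; forcing: optional n x m matrix
#   added to the interior residual (method of manufactured solutions).
newton_bvp <- function(zeta, c2, bc0, source_fn, Y0,
                       tol = 1e-10, max_iter = 40, forcing = NULL,
                       neumann = NULL) {
  n <- length(zeta)
  m <- length(c2)
  interior <- 2:(n - 1)
  tr <- lapply(c2, function(cc) transport_triplets(zeta, cc))
  Ai <- unlist(lapply(seq_len(m), function(f) tr[[f]]$i + (f - 1) * n))
  Aj <- unlist(lapply(seq_len(m), function(f) tr[[f]]$j + (f - 1) * n))
  Ax <- unlist(lapply(tr, `[[`, "x"))
  A <- Matrix::sparseMatrix(i = Ai, j = Aj, x = Ax, dims = c(n * m, n * m))
  b <- numeric(n * m)
  b[1 + (seq_len(m) - 1) * n] <- bc0
  if (!is.null(neumann)) b[n + (seq_len(m) - 1) * n] <- neumann
  # row scaling for the convergence test (interior rows are O(1/h^2))
  rs <- pmax(1, Matrix::rowSums(abs(A)))

  resid <- function(Y) {
    R <- source_fn(Y)$R
    if (!is.null(forcing)) R <- R + forcing
    R[c(1, n), ] <- 0
    as.numeric(A %*% as.numeric(Y)) - b + as.numeric(R)
  }
  scaled_norm <- function(fv) max(abs(fv) / rs)

  Y <- Y0
  fv <- resid(Y)
  f0 <- scaled_norm(fv)
  stalls <- 0L
  polish_left <- 3L
  for (it in seq_len(max_iter + 3L)) {
    if (f0 < tol && polish_left == 0L) {
      return(list(Y = Y, residual = f0, iterations = it - 1L,
                  converged = TRUE))
    }
    # once inside tolerance, take a few undamped steps to drive the residual
    # to its floor: low-frequency error modes are amplified by the inverse
    # operator, so the stopping residual must be far below the target error
    if (f0 < tol) polish_left <- polish_left - 1L
    S <- source_fn(Y)
    dR <- S$dR
    si <- sj <- sx <- vector("list", m * m)
    k <- 1L
    for (f in seq_len(m)) {
      for (g in seq_len(m)) {
        si[[k]] <- interior + (f - 1) * n
        sj[[k]] <- interior + (g - 1) * n
        sx[[k]] <- dR[interior, f, g]
        k <- k + 1L
      }
    }
    J <- A + Matrix::sparseMatrix(
      i = unlist(si), j = unlist(sj), x = unlist(sx), dims = c(n * m, n * m)
    )
    step <- tryCatch(
      as.numeric(Matrix::solve(J, -fv)),
      error = function(e) NULL
    )
    if (is.null(step) || any(!is.finite(step))) {
      return(list(Y = Y, residual = f0, iterations = it,
                  converged = f0 < tol))
    }
    lambda <- 1
    accepted <- FALSE
    repeat {
      Y_try <- Y + matrix(lambda * step, n, m)
      fv_try <- resid(Y_try)
      f_try <- scaled_norm(fv_try)
      if (is.finite(f_try) && f_try < (1 - 1e-4 * lambda) * f0) {
        accepted <- TRUE
        break
      }
      lambda <- lambda / 2
      if (lambda < 1 / 128) break
    }
    if (!accepted) {
      if (f0 < tol) {
        # already inside tolerance and at the residual floor
        return(list(Y = Y, residual = f0, iterations = it, converged = TRUE))
      }
      stalls <- stalls + 1L
      if (stalls >= 3L) {
        return(list(Y = Y, residual = f0, iterations = it, converged = FALSE))
      }
      Y_try <- Y + matrix(lambda * step, n, m)
      fv_try <- resid(Y_try)
      f_try <- scaled_norm(fv_try)
      if (!is.finite(f_try)) {
        return(list(Y = Y, residual = f0, iterations = it, converged = FALSE))
      }
    } else {
      stalls <- 0L
    }
    Y <- Y_try
    fv <- fv_try
    f0 <- f_try
  }
  list(Y = Y, residual = f0, iterations = max_iter, converged = f0 < tol)
}

# Monod saturation with the negative-undershoot policy: values at or below 0
# contribute nothing and have zero slope
monod <- function(u, kappa) {
  up <- pmax(u, 0)
  list(M = up / (kappa + up), dM = ifelse(u > 0, kappa / (kappa + up)^2, 0))
}

bulk_source <- function(gp, pp, kappa_S, kappa_H) {
  n <- length(gp)
  function(Y) {
    Sg <- Y[, 1]
    et <- Y[, 2]
    ms <- monod(Sg, kappa_S)
    mh <- monod(et, kappa_H)
    R <- cbind(gp * ms$M, -gp * ms$M + pp * mh$M)
    dR <- array(0, dim = c(n, 2, 2))
    dR[, 1, 1] <- gp * ms$dM
    dR[, 2, 1] <- -gp * ms$dM
    dR[, 2, 2] <- pp * mh$dM
    list(R = R, dR = dR)
  }
}

iso_source <- function(gp, pp, kappa_S, kappa_H, alpha34) {
  n <- length(gp)
  function(Y) {
    s32 <- Y[, 1]; s34 <- Y[, 2]; h32 <- Y[, 3]; h34 <- Y[, 4]
    Sg <- s32 + s34
    ms <- monod(Sg, kappa_S)
    s32p <- pmax(s32, 0); s34p <- pmax(s34, 0)
    q <- alpha34 * s34p + s32p
    q <- pmax(q, 1e-300)
    f32 <- s32p / q
    f34 <- alpha34 * s34p / q
    df32_d32 <- alpha34 * s34p / q^2
    df32_d34 <- -alpha34 * s32p / q^2
    df34_d32 <- -alpha34 * s34p / q^2
    df34_d34 <- alpha34 * s32p / q^2
    # sulfide sink written as pp * h / (kappa + eta): smooth through eta = 0
    h32p <- pmax(h32, 0); h34p <- pmax(h34, 0)
    eta <- h32p + h34p
    den <- kappa_H + eta
    R <- cbind(
      gp * f32 * ms$M,
      gp * f34 * ms$M,
      -gp * f32 * ms$M + pp * h32p / den,
      -gp * f34 * ms$M + pp * h34p / den
    )
    dR <- array(0, dim = c(n, 4, 4))
    gS32 <- gp * (df32_d32 * ms$M + f32 * ms$dM)
    gS34 <- gp * (df32_d34 * ms$M + f32 * ms$dM)
    gT32 <- gp * (df34_d32 * ms$M + f34 * ms$dM)
    gT34 <- gp * (df34_d34 * ms$M + f34 * ms$dM)
    dR[, 1, 1] <- gS32
    dR[, 1, 2] <- gS34
    dR[, 2, 1] <- gT32
    dR[, 2, 2] <- gT34
    dR[, 3, 1] <- -gS32
    dR[, 3, 2] <- -gS34
    dR[, 4, 1] <- -gT32
    dR[, 4, 2] <- -gT34
    dR[, 3, 3] <- ifelse(h32 > 0, pp * (kappa_H + h34p) / den^2, 0)
    dR[, 3, 4] <- ifelse(h34 > 0, -pp * h32p / den^2, 0)
    dR[, 4, 3] <- ifelse(h32 > 0, -pp * h34p / den^2, 0)
    dR[, 4, 4] <- ifelse(h34 > 0, pp * (kappa_H + h32p) / den^2, 0)
    list(R = R, dR = dR)
  }
}

# closed-system explicit march used as the Newton initial iterate
bulk_initial_guess <- function(zeta, gp, pp, kappa_S, kappa_H, eta0) {
  n <- length(zeta)
  Sg <- numeric(n)
  et <- numeric(n)
  Sg[1] <- 1
  et[1] <- eta0
  for (i in seq_len(n - 1)) {
    h <- zeta[i + 1] - zeta[i]
    msr <- -gp[i] * Sg[i] / (kappa_S + Sg[i])
    snk <- -pp[i] * et[i] / (kappa_H + et[i])
    Sg[i + 1] <- max(Sg[i] - h * msr, 1e-8)
    et[i + 1] <- max(et[i] + h * (msr - snk), 0)
  }
  cbind(Sg, et)
}

#' Solve the bulk sulfate-sulfide boundary-value problem
#'
#' Solves the coupled steady-state equations for non-dimensional sulfate
#' `Sigma` and sulfide `eta` on `zeta` in \[0, zeta_max\]:
#' `Da* Sigma'' - Sigma' + Gamma'(zeta) * Sigma/(kappa_S + Sigma) = 0` and
#' `Delta Da* eta'' - eta' - Gamma' * M_Sigma + Psi'(zeta) * eta/(kappa_H +
#' eta) = 0`, with `Sigma(0) = 1`, `eta(0) = eta0` and zero gradient at the
#' deep boundary. A damped Newton iteration with analytic sparse Jacobian is
#' used; on non-convergence the initial iterate is perturbed (seeded) up to
#' `max_restarts` times before failing with a diagnostic error.
#'
#' @param params A `nondim_params` object ([nondim_params()] or
#'   [nondimensionalize()]).
#' @param config Model configuration ([sed_config()]).
#' @param zeta Optional depth grid; defaults to the configured graded grid.
#' @return A list with `zeta`, `Sigma`, `eta`, and solver diagnostics
#'   (`residual`, `iterations`, `attempts`).
#' @examples
#' sol <- solve_bulk(nondim_params(2, 2, 10))
#' range(sol$Sigma)
#' @export
solve_bulk <- function(params, config = sed_config(), zeta = NULL) {
  sc <- config$solver
  if (is.null(zeta)) zeta <- zeta_grid(sc$n, sc$zeta_max, sc$grading)
  gp <- oc_profile_deriv(params$gamma0, params$da_star, params$a, zeta)
  pp <- fe_profile_deriv(params$psi0, params$da_star, params$chi, params$b,
                         zeta)
  src <- bulk_source(gp, pp, params$kappa_S, params$kappa_H)
  Y0 <- bulk_initial_guess(zeta, gp, pp, params$kappa_S, params$kappa_H,
                           params$eta0)
  c2 <- c(params$da_star, params$Delta * params$da_star)
  bc0 <- c(1, params$eta0)
  out <- NULL
  for (attempt in seq_len(1 + sc$max_restarts)) {
    Yi <- if (attempt == 1) {
      Y0
    } else if (attempt == 2) {
      cbind(rep(1, length(zeta)), rep(params$eta0, length(zeta)))
    } else {
      with_local_seed(1000L + attempt, {
        pmax(Y0 * matrix(stats::runif(length(Y0), 0.5, 1.5), nrow(Y0)), 0)
      })
    }
    out <- newton_bvp(zeta, c2, bc0, src, Yi,
                      tol = sc$tol, max_iter = sc$max_iter)
    if (out$converged) break
  }
  if (!out$converged) {
    stop(sprintf(
      "bulk solve failed to converge (Gamma0=%.3g, Da*=%.3g, Psi0=%.3g): residual %.3e after %d attempts",
      params$gamma0, params$da_star, params$psi0, out$residual, attempt
    ), call. = FALSE)
  }
  check_undershoot(out$Y, sc$undershoot_tol, "bulk")
  list(zeta = zeta, Sigma = out$Y[, 1], eta = out$Y[, 2],
       residual = out$residual, iterations = out$iterations,
       attempts = attempt)
}

check_undershoot <- function(Y, tol, label) {
  worst <- min(Y)
  if (worst < -1e4 * tol) {
    stop(sprintf("%s solve produced negative concentrations (min %.3e)",
                 label, worst), call. = FALSE)
  }
  invisible(worst)
}

#' Solve the isotopologue boundary-value problem
#'
#' Solves the four coupled equations for 32S/34S sulfate and sulfide, with
#' the microbial sulfate reduction rate partitioned between isotopologues by
#' `32Sigma / (alpha34 * 34Sigma + 32Sigma)` (and its 34S complement) and the
#' pyritization sink partitioned by the instantaneous sulfide isotope
#' fraction. The converged bulk solution seeds the Newton iterate; the sum of
#' the isotopologue pair reproducing the bulk field (<= 1e-6 relative) is an
#' emergent consistency check reported in the diagnostics.
#'
#' @inheritParams solve_bulk
#' @param bulk Output of [solve_bulk()] for the same parameters.
#' @return A list with `zeta`, isotopologue arrays `s32`, `s34`, `h32`,
#'   `h34`, bulk sums, and diagnostics including `sum_identity_error`.
#' @export
solve_isotopologues <- function(params, bulk, config = sed_config()) {
  sc <- config$solver
  zeta <- bulk$zeta
  gp <- oc_profile_deriv(params$gamma0, params$da_star, params$a, zeta)
  pp <- fe_profile_deriv(params$psi0, params$da_star, params$chi, params$b,
                         zeta)
  src <- iso_source(gp, pp, params$kappa_S, params$kappa_H, params$alpha34)
  R0 <- params$R_sulfate0
  x32 <- 1 / (1 + R0)
  x34 <- R0 / (1 + R0)
  # Rayleigh-style ratio estimate from the bulk drawdown seeds the iterate;
  # exact in the advective limit, harmless (R ~ R0) in the diffusive one
  R_est <- R0 * pmax(bulk$Sigma, 1e-6)^(params$alpha34 - 1)
  Rh_est <- params$alpha34 * R_est
  Y0 <- cbind(
    bulk$Sigma / (1 + R_est),
    bulk$Sigma * R_est / (1 + R_est),
    bulk$eta / (1 + Rh_est),
    bulk$eta * Rh_est / (1 + Rh_est)
  )
  if (params$eta0 > 0) {
    Rh0 <- params$R_sulfide0
    Y0[1, 3] <- params$eta0 / (1 + Rh0)
    Y0[1, 4] <- params$eta0 * Rh0 / (1 + Rh0)
  }
  c2 <- c(params$da_star, params$da_star,
          params$Delta * params$da_star, params$Delta * params$da_star)
  Rh0 <- params$R_sulfide0
  bc0 <- c(x32, x34,
           params$eta0 / (1 + Rh0), params$eta0 * Rh0 / (1 + Rh0))
  out <- NULL
  for (attempt in seq_len(1 + sc$max_restarts)) {
    Yi <- if (attempt == 1) {
      Y0
    } else {
      with_local_seed(2000L + attempt, {
        pmax(Y0 * matrix(stats::runif(length(Y0), 0.8, 1.2), nrow(Y0)), 0)
      })
    }
    out <- newton_bvp(zeta, c2, bc0, src, Yi,
                      tol = sc$tol, max_iter = sc$max_iter)
    if (out$converged) break
  }
  if (!out$converged) {
    stop(sprintf(
      "isotopologue solve failed to converge (Gamma0=%.3g, Da*=%.3g): residual %.3e",
      params$gamma0, params$da_star, out$residual
    ), call. = FALSE)
  }
  check_undershoot(out$Y, sc$undershoot_tol, "isotopologue")
  sum_S <- out$Y[, 1] + out$Y[, 2]
  sum_H <- out$Y[, 3] + out$Y[, 4]
  # relative to the non-dimensional concentration scale (all species are in
  # units of the seawater sulfate concentration): pointwise-relative is
  # ill-posed where a concentration vanishes
  err_S <- max(abs(sum_S - bulk$Sigma)) / max(1, max(bulk$Sigma))
  err_H <- max(abs(sum_H - bulk$eta)) / max(1, max(bulk$eta))
  list(zeta = zeta,
       s32 = out$Y[, 1], s34 = out$Y[, 2],
       h32 = out$Y[, 3], h34 = out$Y[, 4],
       Sigma = sum_S, eta = sum_H,
       residual = out$residual, iterations = out$iterations,
       attempts = attempt,
       sum_identity_error = max(err_S, err_H))
}

#' Integrate pyrite isotopologues down the profile
#'
#' Pyrite forms at the rate reactive iron is sulfidized:
#' `dPi/dzeta = -dPsi/dzeta * eta/(kappa_H + eta)`, split between
#' isotopologues by the instantaneous sulfide isotope fraction. The
#' right-hand side uses the analytic iron-profile derivative (never a
#' difference of `Psi`), and the cumulative profile starts at `Pi(0) = 0`.
#'
#' @inheritParams solve_bulk
#' @param iso Output of [solve_isotopologues()].
#' @return A list with `pi32`, `pi34`, `pi` (cumulative, dimensionless) and
#'   `dpi_dzeta` (bulk formation rate).
#' @export
integrate_pyrite <- function(params, iso, config = sed_config()) {
  zeta <- iso$zeta
  pp <- fe_profile_deriv(params$psi0, params$da_star, params$chi, params$b,
                         zeta)
  h32 <- pmax(iso$h32, 0)
  h34 <- pmax(iso$h34, 0)
  den <- params$kappa_H + h32 + h34
  r32 <- -pp * h32 / den
  r34 <- -pp * h34 / den
  list(
    pi32 = cumtrapz(zeta, r32),
    pi34 = cumtrapz(zeta, r34),
    pi = cumtrapz(zeta, r32 + r34),
    dpi_dzeta = r32 + r34
  )
}

#' Locate the base of the pyrite formation zone
#'
#' The formation zone ends at the first depth, at or below the peak of the
#' formation rate, where `dPi/dzeta` drops to or below the threshold `beta`.
#' If the rate never falls below the threshold the domain cap is returned; if
#' no pyrite forms at all, `zeta_max = 0`. The rate is the analytic
#' right-hand side of the pyrite equation, not a difference of `Pi`.
#'
#' @param zeta Depth grid.
#' @param dpi_dzeta Formation rate on the grid.
#' @param beta Threshold (> 0; default from the config, 5e-4).
#' @return `zeta_max`, a scalar depth.
#' @export
find_zeta_max <- function(zeta, dpi_dzeta, beta = 5e-4) {
  stopifnot(length(zeta) > 0, length(zeta) == length(dpi_dzeta), beta > 0)
  if (all(dpi_dzeta <= 0)) return(0)
  imax <- which.max(dpi_dzeta)
  idx <- which(dpi_dzeta <= beta & seq_along(zeta) >= imax)
  if (length(idx) == 0) return(zeta[length(zeta)])
  zeta[idx[1]]
}

#' Convert isotopologue profiles to delta notation
#'
#' `delta34S = (R / R_VCDT - 1) * 1000` with `R` the 34S/32S ratio of the
#' species at each depth. Pyrite uses the cumulative buried ratio
#' `34Pi / 32Pi` (NA where no pyrite has yet formed).
#'
#' @param iso Output of [solve_isotopologues()].
#' @param pyr Output of [integrate_pyrite()].
#' @param config Model configuration (VCDT ratio).
#' @return A tibble with `zeta`, `d34S_sulfate`, `d34S_sulfide`,
#'   `d34S_pyrite` (permil VCDT).
#' @export
delta_curves <- function(iso, pyr, config = sed_config()) {
  R_V <- config$constants$R_VCDT
  to_delta <- function(x34, x32) {
    ok <- x32 > 1e-300
    out <- rep(NA_real_, length(x32))
    out[ok] <- (x34[ok] / x32[ok] / R_V - 1) * 1000
    out
  }
  tibble::tibble(
    zeta = iso$zeta,
    d34S_sulfate = to_delta(iso$s34, iso$s32),
    d34S_sulfide = to_delta(iso$h34, iso$h32),
    d34S_pyrite = to_delta(pyr$pi34, pmax(pyr$pi32, 0))
  )
}

#' Solve the full pyrite diagenesis problem for one parameter set
#'
#' Runs the staged pipeline: bulk solve, isotopologue solve, pyrite
#' integration, formation-zone base, and delta-34S curves. This is the main
#' per-site computation; [solve_site()] wraps it for dimensional records.
#'
#' @inheritParams solve_bulk
#' @return An object of class `pyrite_profile`: a list with a `profile`
#'   tibble (depth grid and every species), `params`, `zeta_max`,
#'   `delta_pyrite` (permil; seawater sulfate minus buried pyrite at
#'   `zeta_max`), `pi_integral` (non-dimensional pyrite content integrated
#'   over the formation zone) and solver `diagnostics`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' fit <- solve_profile(nondim_params(3.9, 3.7, 10))
#' glance(fit)
#' }
#' @export
solve_profile <- function(params, config = sed_config(), zeta = NULL) {
  stopifnot(inherits(params, "nondim_params"))
  bulk <- solve_bulk(params, config, zeta)
  iso <- solve_isotopologues(params, bulk, config)
  pyr <- integrate_pyrite(params, iso, config)
  deltas <- delta_curves(iso, pyr, config)
  zmax <- find_zeta_max(iso$zeta, pyr$dpi_dzeta, config$solver$beta)
  R_V <- config$constants$R_VCDT
  d34S_sw <- (params$R_sulfate0 / R_V - 1) * 1000

  izmax <- which.min(abs(iso$zeta - zmax))
  d34S_pyr_buried <- deltas$d34S_pyrite[izmax]
  delta_pyrite <- if (is.na(d34S_pyr_buried)) NA_real_ else
    d34S_sw - d34S_pyr_buried
  in_zone <- iso$zeta <= zmax
  pi_integral <- if (sum(in_zone) >= 2) {
    utils::tail(cumtrapz(iso$zeta[in_zone], pyr$pi[in_zone]), 1)
  } else {
    0
  }

  profile <- tibble::tibble(
    zeta = iso$zeta,
    gamma = params$gamma0 *
      (params$a / (params$a + params$da_star * iso$zeta))^params$a,
    psi = params$psi0 *
      (params$b / (params$b + params$chi * params$da_star * iso$zeta))^params$b,
    sigma = bulk$Sigma,
    eta = bulk$eta,
    s32 = iso$s32, s34 = iso$s34, h32 = iso$h32, h34 = iso$h34,
    pi32 = pyr$pi32, pi34 = pyr$pi34, pi = pyr$pi,
    dpi_dzeta = pyr$dpi_dzeta,
    d34S_sulfate = deltas$d34S_sulfate,
    d34S_sulfide = deltas$d34S_sulfide,
    d34S_pyrite = deltas$d34S_pyrite
  )
  structure(
    list(
      profile = profile,
      params = params,
      zeta_max = zmax,
      d34S_sulfate_sw = d34S_sw,
      d34S_pyrite_buried = d34S_pyr_buried,
      delta_pyrite = delta_pyrite,
      pi_integral = pi_integral,
      diagnostics = list(
        bulk_residual = bulk$residual,
        iso_residual = iso$residual,
        bulk_iterations = bulk$iterations,
        iso_iterations = iso$iterations,
        attempts = c(bulk = bulk$attempts, iso = iso$attempts),
        sum_identity_error = iso$sum_identity_error,
        mesh_size = length(iso$zeta)
      ),
      config_hash = config_hash(config)
    ),
    class = "pyrite_profile"
  )
}

#' Sulfur mass balance of a converged solution
#'
#' Total sulfur produced by microbial sulfate reduction must leave as
#' diffusive sulfide efflux across the sediment-water interface, advective
#' sulfide burial at the bottom of the domain, or pyrite burial. The budget
#' is assembled from the same discretization as the solver and its relative
#' closure error is a solver-quality diagnostic (<= 0.5 % for converged
#' solutions on the default mesh).
#'
#' @param fit A `pyrite_profile` object.
#' @return A one-row tibble with the non-dimensional flux terms and the
#'   relative `closure_error`.
#' @export
sulfur_balance <- function(fit) {
  pr <- fit$profile
  p <- fit$params
  zeta <- pr$zeta
  gp <- oc_profile_deriv(p$gamma0, p$da_star, p$a, zeta)
  msr <- -gp * pr$sigma / (p$kappa_S + pr$sigma) * (pr$sigma > 0)
  production <- utils::tail(cumtrapz(zeta, msr), 1)
  efflux <- p$Delta * p$da_star * top_gradient(zeta, pr$eta)
  advective <- pr$eta[length(zeta)] - p$eta0
  pyrite <- pr$pi[length(zeta)]
  closure <- if (production > 0) {
    abs(production - (efflux + advective + pyrite)) / production
  } else {
    0
  }
  tibble::tibble(
    msr_production = production,
    diffusive_efflux = efflux,
    advective_burial = advective,
    pyrite_burial = pyrite,
    closure_error = closure
  )
}

#' @export
print.pyrite_profile <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<pyrite_profile> Gamma0 = %.3g, Da* = %.3g, Psi0 = %.3g\n",
    p$gamma0, p$da_star, p$psi0
  ))
  cat(sprintf(
    "  zeta_max = %.3f, Delta_pyrite = %s permil, integral(Pi) = %.4g\n",
    x$zeta_max,
    ifelse(is.na(x$delta_pyrite), "NA", sprintf("%.1f", x$delta_pyrite)),
    x$pi_integral
  ))
  cat(sprintf("  residuals: bulk %.2e, iso %.2e; identity error %.2e\n",
              x$diagnostics$bulk_residual, x$diagnostics$iso_residual,
              x$diagnostics$sum_identity_error))
  invisible(x)
}
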