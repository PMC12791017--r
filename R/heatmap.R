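#' Parameter-space heat map of pyrite content and isotopic composition
#'
#' Solves the model on a log-spaced grid of the two governing variables
#' (OC-to-sulfate ratio and modified Damkohler number) at fixed reactive-
#' iron delivery, and records the integrated non-dimensional pyrite content
#' over the formation zone and the paired isotopic offset `Delta_pyrite`.
#' Typical choices are `psi0 = 10` (global-average iron delivery) and
#' `psi0 = 1` (low-iron endmember). Failed nodes are flagged, never
#' interpolated for inversion.
#'
#' @param gamma0 Vector of OC-to-sulfate ratios (log-spaced recommended).
#' @param da_star Vector of Damkohler numbers.
#' @param psi0 Reactive-iron delivery (scalar).
#' @param config Model configuration.
#' @return A `pyrite_heatmap` tibble with columns `gamma0`, `da_star`,
#'   `psi0`, `pi_integral`, `delta_pyrite`, `zeta_max`, `converged`.
#' @examples
#' \donttest{
#' hm <- pyrite_heatmap(gamma0 = c(1, 10), da_star = c(1, 10), psi0 = 10)
#' }
#' @export
pyrite_heatmap <- function(gamma0 = 10^seq(-1, 2, length.out = 21),
                           da_star = 10^seq(-1, 2, length.out = 21),
                           psi0 = 10, config = sed_config()) {
  nodes <- tidyr::expand_grid(gamma0 = gamma0, da_star = da_star)
  out <- purrr::pmap_dfr(nodes, function(gamma0, da_star) {
    fit <- tryCatch(
      solve_profile(nondim_params(gamma0, da_star, psi0, config = config),
                    config),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      tibble::tibble(gamma0 = gamma0, da_star = da_star, psi0 = psi0,
                     pi_integral = NA_real_, delta_pyrite = NA_real_,
                     zeta_max = NA_real_, converged = FALSE)
    } else {
      tibble::tibble(gamma0 = gamma0, da_star = da_star, psi0 = psi0,
                     pi_integral = fit$pi_integral,
                     delta_pyrite = fit$delta_pyrite,
                     zeta_max = fit$zeta_max, converged = TRUE)
    }
  })
  class(out) <- c("pyrite_heatmap", class(out))
  out
}

#' Invert a Delta-pyrite range onto the permissible parameter-space region
#'
#' Given a heat map and an observed `Delta_pyrite` interval (for example a
#' bootstrapped 5th-95th percentile range for a geologic period), flags the
#' nodes whose modelled value falls inside the interval. The associated
#' integrated pyrite content range is reported; because iron delivery in the
#' past was likely higher than assumed, those content values are minimum
#' estimates.
#'
#' @param heatmap A `pyrite_heatmap`.
#' @param delta_range Length-2 numeric, permil (lo, hi).
#' @return A list with `region` (the heat map plus an `in_region` flag),
#'   `n_nodes` (number of permissible nodes), `pi_range`,
#'   `gamma0_centroid`, `da_star_centroid` (log-space centroids; NA when
#'   the region is empty) and `empty`.
#' @export
invert_permissible_region <- function(heatmap, delta_range) {
  stopifnot(length(delta_range) == 2, delta_range[1] <= delta_range[2])
  hm <- dplyr::mutate(
    heatmap,
    in_region = .data$converged &
      .data$delta_pyrite >= delta_range[1] &
      .data$delta_pyrite <= delta_range[2]
  )
  sel <- dplyr::filter(hm, .data$in_region)
  if (nrow(sel) == 0) {
    return(list(region = hm, n_nodes = 0L, pi_range = c(NA_real_, NA_real_),
                gamma0_centroid = NA_real_, da_star_centroid = NA_real_,
                empty = TRUE))
  }
  list(
    region = hm,
    n_nodes = nrow(sel),
    pi_range = range(sel$pi_integral),
    gamma0_centroid = exp(mean(log(sel$gamma0))),
    da_star_centroid = exp(mean(log(sel$da_star))),
    empty = FALSE
  )
}
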