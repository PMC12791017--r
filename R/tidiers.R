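#' Tidy a solved profile into long format
#'
#' @param x A `pyrite_profile`.
#' @param ... Unused.
#' @return A tibble with `zeta`, `species`, `value`, where species covers
#'   the non-dimensional contents/concentrations and the delta-34S curves.
#' @export
tidy.pyrite_profile <- function(x, ...) {
  x$profile %>%
    dplyr::select("zeta", "gamma", "psi", "sigma", "eta", "pi",
                  "d34S_sulfate", "d34S_sulfide", "d34S_pyrite") %>%
    tidyr::pivot_longer(-"zeta", names_to = "species", values_to = "value")
}

#' One-row summary of a solved profile
#'
#' @param x A `pyrite_profile`.
#' @param ... Unused.
#' @return A one-row tibble: governing parameters, `zeta_max`,
#'   `delta_pyrite`, `pi_integral`, solver residuals and the isotopologue
#'   sum-identity error.
#' @export
glance.pyrite_profile <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    gamma0 = p$gamma0,
    da_star = p$da_star,
    psi0 = p$psi0,
    eta0 = p$eta0,
    alpha34 = p$alpha34,
    zeta_max = x$zeta_max,
    delta_pyrite = x$delta_pyrite,
    d34S_pyrite_buried = x$d34S_pyrite_buried,
    pi_integral = x$pi_integral,
    bulk_residual = x$diagnostics$bulk_residual,
    iso_residual = x$diagnostics$iso_residual,
    sum_identity_error = x$diagnostics$sum_identity_error
  )
}

#' @export
tidy.pyrite_global <- function(x, ...) tibble::as_tibble(x$cells)

#' @export
glance.pyrite_global <- function(x, ...) x$totals

#' Plot a solved profile
#'
#' Two-panel depth plot: non-dimensional contents/concentrations and
#' delta-34S curves, depth increasing downwards.
#'
#' @param object A `pyrite_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pyrite_profile <- function(object, ...) {
  td <- tidy(object) %>%
    dplyr::mutate(panel = ifelse(grepl("^d34S", .data$species),
                                 "delta34S (permil)", "non-dimensional"))
  ggplot(td, aes(x = .data$value, y = .data$zeta,
                 colour = .data$species)) +
    geom_path(na.rm = TRUE) +
    geom_hline(yintercept = object$zeta_max, linetype = 2,
               colour = "grey40") +
    scale_y_reverse() +
    facet_wrap(~panel, scales = "free_x") +
    labs(x = NULL, y = "non-dimensional depth") +
    theme_minimal()
}

#' Plot a parameter-space heat map
#'
#' @param object A `pyrite_heatmap`.
#' @param fill `"delta_pyrite"` (default) or `"pi_integral"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pyrite_heatmap <- function(object, fill = "delta_pyrite", ...) {
  ggplot(object, aes(x = .data$gamma0, y = .data$da_star,
                     fill = .data[[fill]])) +
    geom_raster() +
    scale_x_log10() +
    scale_y_log10() +
    scale_fill_viridis_c(na.value = "grey80") +
    labs(x = expression(Gamma[0]), y = expression(Da^"*"), fill = fill) +
    theme_minimal()
}

#' Plot a Delta-pyrite record with its bootstrap band
#'
#' @param object A `delta_pyrite_band`.
#' @param ... Unused.
#' @return A ggplot object (age axis reversed, oldest on the left).
#' @export
autoplot.delta_pyrite_band <- function(object, ...) {
  ggplot(object, aes(x = .data$age)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "steelblue", alpha = 0.3, na.rm = TRUE) +
    geom_line(aes(y = .data$smoothed), colour = "steelblue",
              linewidth = 1, na.rm = TRUE) +
    scale_x_reverse() +
    labs(x = "age (Ma)", y = expression(Delta[pyrite] ~ "(permil)")) +
    theme_minimal()
}

#' Plot global burial maps by cell
#'
#' Burial flux per cell against water depth, coloured by regime: a compact
#' visual of where pyrite burial concentrates.
#'
#' @param object A `pyrite_global`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pyrite_global <- function(object, ...) {
  ok <- dplyr::filter(object$cells, is.finite(.data$J_S_mol_yr))
  ggplot(ok, aes(x = .data$water_depth, y = .data$J_S_mol_yr,
                 colour = .data$regime)) +
    geom_point(alpha = 0.5) +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "water depth (mbsl)", y = "burial flux (mol S/yr per cell)") +
    theme_minimal()
}
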