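#' LOESS smoothing of a geologic isotope series
#'
#' Local quadratic regression with tricube weights over a stated fraction
#' of the data (the classic LOESS smoother), as used to trace long-term
#' trends through scattered delta-34S compilations: span 0.2 for sulfate
#' records, 0.5 for pyrite records.
#'
#' @param series Tibble with columns `age` (Ma) and `value` (permil).
#' @param span Fraction of points used in each local fit (0-1].
#' @param degree Local polynomial degree (default 2).
#' @return The input tibble, sorted by age, with a `smoothed` column.
#' @export
loess_smooth <- function(series, span, degree = 2) {
  stopifnot(all(c("age", "value") %in% names(series)), span > 0, span <= 1)
  series <- dplyr::arrange(series, .data$age)
  n <- nrow(series)
  if (n < max(5, ceiling(span * n))) {
    stop("insufficient data for LOESS smoothing", call. = FALSE)
  }
  # duplicate ages (routine in bootstrap resamples) make some local fits
  # rank-deficient; loess falls back to a pseudoinverse, which is fine here
  fit <- suppressWarnings(
    stats::loess(value ~ age, data = series, span = span,
                 degree = degree, family = "gaussian",
                 surface = "direct")
  )
  dplyr::mutate(series,
                smoothed = suppressWarnings(stats::predict(fit, series$age)))
}

#' Paired isotopic offset series
#'
#' Linearly interpolates a smoothed seawater-sulfate delta-34S curve to the
#' age of each pyrite measurement and forms
#' `Delta_pyrite = d34S_sulfate - d34S_pyrite`. Pyrite ages outside the
#' sulfate record's range are excluded and counted.
#'
#' @param pyrite Tibble with `age`, `value` (pyrite delta-34S, permil).
#' @param sulfate_smoothed Tibble with `age`, `smoothed` (from
#'   [loess_smooth()]).
#' @return A tibble with `age`, `d34S_pyrite`, `d34S_sulfate`,
#'   `delta_pyrite`, plus an attribute `n_excluded`.
#' @export
delta_series <- function(pyrite, sulfate_smoothed) {
  rng <- range(sulfate_smoothed$age)
  inside <- pyrite$age >= rng[1] & pyrite$age <= rng[2]
  interp <- stats::approx(sulfate_smoothed$age, sulfate_smoothed$smoothed,
                          xout = pyrite$age[inside], ties = mean)$y
  out <- tibble::tibble(
    age = pyrite$age[inside],
    d34S_pyrite = pyrite$value[inside],
    d34S_sulfate = interp,
    delta_pyrite = interp - pyrite$value[inside]
  )
  attr(out, "n_excluded") <- sum(!inside)
  out
}

#' Bootstrap confidence band for the Delta-pyrite record
#'
#' Repeats the smoothing pipeline on resampled data: in each iteration both
#' series are resampled with replacement (individual measurements as the
#' resampling unit), the sulfate record is LOESS-smoothed (span
#' `span_sulfate`), interpolated to the resampled pyrite ages,
#' `Delta_pyrite` is formed and smoothed (span `span_pyrite`) onto a common
#' age grid. Pointwise percentiles of the iterations give the band.
#'
#' @param pyrite,sulfate Tibbles with `age`, `value` (permil).
#' @param n_boot Number of bootstrap iterations (1000 for production
#'   figures; smaller for quick checks).
#' @param seed Integer seed (band is reproducible given the seed).
#' @param span_sulfate,span_pyrite LOESS spans (defaults 0.2 and 0.5).
#' @param age_grid Ages (Ma) at which the band is evaluated; default 100
#'   points over the overlap.
#' @param probs Lower/upper percentiles (default 5th and 95th).
#' @return A `delta_pyrite_band` tibble: `age`, `smoothed` (central
#'   estimate from the full data), `lower`, `upper`, with attributes
#'   `n_boot` and `seed`.
#' @export
bootstrap_band <- function(pyrite, sulfate, n_boot = 1000, seed = 1,
                           span_sulfate = 0.2, span_pyrite = 0.5,
                           age_grid = NULL, probs = c(0.05, 0.95)) {
  pipeline <- function(py, su, grid) {
    su_s <- loess_smooth(su, span_sulfate)
    ds <- delta_series(py, su_s)
    if (nrow(ds) < 10) return(rep(NA_real_, length(grid)))
    sm <- loess_smooth(
      tibble::tibble(age = ds$age, value = ds$delta_pyrite), span_pyrite
    )
    stats::approx(sm$age, sm$smoothed, xout = grid, ties = mean)$y
  }
  overlap <- c(max(min(pyrite$age), min(sulfate$age)),
               min(max(pyrite$age), max(sulfate$age)))
  age_grid <- age_grid %||% seq(overlap[1], overlap[2], length.out = 100)
  central <- pipeline(pyrite, sulfate, age_grid)
  draws <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      py <- pyrite[sample.int(nrow(pyrite), replace = TRUE), ]
      su <- sulfate[sample.int(nrow(sulfate), replace = TRUE), ]
      tryCatch(pipeline(py, su, age_grid),
               error = function(e) rep(NA_real_, length(age_grid)))
    }, numeric(length(age_grid)))
  })
  qs <- apply(draws, 1, stats::quantile, probs = probs, na.rm = TRUE)
  out <- tibble::tibble(
    age = age_grid,
    smoothed = central,
    lower = qs[1, ],
    upper = qs[2, ]
  )
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  class(out) <- c("delta_pyrite_band", class(out))
  out
}

#' Synthetic geologic isotope records with a known offset history
#'
#' Generates paired pyrite and seawater-sulfate delta-34S series for
#' pipeline tests: a smooth sulfate curve, a prescribed `Delta_pyrite(t)`
#' signal, and Gaussian measurement scatter matching the dispersion of
#' compiled records (pyrite scatter is large, about 10-15 permil).
#'
#' @param seed Integer seed.
#' @param n_pyrite,n_sulfate Number of measurements.
#' @param age_range Ages in Ma (default Phanerozoic, 0-540).
#' @param sd_pyrite,sd_sulfate Measurement scatter (permil).
#' @param delta_fun Function of age returning the true offset (permil);
#'   default a slow oscillation between ~15 and ~55.
#' @return A list with `pyrite`, `sulfate` (tibbles: `age`, `value`,
#'   `species`) and `truth` (tibble: `age`, `delta_pyrite`).
#' @export
synth_isotope_record <- function(seed, n_pyrite = 400, n_sulfate = 200,
                                 age_range = c(0, 540),
                                 sd_pyrite = 12, sd_sulfate = 2,
                                 delta_fun = NULL) {
  delta_fun <- delta_fun %||%
    function(age) 35 + 20 * sin(2 * pi * age / 400)
  sulfate_fun <- function(age) 22 + 8 * cos(2 * pi * age / 500)
  with_local_seed(seed, {
    age_p <- sort(runif(n_pyrite, age_range[1], age_range[2]))
    age_s <- sort(runif(n_sulfate, age_range[1], age_range[2]))
    list(
      pyrite = tibble::tibble(
        age = age_p,
        value = sulfate_fun(age_p) - delta_fun(age_p) +
          rnorm(n_pyrite, 0, sd_pyrite),
        species = "pyrite"
      ),
      sulfate = tibble::tibble(
        age = age_s,
        value = sulfate_fun(age_s) + rnorm(n_sulfate, 0, sd_sulfate),
        species = "sulfate"
      ),
      truth = tibble::tibble(
        age = seq(age_range[1], age_range[2], length.out = 200),
        delta_pyrite = delta_fun(seq(age_range[1], age_range[2],
                                     length.out = 200))
      )
    )
  })
}

#' Read an isotope-series table
#'
#' CSV with columns `age_Ma`, `d34S_permil`, `species` and optionally
#' `source`; rows flagged `source == "CAS"` (carbonate-associated sulfate,
#' often diagenetically altered) are excluded from sulfate records.
#'
#' @param path CSV path.
#' @param exclude_cas Drop CAS-derived sulfate values (default TRUE).
#' @return A tibble with `age`, `value`, `species`, `source`.
#' @export
read_isotope_series <- function(path, exclude_cas = TRUE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble::tibble(
    age = df$age_Ma,
    value = df$d34S_permil,
    species = df$species,
    source = if ("source" %in% names(df)) df$source else NA_character_
  )
  if (exclude_cas) {
    out <- dplyr::filter(
      out,
      !(.data$species == "sulfate" & !is.na(.data$source) &
          .data$source == "CAS")
    )
  }
  out
}
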