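#' Read a site-conditions table
#'
#' One row per site; column names match the site-record fields
#' ([example_site()]). Minimal validation of the physical invariants is
#' applied (porosity in (0,1), positive sedimentation rate and sulfate).
#'
#' @param path CSV or TSV path.
#' @return A tibble of site records.
#' @export
read_site_table <- function(path) {
  df <- if (grepl("\\.tsv$", path)) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  required <- c("porosity", "solid_density", "sed_rate", "oc_swi", "fe_swi")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("site table lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_porosity(df$porosity)
  if (any(df$sed_rate <= 0)) stop("sed_rate must be > 0", call. = FALSE)
  if ("sulfate" %in% names(df) && any(df$sulfate <= 0)) {
    stop("sulfate must be > 0", call. = FALSE)
  }
  df
}

#' Write profile and grid results
#'
#' `write_profile_csv()` writes a solved profile in tidy long format
#' (`zeta`, `species`, `value`); `write_global_csv()` writes per-cell
#' burial results; `write_summary_json()` writes a provenance-stamped JSON
#' summary (config hash included) for any result object with a `glance()`
#' method.
#'
#' @param fit A `pyrite_profile` / `pyrite_global`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(fit, path) {
  readr::write_csv(tidy(fit), path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
write_global_csv <- function(fit, path) {
  readr::write_csv(fit$cells, path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
write_summary_json <- function(fit, path) {
  summary <- as.list(glance(fit))
  summary$config_hash <- fit$config_hash
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a long-format boundary-condition grid
#'
#' Reads a grid exported by [synthesize_grid()] (or an external grid in the
#' same long CSV dialect) with an optional column mapping for foreign
#' layouts.
#'
#' @param path CSV path.
#' @param mapping Optional named character vector, `c(internal = "foreign")`,
#'   renaming foreign columns onto the internal schema.
#' @return A grid tibble.
#' @export
read_grid_csv <- function(path, mapping = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(mapping)) {
    df <- dplyr::rename(df, !!!setNames(unname(mapping), names(mapping)))
  }
  if (!"mask" %in% names(df)) df$mask <- "active"
  if (!"cell_id" %in% names(df)) df$cell_id <- seq_len(nrow(df))
  df
}
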