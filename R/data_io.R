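#' Convert aboveground biomass to aboveground carbon
#'
#' Applies the default biomass-to-carbon conversion factor of 0.47 used for
#' aboveground live tree biomass, so that compilations mixing biomass and
#' carbon measurements can be placed on a common Mg C ha^-1 scale.
#'
#' @param biomass Numeric vector of aboveground biomass (Mg ha^-1). Must be
#'   non-negative; `NA` values pass through.
#' @return Numeric vector of aboveground carbon (Mg C ha^-1).
#' @examples
#' biomass_to_carbon(100) # 47
#' @export
biomass_to_carbon <- function(biomass) {
  if (!is.numeric(biomass)) {
    abort("`biomass` must be numeric.")
  }
  if (any(biomass < 0, na.rm = TRUE)) {
    abort("`biomass` must be non-negative.")
  }
  biomass * 0.47
}

#' Validate a compilation of treatment-control comparisons
#'
#' Checks that a compilation table satisfies the schema invariants: known
#' treatment labels, strictly positive arm means, non-negative standard
#' deviations, replicate counts of at least one, recognized unit flags, and
#' soil moisture regimes drawn from the four USDA classes. Treatment-specific
#' fields (for example `intercrop_genus`) may only be populated for their
#' treatment.
#'
#' @param data A data frame with the compilation columns (see
#'   [read_compilation()] for the schema).
#' @return `data` (as a tibble), invisibly, if validation passes. Otherwise an
#'   error listing every offending row is raised.
#' @seealso [validation_report()] for the issue table without the error.
#' @export
validate_compilation <- function(data) {
  issues <- validation_report(data)
  if (nrow(issues) > 0) {
    msgs <- sprintf("row %s: %s", issues$row, issues$problem)
    abort(c("Compilation failed validation.", setNames(head(msgs, 20), rep("x", length(head(msgs, 20))))))
  }
  invisible(tibble::as_tibble(data))
}

#' Tabulate validation problems in a compilation
#'
#' @inheritParams validate_compilation
#' @return A tibble with columns `row`, `column`, and `problem`; zero rows
#'   when the compilation is valid. Suitable for JSON export with
#'   [jsonlite::write_json()].
#' @export
validation_report <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.")
  }
  missing_cols <- setdiff(
    c("study_id", "treatment", "mean_treat", "mean_ctrl",
      "sd_treat", "sd_ctrl", "n_treat", "n_ctrl"),
    names(data)
  )
  if (length(missing_cols) > 0) {
    abort(paste0("Compilation is missing required columns: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  issues <- list()
  flag <- function(rows, column, problem) {
    if (length(rows) > 0) {
      issues[[length(issues) + 1]] <<-
        tibble::tibble(row = rows, column = column, problem = problem)
    }
  }

  flag(which(!data$treatment %in% treatment_levels), "treatment",
       "unknown treatment label")
  flag(which(!is.finite(data$mean_treat) | data$mean_treat <= 0),
       "mean_treat", "treatment mean must be finite and > 0")
  flag(which(!is.finite(data$mean_ctrl) | data$mean_ctrl <= 0),
       "mean_ctrl", "control mean must be finite and > 0")
  flag(which(data$sd_treat < 0), "sd_treat", "negative standard deviation")
  flag(which(data$sd_ctrl < 0), "sd_ctrl", "negative standard deviation")
  flag(which(!is.finite(data$n_treat) | data$n_treat < 1),
       "n_treat", "replicate count must be >= 1")
  flag(which(!is.finite(data$n_ctrl) | data$n_ctrl < 1),
       "n_ctrl", "replicate count must be >= 1")
  if ("unit" %in% names(data)) {
    flag(which(!data$unit %in% c("biomass", "carbon")), "unit",
         "unit must be 'biomass' or 'carbon'")
  }
  if ("soil_moisture_regime" %in% names(data)) {
    bad <- which(!is.na(data$soil_moisture_regime) &
                   !data$soil_moisture_regime %in% soil_moisture_levels)
    flag(bad, "soil_moisture_regime",
         paste0("soil moisture regime must be one of: ",
                paste(soil_moisture_levels, collapse = ", ")))
  }
  if ("intercrop_genus" %in% names(data)) {
    flag(which(!is.na(data$intercrop_genus) & data$treatment != "interplant"),
         "intercrop_genus", "intercrop genus populated for a non-interplant row")
  }
  if ("n_applied_unit" %in% names(data)) {
    flag(which(!is.na(data$n_applied_unit) &
                 !data$n_applied_unit %in% c("kg_per_ha", "kg_per_tree")),
         "n_applied_unit", "unit must be 'kg_per_ha' or 'kg_per_tree'")
  }
  if (length(issues) == 0) {
    return(tibble::tibble(row = integer(), column = character(),
                          problem = character()))
  }
  dplyr::arrange(dplyr::bind_rows(issues), .data$row)
}

#' Read a compilation of treatment-control comparisons from CSV
#'
#' Reads the flat interchange table (one row per treatment-control
#' comparison), validates it, and converts any rows measured as aboveground
#' biomass to aboveground carbon via [biomass_to_carbon()] (applied to the
#' arm means and standard deviations; the `unit` flag is then set to
#' `"carbon"` so the conversion can never be applied twice). Missing standard
#' deviations are encoded as empty cells, never 0 - a 0 is a legal SD.
#'
#' @param path Path to a CSV file whose header contains at least `study_id`,
#'   `treatment` (`interplant`, `npk`, or `thin`), `mean_treat`, `mean_ctrl`,
#'   `sd_treat`, `sd_ctrl`, `n_treat`, `n_ctrl`, plus optional `site_id`,
#'   `control_id`, `unit` (`biomass`/`carbon`), moderator columns, and
#'   nitrogen-application columns (`n_applied`, `n_applied_unit`,
#'   `stand_density`).
#' @param convert_units If `TRUE` (default), rows flagged `unit = "biomass"`
#'   are converted to carbon.
#' @return A validated tibble on the carbon scale.
#' @export
read_compilation <- function(path, convert_units = TRUE) {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      study_id = readr::col_character(),
      site_id = readr::col_character(),
      treatment = readr::col_character(),
      unit = readr::col_character(),
      control_id = readr::col_character(),
      tree_genus = readr::col_character(),
      intercrop_genus = readr::col_character(),
      prev_land_use = readr::col_character(),
      soil_moisture_regime = readr::col_character(),
      wood_type = readr::col_character(),
      experimental_design = readr::col_character(),
      application_method = readr::col_character(),
      n_applied_unit = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", "NA"),
    show_col_types = FALSE
  )
  problems <- readr::problems(data)
  if (nrow(problems) > 0) {
    abort(c("Malformed values in compilation CSV.",
            setNames(sprintf("row %d, column %d: expected %s",
                             problems$row, problems$col, problems$expected),
                     rep("x", nrow(problems)))))
  }
  validate_compilation(data)
  if (convert_units && "unit" %in% names(data)) {
    data <- convert_compilation_units(data)
  }
  data
}

#' Convert biomass rows of a compilation to carbon
#'
#' @param data A compilation tibble with a `unit` column.
#' @return The tibble with biomass rows converted and `unit` set to
#'   `"carbon"` everywhere.
#' @export
convert_compilation_units <- function(data) {
  if (!"unit" %in% names(data)) {
    return(data)
  }
  is_biomass <- !is.na(data$unit) & data$unit == "biomass"
  for (col in intersect(c("mean_treat", "mean_ctrl", "sd_treat", "sd_ctrl"),
                        names(data))) {
    data[[col]][is_biomass] <- biomass_to_carbon(data[[col]][is_biomass])
  }
  data$unit[is_biomass] <- "carbon"
  data
}

#' Write a compilation to CSV
#'
#' Writes the interchange CSV with missing values as empty cells, so that
#' `read_compilation(write_compilation(x))` round-trips every field.
#'
#' @param data A compilation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compilation <- function(data, path) {
  ordered <- c(intersect(compilation_columns, names(data)),
               setdiff(names(data), compilation_columns))
  readr::write_csv(data[ordered], path, na = "")
  invisible(path)
}

#' Group comparisons that share a control plot
#'
#' Several treatment arms within one study are often compared against the
#' same control value (for example, multiple thinning intensities against a
#' single unthinned stand). This groups rows by `control_id` for diagnostics;
#' no covariance adjustment is derived from the grouping - the non-independence
#' is handled in the models through publication-level random effects.
#'
#' @param data A compilation tibble with a `control_id` column.
#' @return A tibble with one row per control group: `control_id`,
#'   `n_comparisons`, and a `records` list-column of the grouped rows.
#' @export
group_shared_controls <- function(data) {
  if (nrow(data) == 0) {
    return(tibble::tibble(control_id = character(), n_comparisons = integer(),
                          records = list()))
  }
  if (!"control_id" %in% names(data)) {
    abort("`data` has no `control_id` column.")
  }
  data |>
    dplyr::group_by(.data$control_id) |>
    tidyr::nest(records = !"control_id") |>
    dplyr::ungroup() |>
    dplyr::mutate(n_comparisons = vapply(.data$records, nrow, integer(1))) |>
    dplyr::select("control_id", "n_comparisons", "records")
}
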