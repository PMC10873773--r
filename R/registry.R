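#' Read a trauma-registry encounter table
#'
#' Reads a flat table with one row per pediatric trauma encounter from CSV
#' (RFC 4180) or Parquet, renames columns to the canonical encounter schema,
#' and coerces each field to its expected type. Values that cannot be parsed
#' as numbers (e.g. `"abc"` in a vital-sign column) become missing, with one
#' warning per affected column; empty strings and `NA` are missing without a
#' warning. Row order is preserved.
#'
#' The canonical columns are `encounter_id`, `age_years`, `weight_kg`,
#' `heart_rate`, `resp_rate`, `sbp`, `gcs`, `iss`, the exclusion flags
#' `ohca`, `mech_vent_at_arrival`, `interfacility_transfer`, and the outcome
#' components `blood_product_within_4h`, `ed_to_or_within_90min`,
#' `ed_to_interventional_radiology`, `icu_days`, `ventilator_days`,
#' `death_within_60h`, `in_hospital_death`,
#' `emergent_intervention_within_6h`. Only `age_years` is mandatory; absent
#' columns are filled with `NA`.
#'
#' @param path Path to a `.csv` or `.parquet` file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the column names used in the file, e.g.
#'   `c(age_years = "AGE", sbp = "SBPED")`. Unmapped canonical names are
#'   looked up verbatim.
#' @return A tibble of encounters with the canonical columns.
#' @seealso [write_registry()], [apply_exclusions()]
#' @export
read_registry <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("registry file not found: ", path), class = "pv_io_error")
  }
  raw <- if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("reading parquet requires the 'arrow' package",
            class = "pv_io_error")
    }
    tibble::as_tibble(arrow::read_parquet(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  as_registry(raw, schema = schema)
}

#' Coerce a data frame to the canonical encounter schema
#'
#' @param data A data frame with one row per encounter.
#' @inheritParams read_registry
#' @return A tibble of encounters with the canonical columns.
#' @export
as_registry <- function(data, schema = NULL) {
  data <- tibble::as_tibble(data)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), pv_encounter_cols)
    if (length(bad) > 0) {
      abort(paste0("schema maps unknown field(s): ",
                   paste(bad, collapse = ", ")),
            class = "pv_schema_error")
    }
    missing_src <- setdiff(unname(schema), names(data))
    if (length(missing_src) > 0) {
      abort(paste0("mapped column(s) absent from input: ",
                   paste(missing_src, collapse = ", ")),
            class = "pv_schema_error")
    }
    data <- dplyr::rename(data, !!!setNames(unname(schema), names(schema)))
  }
  if (!"age_years" %in% names(data)) {
    abort("mandatory column missing: age_years", class = "pv_schema_error")
  }

  numeric_cols <- c("age_years", "weight_kg", pv_vital_cols, "gcs", "iss",
                    "icu_days", "ventilator_days")
  logical_cols <- c(pv_flag_cols, setdiff(pv_outcome_cols,
                                          c("icu_days", "ventilator_days")))

  out <- data
  if (!"encounter_id" %in% names(out)) {
    out$encounter_id <- sprintf("E%06d", seq_len(nrow(out)))
  }
  out$encounter_id <- as.character(out$encounter_id)
  for (col in numeric_cols) {
    out[[col]] <- pv_parse_numeric(
      if (col %in% names(out)) out[[col]] else rep(NA, nrow(out)), col)
  }
  for (col in logical_cols) {
    out[[col]] <- pv_parse_logical(
      if (col %in% names(out)) out[[col]] else rep(NA, nrow(out)), col)
  }
  extra <- setdiff(names(out), pv_encounter_cols)
  dplyr::select(out, dplyr::all_of(c(pv_encounter_cols, extra)))
}

# Lenient numeric coercion: empty string/NA -> NA silently; other
# unparseable tokens -> NA with one warning naming the column.
pv_parse_numeric <- function(x, col) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  blank <- is.na(x) | trimws(x) == "" | toupper(trimws(x)) == "NA"
  parsed <- suppressWarnings(as.numeric(x))
  bad <- !blank & is.na(parsed)
  if (any(bad)) {
    warn(sprintf("column '%s': %d unparseable value(s) set to missing",
                 col, sum(bad)), class = "pv_parse_warning")
  }
  parsed
}

pv_parse_logical <- function(x, col) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- trimws(as.character(x))
  up <- toupper(x)
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES", "Y")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO", "N")] <- FALSE
  bad <- !is.na(x) & x != "" & up != "NA" & is.na(out)
  if (any(bad)) {
    warn(sprintf("column '%s': %d unparseable value(s) set to missing",
                 col, sum(bad)), class = "pv_parse_warning")
  }
  out
}

#' Write an encounter table
#'
#' Writes a canonical encounter table to CSV or Parquet (chosen by file
#' extension). Missing values are written as empty fields so that a
#' round trip through [read_registry()] recovers all non-missing fields.
#'
#' @param data Encounter tibble.
#' @param path Output path ending in `.csv` or `.parquet`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(data, path) {
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("writing parquet requires the 'arrow' package",
            class = "pv_io_error")
    }
    arrow::write_parquet(data, path)
  } else {
    readr::write_csv(data, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Estimate infant age from weight
#'
#' The national registry reports infant ages only as "<1 year". A
#' fractional age is recovered from the documented weight by inverting the
#' infant arm of the best-guess weight formula, weight (kg) =
#' (age in months + 9) / 2, i.e. age in months = 2 * weight - 9. The
#' estimate is clamped into \[0, 11.99\] months so the result always lies in
#' \[0, 1) years.
#'
#' @param weight_kg Positive weight(s) in kilograms.
#' @return Estimated age(s) in years, in \[0, 1). `NA` input gives `NA`.
#' @examples
#' estimate_infant_age_years(7) # 5 months = 0.4167 years
#' @export
estimate_infant_age_years <- function(weight_kg) {
  if (any(!is.na(weight_kg) & weight_kg <= 0)) {
    abort("weight_kg must be positive", class = "pv_domain_error")
  }
  months <- pmin(pmax(2 * weight_kg - 9, 0), 11.99)
  months / 12
}

#' Apply the eligibility exclusion cascade
#'
#' Excludes encounters with out-of-hospital cardiac arrest, mechanical
#' ventilation at presentation, interfacility transfer, or no calculable
#' injury severity score, in that order. Each encounter is counted once in
#' the ledger, under the first rule it trips, so the ledger counts sum to
#' the number excluded. Missing exclusion flags are treated as `FALSE`.
#'
#' @param data Encounter tibble (canonical schema).
#' @return A list with `encounters`, the retained tibble, and `ledger`, a
#'   one-row tibble with columns `n_input`, `n_excluded_ohca`,
#'   `n_excluded_vent`, `n_excluded_transfer`, `n_excluded_no_iss`,
#'   `n_retained`.
#' @export
apply_exclusions <- function(data) {
  flag <- function(x) !is.na(x) & x
  ohca <- flag(data$ohca)
  vent <- !ohca & flag(data$mech_vent_at_arrival)
  transfer <- !ohca & !vent & flag(data$interfacility_transfer)
  no_iss <- !ohca & !vent & !transfer & is.na(data$iss)
  keep <- !(ohca | vent | transfer | no_iss)
  ledger <- tibble::tibble(
    n_input = nrow(data),
    n_excluded_ohca = sum(ohca),
    n_excluded_vent = sum(vent),
    n_excluded_transfer = sum(transfer),
    n_excluded_no_iss = sum(no_iss),
    n_retained = sum(keep)
  )
  list(encounters = data[keep, , drop = FALSE], ledger = ledger)
}
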