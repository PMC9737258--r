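read_checked_csv <- function(path, cols, arg = "file") {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s.", path,
                  paste(missing, collapse = ", ")))
  }
  bad <- which(!complete.cases(df[cols]))
  if (length(bad)) {
    abort(sprintf("%s: missing values in required columns at data row(s) %s.",
                  path, paste(utils::head(bad, 5), collapse = ", ")))
  }
  df
}

#' Read pipeline tables from CSV
#'
#' Thin, schema-checked readers for the tables the analysis stages consume.
#' Each reader verifies its required columns and rejects rows with missing
#' values in them, naming the offending rows. Lines starting with `#` are
#' treated as comments (output files carry a `#`-prefixed provenance header).
#'
#' * `read_dose_table()`: `label`, `dose_uM`, `viability`
#' * `read_growth_table()`: `label`, `time_h`, `od`
#' * `read_invasion_table()`: `label`, `time_h`, `area_um2`
#' * `read_survival_records()`: `label`, `time`, `event`, `group`
#' * `read_zone_profiles()`: `channel`, `zone`, `area_um2`, `fraction`
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_dose_table <- function(path) {
  read_checked_csv(path, c("label", "dose_uM", "viability"))
}

#' @rdname read_dose_table
#' @export
read_growth_table <- function(path) {
  read_checked_csv(path, c("label", "time_h", "od"))
}

#' @rdname read_dose_table
#' @export
read_invasion_table <- function(path) {
  read_checked_csv(path, c("label", "time_h", "area_um2"))
}

#' @rdname read_dose_table
#' @export
read_survival_records <- function(path) {
  df <- read_checked_csv(path, c("label", "time", "event", "group"))
  if (!all(df$event %in% c(0, 1))) {
    abort(sprintf("%s: `event` must be 0 or 1.", path))
  }
  df
}

#' @rdname read_dose_table
#' @export
read_zone_profiles <- function(path) {
  read_checked_csv(path, c("channel", "zone", "area_um2"))
}

# Write a CSV with a '#' provenance header (seed, config hash, version).
write_stage_csv <- function(df, path, provenance = NULL) {
  body <- readr::format_csv(df)
  header <- if (is.null(provenance)) "" else sprintf("# %s\n", provenance)
  cat(header, body, file = path, sep = "")
  invisible(path)
}
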