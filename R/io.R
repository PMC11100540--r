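schema_cols <- c("participant", "experiment", "block", "trial", "set_size",
                 "wm_load", "ltm_load", "pair_type", "serial_position",
                 "cue_id", "target_id", "target_color_deg", "ltm_color_deg",
                 "response_category", "response_deg")

#' Write a simulated dataset to CSV
#'
#' Serialises a `ChoiceDataset` or `ReproDataset` using the package's
#' fixed column schema (participant, experiment, block, trial,
#' set_size, wm_load, ltm_load, pair_type, serial_position, cue_id,
#' target_id, target_color_deg, ltm_color_deg, response_category,
#' response_deg). Columns that do not apply to a dataset type are
#' written empty.
#'
#' @param data Dataset tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(data, path) {
  df <- tibble::as_tibble(data)
  if (!"participant" %in% names(df)) df$participant <- 1L
  for (cc in setdiff(schema_cols, names(df))) df[[cc]] <- NA
  readr::write_csv(df[schema_cols], path, na = "")
  invisible(path)
}

#' Read a dataset written by [write_trial_data()]
#'
#' @param path CSV path.
#' @return Tibble with the package's trial-data schema.
#' @export
read_trial_data <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(
                    participant = readr::col_integer(),
                    experiment = readr::col_character(),
                    block = readr::col_integer(),
                    trial = readr::col_integer(),
                    set_size = readr::col_integer(),
                    wm_load = readr::col_integer(),
                    ltm_load = readr::col_integer(),
                    pair_type = readr::col_character(),
                    serial_position = readr::col_integer(),
                    cue_id = readr::col_character(),
                    target_id = readr::col_character(),
                    target_color_deg = readr::col_double(),
                    ltm_color_deg = readr::col_double(),
                    response_category = readr::col_character(),
                    response_deg = readr::col_double()
                  ))
}
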