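#' Read / write an observation table as CSV
#'
#' Plain one-header-row CSV with the canonical observation columns
#' (`species_id`, `class_id`, `position`, `shift_velocity_signed`,
#' `isotherm_velocity_signed`, `genetic_diversity`, `log_n_periods`,
#' `grain_size`, `data_type`, `sampling_design`, `log_study_extent`,
#' `latitude`).
#'
#' @param path File path.
#' @param table Observation table to write.
#' @return `read_observation_table` returns a `data.frame`;
#'   `write_observation_table` returns `path` invisibly.
#' @export
read_observation_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species_id", "class_id", "position",
                "shift_velocity_signed", "isotherm_velocity_signed",
                "genetic_diversity", "log_n_periods", "grain_size",
                "data_type", "sampling_design", "log_study_extent")
  if (length(miss <- setdiff(required, names(tab))))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' @rdname read_observation_table
#' @export
write_observation_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
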