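# Thin CSV readers/writers for the pipeline's file formats.  All files are
# plain RFC-4180 CSV, UTF-8, "." decimal separator.

#' Read a facility activity panel CSV
#' @param path file path.
#' @return data frame in the panel column convention.
#' @export
read_facility_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("facility_id", "state", "year", "centre_type", "cadre", "weekly_hours")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Read an activity-standards CSV
#' @param path file path (columns `centre_type`, `cadre`, `service`,
#'   `unit_time_min`).
#' @return data frame.
#' @export
read_standards <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("centre_type", "cadre", "service", "unit_time_min"), names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (any(df$unit_time_min <= 0, na.rm = TRUE)) {
    stop("activity standards must be positive", call. = FALSE)
  }
  df
}

#' Read a state staffing table CSV
#' @param path file path (columns `state`, `centre_type`, `cadre`,
#'   `in_position`, `sanctioned`, `n_centres`).
#' @return data frame.
#' @export
read_state_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("state", "centre_type", "cadre", "in_position",
                    "sanctioned", "n_centres"), names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df
}

write_output_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
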