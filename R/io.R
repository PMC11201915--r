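# CSV readers/writers for the pipeline's tabular dialects. All stage
# outputs start with comment header lines recording the seed and the
# configuration fingerprint; readers skip lines starting with '#'.

#' Write a stage CSV with a provenance header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param fingerprint Configuration fingerprint recorded in the header.
#' @return `path`, invisibly.
#' @export
write_stage_csv <- function(df, path, seed = NA, fingerprint = "") {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# seed=%s config=%s", seed, fingerprint), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline-dialect CSV
#'
#' Reads a CSV written by [write_stage_csv()] (or any plain CSV), skipping
#' `#` comment header lines.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_stage_csv <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a single-agent viability table
#'
#' Expects the dialect
#' `agent,cell_line,concentration_ug_ml,replicate,viability_pct`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_dose_response_csv <- function(path) {
  df <- read_stage_csv(path)
  assert_columns(df, c("agent", "cell_line", "concentration_ug_ml",
                       "viability_pct"), path)
  df
}

#' Read a time-course table
#'
#' Expects the dialect `condition,time_h,concentration_nmol_ml,replicate`
#' (a `cell_line` column is optional).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_time_course_csv <- function(path) {
  df <- read_stage_csv(path)
  assert_columns(df, c("condition", "time_h", "concentration_nmol_ml"), path)
  df
}
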