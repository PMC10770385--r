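#' Write a feature table to CSV
#'
#' Subjects x features matrix with a header row; the first column is the
#' subject ID.
#'
#' @param x numeric matrix with row names (subject IDs) and column names
#'   (feature names).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(subject = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()] (first column
#'   subject ID, remaining columns numeric features).
#' @return Numeric matrix with subject row names.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a run manifest
#'
#' Records command, resolved parameters, seeds, input checksums and a
#' timestamp next to an output artifact so a run can be reproduced
#' exactly.
#'
#' @param path manifest JSON path.
#' @param command command or function name.
#' @param params named list of resolved parameters.
#' @param inputs character vector of input file paths (checksummed when
#'   they exist).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, params = list(),
                               inputs = character(0)) {
  checksums <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- list(command = command,
                   package_version = as.character(
                     utils::packageVersion("radtract")),
                   parameters = params,
                   input_checksums = as.list(checksums),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
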