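# Plain-CSV interchange (UTF-8, header row, '.' decimal separator).
# Column contracts:
#   rates.csv         substrate_uM, inhibitor_uM, enzyme_scale, velocity
#   progress.csv      condition_id, t_s, od290
#   titration.csv     temperature_K, addition_index, quencher_uM,
#                     f_measured, a_ex, a_em
#   dose_response.csv inhibitor_uM, relative_activity_pct

#' Write an assay table to CSV
#'
#' @param x data.frame produced by a simulator or assembled by the user
#' @param path output file
#' @return `path`, invisibly
#' @export
write_assay_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_domain("input file not found: ", path)
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop_domain(path, " lacks required column(s): ",
                paste(missing, collapse = ", "))
  d
}

#' Read assay CSV tables
#'
#' Readers for the four interchange tables; each validates the required
#' columns. `read_titration()` returns a list of `titration_series`, one
#' per temperature.
#'
#' @param path CSV file path
#' @return data.frame (or list of `titration_series` for
#'   `read_titration()`)
#' @export
read_rate_table <- function(path) {
  read_csv_checked(path, c("substrate_uM", "inhibitor_uM", "velocity"))
}

#' @rdname read_rate_table
#' @export
read_dose_response <- function(path) {
  read_csv_checked(path, c("inhibitor_uM", "relative_activity_pct"))
}

#' @rdname read_rate_table
#' @export
read_progress <- function(path) {
  read_csv_checked(path, c("condition_id", "t_s", "od290"))
}

#' @rdname read_rate_table
#' @export
read_titration <- function(path) {
  d <- read_csv_checked(path, c("temperature_K", "addition_index",
                                "quencher_uM", "f_measured", "a_ex", "a_em"))
  lapply(split(d, d$temperature_K), function(s) {
    s <- s[order(s$addition_index), ]
    class(s) <- c("titration_series", "data.frame")
    s
  })
}

#' Read a simulation scenario from JSON
#'
#' Scenarios carry every generator parameter plus the master seed; they are
#' schema-versioned through a `schema_version` field. The bundled
#' `reference_scenario.json` scenario encodes the reference assay
#' conditions (mixed inhibition with Ki = 10.6 and Kis = 57.24 umol/L,
#' IC50 = 22.97 umol/L, and the three-temperature quenching parameters).
#'
#' @param path JSON file; default the bundled reference scenario
#' @return scenario list
#' @export
read_scenario <- function(path = system.file("extdata", "reference_scenario.json",
                                             package = "quenchkin")) {
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(sc$schema_version))
    stop_domain("scenario lacks schema_version")
  if (sc$schema_version != 1)
    stop_domain("unsupported scenario schema_version: ", sc$schema_version)
  sc
}
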