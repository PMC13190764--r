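# Readers and writers for the four delimited input formats.
#
# All tables are comma-separated UTF-8 with dot decimals and ISO-8601
# timestamps (UTC). readr handles byte-order marks and CRLF line endings
# transparently, so files from either platform parse identically.
#
# Column dictionaries:
#   bag samples : chamber_id, treatment, timestamp, analyzer_id, t_fill_min,
#                 conc_n2o_ppb, d15a_permil, d15b_permil, d18o_permil,
#                 air_temp_c, pressure_pa, chamber_height_m
#   sensor      : timestamp, plot_id, vwc
#   weather     : date, tmin_c, tmax_c, precip_mm
#   model daily : date, n2o_total, n2o_nit, n2o_denit, n2 [, wfps_sim]
#                 (g N ha-1 d-1; one file per parameter set)

read_validated <- function(path, required, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s: missing mandatory column(s): %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

reject_rows <- function(df, bad, what) {
  if (any(bad)) {
    # +1 for the header row: report file line numbers
    rlang::inform(sprintf("rejected %d malformed row(s) (%s) at file line(s): %s",
                          sum(bad), what,
                          paste(which(bad) + 1L, collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Read a bag-sample table
#'
#' Rows with non-positive concentration or fill time are rejected with a
#' line-numbered message.
#'
#' @param path CSV path.
#' @return Validated tibble in the bag-sample layout.
#' @export
read_bag_samples <- function(path) {
  req <- c("chamber_id", "treatment", "timestamp", "analyzer_id",
           "t_fill_min", "conc_n2o_ppb", "d15a_permil", "d15b_permil",
           "d18o_permil", "air_temp_c", "pressure_pa", "chamber_height_m")
  df <- read_validated(path, req, readr::cols(
    chamber_id = "c", treatment = "c",
    timestamp = readr::col_datetime(), analyzer_id = "c",
    .default = readr::col_double()))
  reject_rows(df, !is.finite(df$conc_n2o_ppb) | df$conc_n2o_ppb <= 0 |
                !is.finite(df$t_fill_min) | df$t_fill_min <= 0,
              "non-positive concentration or fill time")
}

#' Read a soil-moisture sensor table
#' @param path CSV path.
#' @return Tibble with `timestamp`, `plot_id`, `vwc`.
#' @export
read_vwc_sensor <- function(path) {
  df <- read_validated(path, c("timestamp", "plot_id", "vwc"),
                       readr::cols(timestamp = readr::col_datetime(),
                                   plot_id = "c", vwc = "d"))
  reject_rows(df, !is.na(df$vwc) & (df$vwc < 0 | df$vwc >= 1),
              "VWC outside [0, 1)")
}

#' Read a daily weather table
#' @param path CSV path.
#' @return Tibble with `date`, `tmin_c`, `tmax_c`, `precip_mm`.
#' @export
read_weather_daily <- function(path) {
  df <- read_validated(path, c("date", "tmin_c", "tmax_c", "precip_mm"),
                       readr::cols(date = readr::col_date(),
                                   .default = "d"))
  reject_rows(df, is.finite(df$precip_mm) & df$precip_mm < 0,
              "negative precipitation")
}

#' Read a daily model-output table
#'
#' Enforces the pathway-closure invariant
#' `n2o_total == n2o_nit + n2o_denit` (tolerance 1e-6).
#'
#' @param path CSV path.
#' @return Tibble in the model-daily layout, sorted by date.
#' @export
read_model_daily <- function(path) {
  df <- read_validated(path, c("date", "n2o_total", "n2o_nit", "n2o_denit", "n2"),
                       readr::cols(date = readr::col_date(), .default = "d"))
  validate_simulated_daily(df)
}
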