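# Soil-water processing: VWC -> WFPS, daily averaging with neighbor-plot
# gap filling, and observed-vs-simulated threshold diagnostics.

#' Water-filled pore space from volumetric water content
#'
#' `WFPS = 100 * VWC / (1 - BD/PD)`: the fraction of total pore space
#' occupied by water, with porosity derived from bulk density and particle
#' density. Values above 100% are returned as-is (they flag sensor or
#' bulk-density mismatch and are diagnostic information), not clipped.
#'
#' @param vwc Volumetric water content (m3 m-3, >= 0).
#' @param bd Bulk density (g cm-3).
#' @param pd Particle density (g cm-3), default 2.65.
#' @return WFPS in percent of pore space.
#' @export
#' @examples
#' wfps_from_vwc(0.30, bd = 1.39)  # 63.10
wfps_from_vwc <- function(vwc, bd = 1.39, pd = 2.65) {
  if (bd <= 0 || bd >= pd) stop("need 0 < bd < pd", call. = FALSE)
  if (any(vwc < 0, na.rm = TRUE)) stop("vwc must be >= 0", call. = FALSE)
  100 * vwc / (1 - bd / pd)
}

#' Daily averages of a sensor series with neighbor-plot gap filling
#'
#' Averages 15-min (or any sub-daily) volumetric-water-content records to
#' daily means. Dates missing from the primary plot are substituted by the
#' neighbor plot's daily mean (direct substitution, no bias adjustment) and
#' flagged `source_plot = "neighbor"`. Dates missing in both series are
#' retained with `NA` and reported in a message.
#'
#' @param primary Tibble with `timestamp` (POSIXct) and `vwc`.
#' @param neighbor Optional tibble of parallel measurements from a nearby
#'   plot, same columns.
#' @return Tibble with `date`, `vwc`, `source_plot`
#'   (`"primary"|"neighbor"|NA`), covering every date in the union of the
#'   two series' ranges.
#' @export
daily_average_and_gapfill <- function(primary, neighbor = NULL) {
  daily <- function(x) {
    if (is.null(x) || nrow(x) == 0) {
      return(tibble::tibble(date = as.Date(character()), vwc = numeric()))
    }
    dplyr::summarise(
      dplyr::group_by(dplyr::mutate(x, date = as.Date(.data$timestamp)),
                      .data$date),
      vwc = mean(.data$vwc, na.rm = TRUE), .groups = "drop")
  }
  p <- daily(primary)
  nb <- daily(neighbor)
  if (nrow(p) == 0 && nrow(nb) == 0) stop("no records supplied", call. = FALSE)
  all_dates <- seq(min(c(p$date, nb$date)), max(c(p$date, nb$date)), by = "day")
  out <- tibble::tibble(date = all_dates)
  out <- dplyr::left_join(out, dplyr::rename(p, vwc_p = "vwc"), by = "date")
  out <- dplyr::left_join(out, dplyr::rename(nb, vwc_n = "vwc"), by = "date")
  out <- dplyr::mutate(out,
    source_plot = dplyr::case_when(
      is.finite(.data$vwc_p) ~ "primary",
      is.finite(.data$vwc_n) ~ "neighbor",
      TRUE ~ NA_character_),
    vwc = dplyr::coalesce(.data$vwc_p, .data$vwc_n))
  gaps <- sum(is.na(out$vwc))
  if (gaps > 0) {
    rlang::inform(sprintf("%d date(s) missing in both primary and neighbor series",
                          gaps))
  }
  dplyr::select(out, "date", "vwc", "source_plot")
}

#' Attach WFPS to a daily soil-water series
#'
#' @param daily Tibble with `date` and `vwc` (from
#'   [daily_average_and_gapfill()]).
#' @param bd,pd Bulk and particle density (g cm-3).
#' @return Input with added `wfps` (%) and logical `over_saturation`
#'   (WFPS > 100, retained and flagged).
#' @export
soil_water_records <- function(daily, bd = 1.39, pd = 2.65) {
  dplyr::mutate(daily, wfps = wfps_from_vwc(.data$vwc, bd, pd),
                over_saturation = .data$wfps > 100)
}

#' Observed-vs-simulated WFPS diagnostics
#'
#' Compares two daily WFPS series: squared Pearson correlation on common
#' dates, inclusive day counts at or above field capacity and at or below
#' wilting point for each series, and each series' range (max - min). A
#' constant series has no defined correlation; `r2_obs_sim` is then `NA`
#' with a warning.
#'
#' @param obs,sim Tibbles with `date` and `wfps`.
#' @param fc Field capacity threshold (% WFPS), default 78.87.
#' @param wp Wilting point threshold (% WFPS), default 39.33.
#' @return List of class `wfps_diagnostics`: `r2_obs_sim`, `days_fc_obs`,
#'   `days_fc_sim`, `days_wp_obs`, `days_wp_sim`, `range_obs`, `range_sim`,
#'   `n_common`.
#' @export
wfps_diagnostics <- function(obs, sim, fc = 78.87, wp = 39.33) {
  obs <- dplyr::filter(obs, is.finite(.data$wfps))
  sim <- dplyr::filter(sim, is.finite(.data$wfps))
  common <- dplyr::inner_join(dplyr::select(obs, "date", o = "wfps"),
                              dplyr::select(sim, "date", s = "wfps"),
                              by = "date")
  if (nrow(common) < 3) {
    stop("insufficient data: fewer than 3 common dates", call. = FALSE)
  }
  r2 <- if (stats::sd(common$o) == 0 || stats::sd(common$s) == 0) {
    warning("constant WFPS series: r2 undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(common$o, common$s)^2
  }
  out <- list(r2_obs_sim = r2,
              days_fc_obs = sum(obs$wfps >= fc),
              days_fc_sim = sum(sim$wfps >= fc),
              days_wp_obs = sum(obs$wfps <= wp),
              days_wp_sim = sum(sim$wfps <= wp),
              range_obs = diff(range(obs$wfps)),
              range_sim = diff(range(sim$wfps)),
              n_common = nrow(common))
  class(out) <- "wfps_diagnostics"
  out
}

#' @export
print.wfps_diagnostics <- function(x, ...) {
  cat("<WFPS observed-vs-simulated diagnostics>\n")
  cat(sprintf("  r2 (common dates, n=%d): %s\n", x$n_common,
              ifelse(is.na(x$r2_obs_sim), "undefined",
                     sprintf("%.3f", x$r2_obs_sim))))
  cat(sprintf("  days at/above FC: obs %d, sim %d\n",
              x$days_fc_obs, x$days_fc_sim))
  cat(sprintf("  days at/below WP: obs %d, sim %d\n",
              x$days_wp_obs, x$days_wp_sim))
  cat(sprintf("  range: obs %.1f, sim %.1f %% WFPS\n",
              x$range_obs, x$range_sim))
  invisible(x)
}
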