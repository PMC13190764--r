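# Chamber flux estimation and aggregation.

# Universal gas constant, J mol-1 K-1.
.R_GAS <- 8.314

#' Concentration-slope to areal-flux conversion factor
#'
#' A closed chamber of headspace height h accumulates gas at a rate
#' proportional to the surface flux. With the ideal-gas molar density
#' p/(R T) and 28 g N per mol N2O (both nitrogen atoms), a concentration
#' slope in ppb h-1 converts to ug N2O-N m-2 h-1 as
#' `slope * 1e-9 * p/(R*T) * 28e6 * h`.
#'
#' @param pressure Air pressure (Pa).
#' @param air_temp Air temperature (deg C).
#' @param chamber_height Headspace height (m).
#' @return Flux (ug N2O-N m-2 h-1) per unit slope (ppb h-1).
#' @export
#' @examples
#' 100 * flux_conversion(101325, 25, 0.3)  # ~34.33
flux_conversion <- function(pressure, air_temp, chamber_height) {
  t_k <- air_temp + 273.15
  1e-9 * pressure / (.R_GAS * t_k) * 28e6 * chamber_height
}

#' Estimate an N2O flux from one closure event
#'
#' Fits ordinary least squares of N2O mole fraction against time since
#' closure, converts the slope to an areal flux using the dynamic molar
#' volume (ideal gas at the event's temperature and pressure), and applies
#' the regression-quality acceptance gate. When bags from duplicate
#' analyzers are present all bags enter one regression.
#'
#' A closure in which every bag has the same concentration has an undefined
#' R-squared; it is recorded as flux 0 and rejected, the conservative
#' reading of the acceptance gate.
#'
#' @param event A [closure_event()].
#' @param r2_min Acceptance threshold on R-squared (default 0.7).
#' @return A one-row tibble: `chamber_id`, `treatment`, `timestamp`, `flux`
#'   (ug N2O-N m-2 h-1), `slope` (ppb h-1), `se_flux`, `r2`, `accepted`,
#'   `n_bags`.
#' @export
compute_flux <- function(event, r2_min = 0.7) {
  event <- validate_closure_event(event)
  b <- event$bags
  t_h <- b$t_fill / 60
  if (stats::var(t_h) == 0) {
    stop("degenerate fit: no variation in bag fill times", call. = FALSE)
  }
  conv <- flux_conversion(event$pressure, event$air_temp, event$chamber_height)
  base <- tibble::tibble(chamber_id = event$chamber_id,
                         treatment = event$treatment,
                         timestamp = event$timestamp,
                         n_bags = nrow(b))
  if (stats::sd(b$conc_n2o) == 0) {
    return(dplyr::mutate(base, flux = 0, slope = 0, se_flux = 0,
                         r2 = NA_real_, accepted = FALSE))
  }
  fit <- stats::lm(conc_n2o ~ t_h, data = data.frame(conc_n2o = b$conc_n2o,
                                                     t_h = t_h))
  sm <- suppressWarnings(summary(fit))  # perfect noiseless fits are expected
  slope <- unname(stats::coef(fit)[2])
  se_slope <- sm$coefficients[2, 2]
  r2 <- sm$r.squared
  dplyr::mutate(base, flux = slope * conv, slope = slope,
                se_flux = se_slope * conv, r2 = r2,
                accepted = is.finite(r2) && r2 >= r2_min)
}

#' Weekly mean fluxes
#'
#' Averages accepted flux estimates into ISO weeks (weeks start Monday).
#' With `grouping = "treatment"` the estimates are first averaged per chamber
#' and the weekly mean is the mean of chamber means; the standard error
#' combines the regression uncertainty and the among-chamber variation as
#' `sqrt(var(chamber means)/n_chambers + mean(se_flux^2))`. With a single
#' chamber the between-chamber term vanishes and only the regression error
#' remains. Weeks without any accepted estimate are omitted (a message
#' reports them).
#'
#' @param estimates Tibble of flux estimates (rows from [compute_flux()]).
#' @param grouping `"treatment"` (default) or `"chamber"`.
#' @return Tibble with `week` (Monday date), the grouping label, `flux_mean`,
#'   `flux_se`, `n_estimates`, `n_chambers`.
#' @export
weekly_mean_flux <- function(estimates, grouping = c("treatment", "chamber")) {
  grouping <- match.arg(grouping)
  if (nrow(estimates) == 0) stop("no flux estimates supplied", call. = FALSE)
  est <- dplyr::mutate(estimates,
                       week = as.Date(cut(as.Date(.data$timestamp), "week")))
  acc <- dplyr::filter(est, .data$accepted)
  dropped <- dplyr::anti_join(dplyr::distinct(est, .data$week),
                              dplyr::distinct(acc, .data$week), by = "week")
  if (nrow(dropped) > 0) {
    rlang::inform(paste0("weeks without accepted fluxes omitted: ",
                         paste(format(dropped$week), collapse = ", ")))
  }
  if (nrow(acc) == 0) {
    return(tibble::tibble(week = as.Date(character()),
                          group = character(), flux_mean = numeric(),
                          flux_se = numeric(), n_estimates = integer(),
                          n_chambers = integer()))
  }
  grp <- if (grouping == "treatment") "treatment" else "chamber_id"
  per_chamber <- dplyr::summarise(
    dplyr::group_by(acc, .data$week, group = .data[[grp]], .data$chamber_id),
    m = mean(.data$flux), msq_se = mean(.data$se_flux^2),
    n = dplyr::n(), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(per_chamber, .data$week, .data$group),
    flux_mean = mean(.data$m),
    flux_se = sqrt(
      (if (dplyr::n() > 1) stats::var(.data$m) / dplyr::n() else 0) +
        stats::weighted.mean(.data$msq_se, .data$n)),
    n_estimates = sum(.data$n), n_chambers = dplyr::n(), .groups = "drop")
  dplyr::arrange(out, .data$group, .data$week)
}

#' Cumulative flux over a period
#'
#' Integrates a weekly mean-flux series to a cumulative emission in
#' kg N ha-1. Each weekly mean applies as a constant over its week; weeks
#' missing inside the series are linearly interpolated between the adjacent
#' weekly means (edge gaps extend the nearest value). The unit conversion is
#' ug m-2 -> kg ha-1, a factor 1e-5.
#'
#' @param weekly Tibble with columns `week` (Monday date) and `flux_mean`
#'   (ug N2O-N m-2 h-1); one group at a time.
#' @param period Length-2 Date vector `c(start, end)`, inclusive. Defaults to
#'   the full span of the weekly series.
#' @return Tibble with one row per day: `date`, `flux` (ug N2O-N m-2 h-1)
#'   and `cum_kg_n_ha`.
#' @export
#' @examples
#' wk <- tibble::tibble(week = seq(as.Date("2024-01-01"), by = 7, length.out = 53),
#'                      flux_mean = 100)
#' cf <- cumulative_flux(wk, as.Date(c("2024-01-01", "2024-12-30")))
#' tail(cf$cum_kg_n_ha, 1)  # 100 * 365 * 24 * 1e-5 = 8.76
cumulative_flux <- function(weekly, period = NULL) {
  if (is.null(weekly) || nrow(weekly) == 0) {
    stop("empty weekly series", call. = FALSE)
  }
  if (is.null(period)) {
    period <- c(min(weekly$week), max(weekly$week) + 6)
  }
  period <- as.Date(period)
  if (period[2] < period[1]) stop("period end precedes start", call. = FALSE)
  days <- seq(period[1], period[2], by = "day")
  wk_of_day <- as.Date(cut(days, "week"))
  wk_idx <- as.numeric(wk_of_day)
  flux <- if (nrow(weekly) == 1) {
    rep(weekly$flux_mean, length(days))
  } else {
    stats::approx(x = as.numeric(weekly$week), y = weekly$flux_mean,
                  xout = wk_idx, method = "linear", rule = 2)$y
  }
  tibble::tibble(date = days, flux = flux,
                 cum_kg_n_ha = cumsum(flux * 24) * 1e-5)
}

#' Total cumulative emission of a series from [cumulative_flux()]
#'
#' @param cum Tibble returned by [cumulative_flux()].
#' @return Total emission, kg N ha-1.
#' @export
cumulative_total <- function(cum) {
  utils::tail(cum$cum_kg_n_ha, 1)
}
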