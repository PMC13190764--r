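# Synthetic-data generation.
#
# Emulates every input the pipeline consumes with the statistical structure
# the analysis assumes: linear headspace accumulation over an ambient
# background with exact conservative isotope mixing (so the Keeling
# intercept of a noiseless closure IS the source delta), a two-pathway
# production mixture with optional closed-system Rayleigh reduction,
# seasonal soil-moisture series with prescribed excursions past the
# field-capacity and wilting-point thresholds, simple seasonal weather, and
# pathway-split daily emission series in the model-output format. The
# noise model is independent Gaussian per bag on concentration and on each
# delta channel.

#' True scenario for closure generation
#'
#' Holds the ground truth a synthetic closure is built from: the areal
#' flux, the microbial source endmember, the ambient background, the
#' chamber geometry and environmental state, and the noise levels.
#'
#' @param flux_true True N2O flux (ug N2O-N m-2 h-1, >= 0).
#' @param source_d15a,source_d15b,source_d18O Source endmember deltas
#'   (permil).
#' @param ambient_conc Ambient N2O (ppb, > 0).
#' @param ambient_d15a,ambient_d15b,ambient_d18O Ambient deltas (permil).
#' @param chamber_height Headspace height (m, > 0).
#' @param air_temp Air temperature (deg C).
#' @param pressure Air pressure (Pa).
#' @param noise_conc Gaussian sd of concentration noise per bag (ppb, >= 0).
#' @param noise_delta Gaussian sd of delta noise per bag and channel
#'   (permil, >= 0).
#' @param seed Optional integer seed.
#' @return List of class `true_scenario`.
#' @export
true_scenario <- function(flux_true = 103,
                          source_d15a = 0, source_d15b = 0, source_d18O = 30,
                          ambient_conc = 330, ambient_d15a = 16.05,
                          ambient_d15b = -2.65, ambient_d18O = 44.6,
                          chamber_height = 0.3, air_temp = 15,
                          pressure = 96600,
                          noise_conc = 0, noise_delta = 0, seed = NULL) {
  sc <- structure(as.list(environment()), class = "true_scenario")
  validate_scenario(sc)
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "true_scenario"))
  if (sc$flux_true < 0) stop("flux_true must be >= 0", call. = FALSE)
  if (sc$ambient_conc <= 0) stop("ambient_conc must be > 0", call. = FALSE)
  if (sc$noise_conc < 0 || sc$noise_delta < 0) {
    stop("noise sds must be >= 0", call. = FALSE)
  }
  if (sc$chamber_height <= 0) stop("chamber_height must be > 0", call. = FALSE)
  if (sc$pressure <= 0) stop("pressure must be > 0", call. = FALSE)
  sc
}

#' Pathway mixing specification
#'
#' Describes how the true source endmember of a campaign arises from a
#' two-pathway production mixture (denitrification group vs nitrification)
#' subject to partial closed-system reduction of the produced pool.
#' Endmember defaults sit at the centers of the conventional site
#' preference ranges; the net isotope effects of reduction default to
#' literature-typical magnitudes.
#'
#' @param f_den Fraction of gross N2O production from the denitrification
#'   group, in `[0, 1]`.
#' @param endmember_sp_den,endmember_sp_nit SP endmembers (permil).
#' @param endmember_bulk_den,endmember_bulk_nit Bulk d15N endmembers
#'   (permil).
#' @param reduction_r Fraction of produced N2O further reduced to N2, in
#'   `[0, 1)`.
#' @param eps_sp_red,eps_bulk_red,eps_d18O_red Net isotope effects of
#'   reduction (permil, negative).
#' @return List of class `pathway_mix_spec`.
#' @export
pathway_mix_spec <- function(f_den = 0.85,
                             endmember_sp_den = 0, endmember_sp_nit = 35.5,
                             endmember_bulk_den = -20, endmember_bulk_nit = -40,
                             reduction_r = 0,
                             eps_sp_red = -5, eps_bulk_red = -7,
                             eps_d18O_red = -15) {
  spec <- structure(as.list(environment()), class = "pathway_mix_spec")
  if (spec$f_den < 0 || spec$f_den > 1) {
    stop("f_den must lie in [0, 1]", call. = FALSE)
  }
  if (spec$reduction_r < 0 || spec$reduction_r >= 1) {
    stop("reduction_r must lie in [0, 1); r = 1 means a fully consumed pool",
         call. = FALSE)
  }
  spec
}

#' Mix two pathway endmembers and apply Rayleigh reduction
#'
#' Production mixture `delta_prod = f_den * delta_den + (1 - f_den) *
#' delta_nit` applied to SP and bulk independently, then the closed-system
#' residual-pool shift `delta_emit = delta_prod + eps * ln(1 - r)`; with
#' negative eps the emitted pool is enriched for any r > 0.
#'
#' @param spec A [pathway_mix_spec()].
#' @return List with `sp_emitted` and `bulk_emitted` (permil).
#' @export
#' @examples
#' mix_and_reduce(pathway_mix_spec(f_den = 1, endmember_sp_den = 0,
#'                                 reduction_r = 0.5))$sp_emitted  # 3.466
mix_and_reduce <- function(spec) {
  stopifnot(inherits(spec, "pathway_mix_spec"))
  shift <- log(1 - spec$reduction_r)
  sp_prod <- spec$f_den * spec$endmember_sp_den +
    (1 - spec$f_den) * spec$endmember_sp_nit
  bulk_prod <- spec$f_den * spec$endmember_bulk_den +
    (1 - spec$f_den) * spec$endmember_bulk_nit
  list(sp_emitted = sp_prod + spec$eps_sp_red * shift,
       bulk_emitted = bulk_prod + spec$eps_bulk_red * shift)
}

#' Generate one synthetic closure event
#'
#' Builds bag samples whose concentration follows
#' `ambient + slope * t` (slope back-computed from the true flux through
#' the inverse of the flux conversion) and whose deltas obey exact
#' conservative two-endmember mixing,
#' `delta = (C_amb * delta_amb + dC * delta_src) / (C_amb + dC)`, each with
#' independent Gaussian noise. The delta mixing uses the noiseless added
#' concentration so that at zero noise the Keeling intercept reproduces the
#' source delta exactly.
#'
#' @param scenario A [true_scenario()].
#' @param bag_times Fill times in minutes after closure, strictly
#'   increasing within `(0, closure_minutes]`. The default reproduces the
#'   operational timing 3.50/7.25/11.50/14.25 min of a 15-min closure.
#' @param closure_minutes Closure duration (min).
#' @param chamber_id,treatment Labels.
#' @param timestamp Closure start time.
#' @param analyzer_ids Character vector; one full bag sequence is generated
#'   per analyzer (duplicate analysis with independent noise).
#' @param seed Optional seed (overrides `scenario$seed`).
#' @return A [closure_event()].
#' @export
generate_closure <- function(scenario,
                             bag_times = c(3.50, 7.25, 11.50, 14.25),
                             closure_minutes = 15,
                             chamber_id = "CH1", treatment = "NPK",
                             timestamp = as.POSIXct("2024-05-14 08:00:00",
                                                    tz = "UTC"),
                             analyzer_ids = "A1", seed = NULL) {
  scenario <- validate_scenario(scenario)
  if (any(diff(bag_times) <= 0)) {
    stop("bag_times must be strictly increasing", call. = FALSE)
  }
  if (any(bag_times <= 0) || any(bag_times > closure_minutes)) {
    stop("bag_times must lie in (0, closure_minutes]", call. = FALSE)
  }
  seed <- seed %||% scenario$seed
  if (!is.null(seed)) set.seed(seed)

  conv <- flux_conversion(scenario$pressure, scenario$air_temp,
                          scenario$chamber_height)
  slope <- scenario$flux_true / conv            # ppb h-1
  dC <- slope * bag_times / 60                  # noiseless added N2O, ppb
  c_amb <- scenario$ambient_conc
  mix <- function(d_amb, d_src) (c_amb * d_amb + dC * d_src) / (c_amb + dC)
  n <- length(bag_times)
  bags <- lapply(analyzer_ids, function(an) {
    bag_samples(
      t_fill = bag_times,
      conc_n2o = c_amb + dC + stats::rnorm(n, 0, scenario$noise_conc),
      d15a = mix(scenario$ambient_d15a, scenario$source_d15a) +
        stats::rnorm(n, 0, scenario$noise_delta),
      d15b = mix(scenario$ambient_d15b, scenario$source_d15b) +
        stats::rnorm(n, 0, scenario$noise_delta),
      d18O = mix(scenario$ambient_d18O, scenario$source_d18O) +
        stats::rnorm(n, 0, scenario$noise_delta),
      analyzer_id = an)
  })
  closure_event(dplyr::bind_rows(bags), chamber_id = chamber_id,
                treatment = treatment, timestamp = timestamp,
                air_temp = scenario$air_temp, pressure = scenario$pressure,
                chamber_height = scenario$chamber_height)
}

#' Generate a measurement campaign
#'
#' A sequence of closures on a 4-hour grid per chamber, with per-closure
#' true fluxes from `flux_series` and the true source endmember derived
#' from a pathway mixing specification via [mix_and_reduce()] (bulk and SP
#' converted to alpha/beta as `alpha = bulk + sp/2`, `beta = bulk - sp/2`).
#'
#' @param n_closures Closures per chamber (> 0).
#' @param flux_series True fluxes, length 1 or `n_closures`.
#' @param mix_spec Optional [pathway_mix_spec()]; when supplied it
#'   overrides the scenario's source deltas (d18O keeps the scenario source
#'   value, shifted by the reduction effect).
#' @param scenario Template [true_scenario()]; its `flux_true` is ignored.
#' @param seed Integer seed; the campaign is deterministic under it.
#' @param start First closure time.
#' @param chamber_ids Chambers to simulate (closures replicated per
#'   chamber with independent noise).
#' @param treatment Treatment label.
#' @param analyzer_ids Analyzer labels per closure.
#' @return List of [closure_event()], ordered chamber-major.
#' @export
generate_campaign <- function(n_closures, flux_series,
                              mix_spec = NULL,
                              scenario = true_scenario(),
                              seed = NULL,
                              start = as.POSIXct("2024-05-01 00:00:00",
                                                 tz = "UTC"),
                              chamber_ids = "CH1", treatment = "NPK",
                              analyzer_ids = "A1") {
  if (n_closures <= 0) stop("n_closures must be > 0", call. = FALSE)
  if (length(flux_series) == 1) flux_series <- rep(flux_series, n_closures)
  if (length(flux_series) != n_closures) {
    stop("flux_series length must be 1 or n_closures", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(mix_spec)) {
    em <- mix_and_reduce(mix_spec)
    scenario$source_d15a <- em$bulk_emitted + em$sp_emitted / 2
    scenario$source_d15b <- em$bulk_emitted - em$sp_emitted / 2
    scenario$source_d18O <- scenario$source_d18O +
      mix_spec$eps_d18O_red * log(1 - mix_spec$reduction_r)
  }
  scenario$seed <- NULL   # RNG already seeded once for the whole campaign
  times <- start + (seq_len(n_closures) - 1) * 4 * 3600
  events <- list()
  for (ch in chamber_ids) {
    for (i in seq_len(n_closures)) {
      sc <- scenario
      sc$flux_true <- flux_series[i]
      events[[length(events) + 1]] <- generate_closure(
        sc, chamber_id = ch, treatment = treatment,
        timestamp = times[i], analyzer_ids = analyzer_ids)
    }
  }
  events
}

#' Generate a 15-min soil-moisture sensor series
#'
#' A constant baseline WFPS halfway between the wilting-point and
#' field-capacity thresholds, pushed above field capacity on the requested
#' wet days and below wilting point on the requested dry days; converted to
#' volumetric water content through the porosity and emitted at 15-min
#' resolution. With zero noise the daily WFPS day-count diagnostics
#' recover the requested day sets exactly.
#'
#' @param days Number of days (> 0).
#' @param porosity Total porosity (m3 m-3); the default matches bulk
#'   density 1.39 over particle density 2.65.
#' @param fc_wfps,wp_wfps Thresholds (% WFPS), `0 < wp < fc <= 100`.
#' @param wet_days,dry_days Integer day indices in `1:days`; must not
#'   overlap.
#' @param noise Gaussian sd on VWC (m3 m-3).
#' @param seed Optional seed.
#' @param start_date First day.
#' @param plot_id Plot label.
#' @return Tibble with `timestamp`, `plot_id`, `vwc` (96 rows per day).
#' @export
generate_vwc_series <- function(days, porosity = 1 - 1.39 / 2.65,
                                fc_wfps = 78.87, wp_wfps = 39.33,
                                wet_days = integer(), dry_days = integer(),
                                noise = 0, seed = NULL,
                                start_date = as.Date("2023-01-01"),
                                plot_id = "NPK") {
  if (days <= 0) stop("days must be > 0", call. = FALSE)
  if (!(wp_wfps > 0 && wp_wfps < fc_wfps && fc_wfps <= 100)) {
    stop("need 0 < wp_wfps < fc_wfps <= 100", call. = FALSE)
  }
  if (length(intersect(wet_days, dry_days)) > 0) {
    stop("wet_days and dry_days must not overlap", call. = FALSE)
  }
  if (any(c(wet_days, dry_days) < 1) || any(c(wet_days, dry_days) > days)) {
    stop("wet/dry day indices must lie in 1:days", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  wfps_day <- rep((fc_wfps + wp_wfps) / 2, days)
  wfps_day[wet_days] <- fc_wfps + 0.5 * (100 - fc_wfps)
  wfps_day[dry_days] <- 0.5 * wp_wfps
  vwc_day <- wfps_day / 100 * porosity
  n_per_day <- 96L
  ts <- as.POSIXct(start_date, tz = "UTC") +
    rep((seq_len(days) - 1) * 86400, each = n_per_day) +
    rep(seq(0, 86400 - 900, by = 900), times = days)
  vwc <- rep(vwc_day, each = n_per_day)
  if (noise > 0) vwc <- pmax(vwc + stats::rnorm(length(vwc), 0, noise), 0)
  tibble::tibble(timestamp = ts, plot_id = plot_id, vwc = vwc)
}

#' Generate a daily weather series
#'
#' Sinusoidal seasonal temperature cycle around a site-typical mean with
#' Gaussian day-to-day variation, and precipitation as wet-day Bernoulli
#' draws with gamma-distributed amounts calibrated to a target annual sum.
#' Defaults emulate a cool-temperate lowland site (mean 9.4 deg C, about
#' 1030 mm yr-1).
#'
#' @param days Number of days.
#' @param start_date First day.
#' @param mean_temp Annual mean temperature (deg C).
#' @param amplitude Seasonal half-amplitude (deg C).
#' @param diurnal_range Mean tmax - tmin spread (deg C).
#' @param annual_precip Target annual precipitation (mm).
#' @param wet_prob Probability of a wet day.
#' @param sd_temp Day-to-day temperature sd (deg C).
#' @param seed Optional seed.
#' @return Tibble with `date`, `tmin_c`, `tmax_c`, `precip_mm`.
#' @export
generate_weather_daily <- function(days, start_date = as.Date("2024-01-01"),
                                   mean_temp = 9.4, amplitude = 9,
                                   diurnal_range = 8, annual_precip = 1031,
                                   wet_prob = 0.4, sd_temp = 2.5,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- seq(start_date, by = "day", length.out = days)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- mean_temp + amplitude * sin(2 * pi * (doy - 105) / 365.25)
  tmean <- seasonal + stats::rnorm(days, 0, sd_temp)
  wet <- stats::rbinom(days, 1, wet_prob)
  mean_amt <- annual_precip / (365.25 * wet_prob)
  amt <- stats::rgamma(days, shape = 0.9, scale = mean_amt / 0.9)
  tibble::tibble(date = dates,
                 tmin_c = tmean - diurnal_range / 2,
                 tmax_c = tmean + diurnal_range / 2,
                 precip_mm = wet * amt)
}

#' Generate a pathway-split daily model-output series
#'
#' Builds a daily emission series in the model-output layout from a total
#' N2O series and a denitrification share, with N2 proportional to the
#' denitrification-derived N2O and an optional simulated WFPS column.
#'
#' @param dates Date vector.
#' @param n2o_total Daily total N2O (g N ha-1 d-1), length 1 or
#'   `length(dates)`.
#' @param f_den Denitrification share of production, length 1 or
#'   `length(dates)`.
#' @param n2_ratio N2 : denitrification-N2O ratio.
#' @param wfps_sim Optional simulated WFPS (%), recycled.
#' @return Tibble in the model-daily layout.
#' @export
generate_model_daily <- function(dates, n2o_total, f_den = 0.85,
                                 n2_ratio = 1.5, wfps_sim = NA_real_) {
  n <- length(dates)
  n2o_total <- rep_len(n2o_total, n)
  f_den <- rep_len(f_den, n)
  denit <- n2o_total * f_den
  tibble::tibble(date = as.Date(dates),
                 n2o_total = n2o_total,
                 n2o_nit = n2o_total - denit,
                 n2o_denit = denit,
                 n2 = denit * n2_ratio,
                 wfps_sim = rep_len(wfps_sim, n))
}

#' Write a full set of synthetic pipeline inputs
#'
#' Generates and writes the four input tables (bag samples, soil-moisture
#' sensor, daily weather, model daily output) for a default one-season
#' scenario, reproducible under the seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_closures Closures per chamber.
#' @param chamber_ids Chambers.
#' @param mix_spec A [pathway_mix_spec()] defining the true source.
#' @param scenario Template [true_scenario()].
#' @return Invisibly, the named list of file paths.
#' @export
write_synthetic_inputs <- function(out_dir, seed = 1L, n_closures = 42,
                                   chamber_ids = c("CH1", "CH2", "CH3"),
                                   mix_spec = pathway_mix_spec(),
                                   scenario = true_scenario(noise_conc = 1,
                                                            noise_delta = 0.3)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  n_days <- max(ceiling(n_closures / 6) + 7, 14)
  start <- as.POSIXct("2024-05-01 00:00:00", tz = "UTC")
  # Two fertilization-style emission pulses over a low background.
  idx <- seq_len(n_closures)
  fluxes <- 20 + 330 * exp(-((idx - n_closures * 0.3) / 4)^2) +
    250 * exp(-((idx - n_closures * 0.7) / 5)^2)
  events <- generate_campaign(n_closures, fluxes, mix_spec = mix_spec,
                              scenario = scenario, seed = seed + 1,
                              start = start, chamber_ids = chamber_ids,
                              analyzer_ids = c("A1", "A2"))
  vwc <- generate_vwc_series(n_days, wet_days = c(3, 4), dry_days = c(10, 11),
                             noise = 0.005, seed = seed + 2,
                             start_date = as.Date(start))
  # weather and model output bracket the campaign so antecedent-rain windows
  # and weekly-rounded cumulative periods are always covered
  wide_start <- as.Date(start) - 7
  n_wide <- n_days + 21
  weather <- generate_weather_daily(n_wide, start_date = wide_start,
                                    seed = seed + 3)
  model_dates <- seq(wide_start, by = "day", length.out = n_wide)
  model <- generate_model_daily(model_dates,
                                n2o_total = 2 + 10 * exp(-((seq_len(n_wide) -
                                  n_wide * 0.4) / 3)^2),
                                f_den = 0.85,
                                wfps_sim = 59 + 12 * sin(seq_len(n_wide) / 3))
  paths <- list(bags = file.path(out_dir, "bag_samples.csv"),
                sensor = file.path(out_dir, "vwc_sensor.csv"),
                weather = file.path(out_dir, "weather_daily.csv"),
                model = file.path(out_dir, "model_daily.csv"))
  readr::write_csv(bags_table(events), paths$bags)
  readr::write_csv(vwc, paths$sensor)
  readr::write_csv(weather, paths$weather)
  readr::write_csv(model, paths$model)
  invisible(paths)
}
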