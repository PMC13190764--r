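# Model-evaluation statistics: RMSE, parameter-set comparison, Welch
# monthly weather test.

#' Root mean squared error
#'
#' `sqrt(sum((S_i - O_i)^2) / n)` between simulated and observed values.
#'
#' @param observed,simulated Numeric vectors of equal length (n >= 1).
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(observed, simulated) {
  if (length(observed) == 0) stop("n must be >= 1", call. = FALSE)
  if (length(observed) != length(simulated)) {
    stop("observed and simulated must have equal length", call. = FALSE)
  }
  sqrt(mean((simulated - observed)^2))
}

#' Bookkeeping of the three biogeochemical-model parameter sets
#'
#' The seven nitrogen-cycle parameters of the daily ecosystem model under
#' its default values, a traditional calibration against total N2O flux,
#' and an expert-informed parameterization guided by soil-moisture and
#' isotope observations. The three water-related parameters are
#' `n2oadjust_fc` and `n2oadjust_wp` (maximum/minimum proportion of
#' nitrified N lost as N2O at field capacity / wilting point) and
#' `wfpsdnitadj` (inflection-point adjustment of the WFPS effect on
#' denitrification; values below one let denitrification proceed in drier
#' soil).
#'
#' @return Tibble with one row per parameter set.
#' @export
daycent_param_sets <- function() {
  tibble::tibble(
    name         = c("default", "traditional", "expert"),
    ncoeff       = c(0.030, 0.027, 0.027),
    n2oadjust_fc = c(0.025, 0.000, 0.001),
    n2oadjust_wp = c(0.020, 0.004, 0.001),
    maxnitamt    = c(1.500, 3.690, 3.690),
    netmn_to_no3 = c(0.200, 0.359, 0.359),
    wfpsdnitadj  = c(1.000, 1.400, 1.000),
    n2n2oadj     = c(1.000, 1.159, 1.000))
}

#' Compare simulated parameter-set runs against observed cumulative flux
#'
#' For each daily model-output run: cumulative total N2O, cumulative N2O
#' per pathway with pathway shares, cumulative N2, and the RMSE between the
#' simulated cumulative total (interpolated to the observation dates) and
#' the observed cumulative series. Daily model outputs are in g N ha-1 d-1;
#' cumulative results are reported in kg N ha-1.
#'
#' @param runs Named list of daily model-output tibbles with columns `date`,
#'   `n2o_total`, `n2o_nit`, `n2o_denit`, `n2` (g N ha-1 d-1).
#' @param observed_cum Tibble with `date` and `cum_kg_n_ha`, e.g. sampled
#'   from [cumulative_flux()] output at observation dates.
#' @return Tibble with one row per run: cumulative totals (kg N ha-1),
#'   pathway shares, and `rmse_cum_kg`.
#' @export
compare_parameterizations <- function(runs, observed_cum) {
  if (is.null(names(runs)) || any(names(runs) == "")) {
    stop("runs must be a named list", call. = FALSE)
  }
  rows <- lapply(names(runs), function(nm) {
    run <- validate_simulated_daily(runs[[nm]])
    if (min(run$date) > min(observed_cum$date) ||
        max(run$date) < max(observed_cum$date)) {
      stop(sprintf("run '%s' does not cover the observation period", nm),
           call. = FALSE)
    }
    cum_total <- cumsum(run$n2o_total) / 1000      # g -> kg N ha-1
    sim_at_obs <- stats::approx(as.numeric(run$date), cum_total,
                                xout = as.numeric(observed_cum$date),
                                rule = 2)$y
    tot <- sum(run$n2o_total)
    tibble::tibble(
      param_set = nm,
      cum_n2o_kg = tot / 1000,
      cum_n2o_nit_kg = sum(run$n2o_nit) / 1000,
      cum_n2o_denit_kg = sum(run$n2o_denit) / 1000,
      share_nit = if (tot > 0) sum(run$n2o_nit) / tot else NA_real_,
      share_den = if (tot > 0) sum(run$n2o_denit) / tot else NA_real_,
      cum_n2_kg = sum(run$n2) / 1000,
      rmse_cum_kg = rmse(observed_cum$cum_kg_n_ha, sim_at_obs))
  })
  dplyr::bind_rows(rows)
}

validate_simulated_daily <- function(run, tol = 1e-6) {
  need <- c("date", "n2o_total", "n2o_nit", "n2o_denit", "n2")
  miss <- setdiff(need, names(run))
  if (length(miss) > 0) {
    stop("model daily output missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  gap <- abs(run$n2o_total - (run$n2o_nit + run$n2o_denit))
  if (any(gap > tol)) {
    stop("n2o_total must equal n2o_nit + n2o_denit (tolerance 1e-6)",
         call. = FALSE)
  }
  dplyr::arrange(run, .data$date)
}

#' Welch two-sample comparison of monthly weather between two years
#'
#' For every calendar month with at least two daily records in each year,
#' the Welch statistic `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. When
#' both samples are constant with equal means the comparison is reported
#' as `t = 0`, `p = 1` (a case the textbook test leaves undefined).
#'
#' @param year1,year2 Daily tibbles with `date` and the named variable.
#' @param variable Column to compare, e.g. `"precip_mm"`, `"tmax_c"`.
#' @param alpha Significance level, default 0.05.
#' @return Tibble with one row per month: sample sizes, means, `t`, `df`,
#'   `p`, `significant`.
#' @export
welch_monthly_weather <- function(year1, year2, variable, alpha = 0.05) {
  stopifnot(variable %in% names(year1), variable %in% names(year2))
  by_month <- function(x) split(x[[variable]], as.integer(format(x$date, "%m")))
  g1 <- by_month(year1)
  g2 <- by_month(year2)
  months <- sort(as.integer(intersect(names(g1), names(g2))))
  rows <- lapply(months, function(m) {
    a <- g1[[as.character(m)]]; b <- g2[[as.character(m)]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    wt <- welch_t(a, b)
    tibble::tibble(month = m, n1 = length(a), n2 = length(b),
                   mean1 = mean(a), mean2 = mean(b),
                   t = wt$t, df = wt$df, p = wt$p,
                   significant = wt$p < alpha)
  })
  dplyr::bind_rows(rows)
}

welch_t <- function(a, b) {
  v1 <- stats::var(a) / length(a)
  v2 <- stats::var(b) / length(b)
  se2 <- v1 + v2
  if (se2 == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
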