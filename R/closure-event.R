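# Core record types for chamber closures.
#
# A closure event is one 15-min (by default) chamber deployment: an ordered
# set of headspace bag samples, each with a fill time (minutes after closure),
# an N2O mole fraction (ppb) and, when measured on an isotope analyzer, the
# three singly-substituted isotopocule deltas (permil). Bags from duplicate
# analyzers share fill times but carry distinct analyzer_id.

#' Construct a bag-sample table
#'
#' @param t_fill Fill times, minutes after chamber closure (strictly positive).
#' @param conc_n2o N2O mole fractions (ppb, > 0).
#' @param d15a,d15b,d18O Isotopocule deltas (permil); `NA` when the bag was
#'   analyzed for concentration only.
#' @param analyzer_id Analyzer label(s), recycled.
#' @return A tibble with one row per bag.
#' @export
bag_samples <- function(t_fill, conc_n2o, d15a = NA_real_, d15b = NA_real_,
                        d18O = NA_real_, analyzer_id = "A1") {
  if (any(t_fill <= 0)) stop("t_fill must be > 0", call. = FALSE)
  if (any(conc_n2o <= 0)) stop("conc_n2o must be > 0", call. = FALSE)
  tibble::tibble(t_fill = as.numeric(t_fill),
                 conc_n2o = as.numeric(conc_n2o),
                 d15a = as.numeric(d15a), d15b = as.numeric(d15b),
                 d18O = as.numeric(d18O),
                 analyzer_id = as.character(analyzer_id))
}

#' Construct a closure event
#'
#' @param bags Bag-sample tibble from [bag_samples()] (or with the same
#'   columns). Within each analyzer the fill times must be strictly
#'   increasing and there must be at least two bags.
#' @param chamber_id,treatment Labels.
#' @param timestamp Closure start time (`POSIXct`).
#' @param air_temp Air temperature (deg C) used for the molar volume.
#' @param pressure Air pressure (Pa).
#' @param chamber_height Headspace height (m).
#' @return A list of class `closure_event`.
#' @export
closure_event <- function(bags, chamber_id = "CH1", treatment = "NPK",
                          timestamp = as.POSIXct("2024-05-14 08:00:00", tz = "UTC"),
                          air_temp = 15, pressure = 96600,
                          chamber_height = 0.3) {
  ev <- structure(
    list(chamber_id = as.character(chamber_id),
         treatment = as.character(treatment),
         timestamp = timestamp,
         air_temp = air_temp, pressure = pressure,
         chamber_height = chamber_height,
         bags = bags),
    class = "closure_event")
  validate_closure_event(ev)
}

validate_closure_event <- function(ev) {
  stopifnot(inherits(ev, "closure_event"))
  b <- ev$bags
  need <- c("t_fill", "conc_n2o", "analyzer_id")
  if (!all(need %in% names(b))) {
    stop("bags must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(b) < 2) stop("a closure event needs at least 2 bags", call. = FALSE)
  if (any(b$t_fill <= 0)) stop("t_fill must be > 0", call. = FALSE)
  if (any(b$conc_n2o <= 0)) stop("conc_n2o must be > 0", call. = FALSE)
  incr <- vapply(split(b$t_fill, b$analyzer_id),
                 function(t) all(diff(t) > 0), logical(1))
  if (!all(incr)) {
    stop("t_fill must be strictly increasing within each analyzer", call. = FALSE)
  }
  if (!is.finite(ev$air_temp) || ev$air_temp <= -100) {
    stop("air_temp must be a plausible temperature in deg C", call. = FALSE)
  }
  if (ev$pressure <= 0 || ev$chamber_height <= 0) {
    stop("pressure and chamber_height must be positive", call. = FALSE)
  }
  ev
}

#' @export
print.closure_event <- function(x, ...) {
  cat(sprintf("<closure_event> chamber %s (%s) at %s\n", x$chamber_id,
              x$treatment, format(x$timestamp, "%Y-%m-%d %H:%M", tz = "UTC")))
  cat(sprintf("  %d bags, %d analyzer(s); T %g degC, p %g Pa, h %g m\n",
              nrow(x$bags), length(unique(x$bags$analyzer_id)),
              x$air_temp, x$pressure, x$chamber_height))
  invisible(x)
}

#' Convert a closure-event list to one flat bag table
#'
#' One row per bag with the closure metadata repeated; the inverse of
#' [closure_events_from_bags()].
#'
#' @param events List of `closure_event`.
#' @return A tibble in the bag-sample file layout.
#' @export
bags_table <- function(events) {
  rows <- lapply(events, function(ev) {
    dplyr::mutate(ev$bags,
                  chamber_id = ev$chamber_id, treatment = ev$treatment,
                  timestamp = ev$timestamp, air_temp_c = ev$air_temp,
                  pressure_pa = ev$pressure, chamber_height_m = ev$chamber_height)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "chamber_id", "treatment", "timestamp", "analyzer_id",
                t_fill_min = "t_fill", conc_n2o_ppb = "conc_n2o",
                d15a_permil = "d15a", d15b_permil = "d15b",
                d18o_permil = "d18O", "air_temp_c", "pressure_pa",
                "chamber_height_m")
}

#' Group a flat bag table back into closure events
#'
#' @param df Bag table as produced by [bags_table()] or read by
#'   [read_bag_samples()].
#' @return A list of `closure_event`, ordered by chamber then timestamp.
#' @export
closure_events_from_bags <- function(df) {
  key <- paste(df$chamber_id, format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  parts <- split(df, key)
  evs <- lapply(parts, function(g) {
    g <- g[order(g$analyzer_id, g$t_fill_min), ]
    closure_event(
      bags = bag_samples(g$t_fill_min, g$conc_n2o_ppb, g$d15a_permil,
                         g$d15b_permil, g$d18o_permil, g$analyzer_id),
      chamber_id = g$chamber_id[1], treatment = g$treatment[1],
      timestamp = g$timestamp[1], air_temp = g$air_temp_c[1],
      pressure = g$pressure_pa[1], chamber_height = g$chamber_height_m[1])
  })
  ord <- order(vapply(evs, function(e) e$chamber_id, character(1)),
               vapply(evs, function(e) as.numeric(e$timestamp), numeric(1)))
  unname(evs[ord])
}
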