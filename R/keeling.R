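# Keeling-plot source signatures.
#
# Every bag from a closed chamber holds a two-endmember mixture of ambient
# air and soil-derived N2O. Conservative mixing makes the delta of the
# mixture linear in the reciprocal concentration,
#   delta = delta_src + C_amb * (delta_amb - delta_src) / C,
# so the intercept of delta vs 1/C at 1/C -> 0 estimates the microbial
# source signature.

#' Fit a Keeling plot for one isotope channel
#'
#' Ordinary least squares of the delta value against reciprocal N2O
#' concentration over the bags of one closure (optionally restricted to one
#' analyzer). Requires at least three bags with a valid delta on the channel
#' and a minimal relative concentration spread; without spread the intercept
#' is an uncontrolled extrapolation and a degenerate-fit error is raised.
#'
#' @param event A [closure_event()].
#' @param channel One of `"d15a"`, `"d15b"`, `"d18O"`.
#' @param analyzer Optional analyzer id to restrict the bags to.
#' @param spread_tol Minimum fractional spread: `max(conc)/min(conc)` must
#'   exceed `1 + spread_tol`.
#' @return List with `intercept` (permil), `slope`, `r2`, `n`, `channel`,
#'   `analyzer`.
#' @export
fit_keeling <- function(event, channel = c("d15a", "d15b", "d18O"),
                        analyzer = NULL, spread_tol = 1e-3) {
  channel <- match.arg(channel)
  b <- event$bags
  if (!is.null(analyzer)) b <- b[b$analyzer_id == analyzer, , drop = FALSE]
  ok <- is.finite(b$conc_n2o) & is.finite(b[[channel]])
  b <- b[ok, , drop = FALSE]
  if (nrow(b) < 3) {
    stop(sprintf("insufficient data: %d valid bags on channel %s (need >= 3)",
                 nrow(b), channel), call. = FALSE)
  }
  if (max(b$conc_n2o) / min(b$conc_n2o) <= 1 + spread_tol) {
    stop("degenerate fit: insufficient concentration spread for a Keeling plot",
         call. = FALSE)
  }
  x <- 1 / b$conc_n2o
  y <- b[[channel]]
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect noiseless fits are expected
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r2 = sm$r.squared, n = nrow(b), channel = channel,
       analyzer = analyzer %||% "all")
}

#' Classify the quality of a Keeling fit
#'
#' The fitted line, evaluated at the ambient concentration, predicts the
#' isotopic composition of background air; its deviation from the known
#' ambient reference grades the fit. Deviations within the first threshold
#' are Q1, within the second Q2, within the third Q3, and beyond that the
#' fit is rejected. Defaults 4/6/8 permil.
#'
#' @param fit List from [fit_keeling()].
#' @param ambient_conc Ambient N2O mole fraction (ppb).
#' @param ambient_delta Reference ambient delta for the fitted channel
#'   (permil).
#' @param thresholds Strictly increasing class boundaries (permil).
#' @return List with `quality` (`"Q1"|"Q2"|"Q3"|"rejected"`) and
#'   `ambient_dev` (signed deviation, permil).
#' @export
classify_quality <- function(fit, ambient_conc, ambient_delta,
                             thresholds = c(4, 6, 8)) {
  pred <- fit$intercept + fit$slope / ambient_conc
  dev <- pred - ambient_delta
  a <- abs(dev)
  quality <- if (a <= thresholds[1]) "Q1"
  else if (a <= thresholds[2]) "Q2"
  else if (a <= thresholds[3]) "Q3"
  else "rejected"
  list(quality = quality, ambient_dev = dev)
}

#' All Keeling fits of one closure, per analyzer and channel
#'
#' Runs [fit_keeling()] and [classify_quality()] for every
#' analyzer-by-channel combination that has enough valid data; combinations
#' that fail the data or spread preconditions are skipped with a message.
#'
#' @param event A [closure_event()].
#' @param config A [pipeline_config()] supplying the ambient reference and
#'   thresholds.
#' @return Tibble with one row per fitted analyzer/channel: `analyzer_id`,
#'   `channel`, `intercept`, `slope`, `r2`, `n`, `ambient_dev`, `quality`.
#' @export
keeling_fits <- function(event, config = pipeline_config()) {
  amb <- config$ambient
  rows <- list()
  for (an in unique(event$bags$analyzer_id)) {
    for (ch in c("d15a", "d15b", "d18O")) {
      fit <- tryCatch(
        fit_keeling(event, ch, analyzer = an,
                    spread_tol = config$keeling_spread_tol),
        error = function(e) {
          rlang::inform(sprintf("keeling fit skipped (%s/%s): %s",
                                an, ch, conditionMessage(e)))
          NULL
        })
      if (is.null(fit)) next
      cls <- classify_quality(fit, amb$conc_ppb, amb[[ch]],
                              config$quality_thresholds)
      rows[[length(rows) + 1]] <- tibble::tibble(
        analyzer_id = an, channel = ch, intercept = fit$intercept,
        slope = fit$slope, r2 = fit$r2, n = fit$n,
        ambient_dev = cls$ambient_dev, quality = cls$quality)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(analyzer_id = character(), channel = character(),
                          intercept = numeric(), slope = numeric(),
                          r2 = numeric(), n = integer(),
                          ambient_dev = numeric(), quality = character()))
  }
  dplyr::bind_rows(rows)
}

.quality_rank <- c(Q1 = 1, Q2 = 2, Q3 = 3, rejected = 4)

#' Finalize a source signature from per-analyzer Keeling fits
#'
#' Intercepts from duplicate analyzers are arithmetically averaged per
#' channel before any derived quantity is computed; bulk d15N and site
#' preference are then `(alpha + beta)/2` and `alpha - beta` of the averaged
#' intercepts. A signature is emitted only when the closure's flux clears
#' the minimum-flux gate and its concentration regression the R-squared
#' gate. The reported class is the worst among the nitrogen channels
#' (alpha, beta); a failed d18O fit does not reject the nitrogen signature,
#' the channels are classified independently.
#'
#' @param fits Tibble from [keeling_fits()].
#' @param flux One-row tibble from [compute_flux()] for the same closure.
#' @param flux_min Minimum flux (ug N2O-N m-2 h-1) for interpretation.
#' @param r2_min R-squared gate re-applied to the flux regression.
#' @return One-row tibble: `chamber_id`, `timestamp`, `status`
#'   (`"ok"`/`"rejected"`), `reason`, `d15a_src`, `d15b_src`, `d18o_src`,
#'   `d15_bulk`, `d15_sp`, `quality`, `dev_d15a`, `dev_d15b`,
#'   `r2_keeling_min`, `n_analyzers`, `flux`, `se_flux`.
#' @export
finalize_signature <- function(fits, flux, flux_min = 75, r2_min = 0.7) {
  flux_val <- flux$flux
  se_val <- flux$se_flux
  base <- tibble::tibble(chamber_id = flux$chamber_id,
                         timestamp = flux$timestamp,
                         flux = flux_val, se_flux = se_val)
  rejected <- function(reason) {
    dplyr::mutate(base, status = "rejected", reason = reason,
                  d15a_src = NA_real_, d15b_src = NA_real_,
                  d18o_src = NA_real_, d15_bulk = NA_real_,
                  d15_sp = NA_real_, quality = "rejected",
                  dev_d15a = NA_real_, dev_d15b = NA_real_,
                  r2_keeling_min = NA_real_, n_analyzers = 0L)
  }
  if (!isTRUE(flux$accepted) || !is.finite(flux$r2) || flux$r2 < r2_min) {
    return(rejected("flux regression below R2 gate"))
  }
  if (flux$flux < flux_min) {
    return(rejected(sprintf("flux %.1f below %g ug N2O-N m-2 h-1 gate",
                            flux$flux, flux_min)))
  }
  keep <- dplyr::filter(fits, .data$quality != "rejected")
  for (ch in c("d15a", "d15b")) {
    if (!any(keep$channel == ch)) {
      return(rejected(sprintf("no acceptable Keeling fit on channel %s", ch)))
    }
  }
  avg <- dplyr::summarise(dplyr::group_by(keep, .data$channel),
                          intercept = mean(.data$intercept),
                          worst = max(.quality_rank[.data$quality]),
                          dev = .data$ambient_dev[which.max(abs(.data$ambient_dev))],
                          r2 = min(.data$r2),
                          n_an = dplyr::n(), .groups = "drop")
  get <- function(ch, col) {
    v <- avg[[col]][avg$channel == ch]
    if (length(v) == 0) NA_real_ else v
  }
  a <- get("d15a", "intercept"); b <- get("d15b", "intercept")
  nq <- max(get("d15a", "worst"), get("d15b", "worst"))
  dplyr::mutate(base, status = "ok", reason = NA_character_,
                d15a_src = a, d15b_src = b,
                d18o_src = get("d18O", "intercept"),
                d15_bulk = (a + b) / 2, d15_sp = a - b,
                quality = names(.quality_rank)[nq],
                dev_d15a = get("d15a", "dev"), dev_d15b = get("d15b", "dev"),
                r2_keeling_min = min(get("d15a", "r2"), get("d15b", "r2")),
                n_analyzers = as.integer(max(avg$n_an)))
}

#' Flux estimate and source signature for one closure
#'
#' Convenience wrapper chaining [compute_flux()], [keeling_fits()] and
#' [finalize_signature()] under one configuration.
#'
#' @param event A [closure_event()].
#' @param config A [pipeline_config()].
#' @return List with `flux` (one-row tibble) and `signature` (one-row
#'   tibble).
#' @export
process_closure <- function(event, config = pipeline_config()) {
  fl <- compute_flux(event, r2_min = config$r2_min)
  fits <- keeling_fits(event, config)
  sig <- finalize_signature(fits, fl, flux_min = config$flux_min,
                            r2_min = config$r2_min)
  list(flux = fl, signature = sig)
}
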