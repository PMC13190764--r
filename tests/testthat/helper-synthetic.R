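# Shared builders for synthetic fixtures.

# Point endmember boxes (zero-width ranges) for partition tests.
point_boxes <- function(sp_den = 0, sp_nit = 35.5,
                        bulk_den = -20, bulk_nit = -40) {
  list(den = list(sp = c(sp_den, sp_den), bulk = c(bulk_den, bulk_den)),
       nit = list(sp = c(sp_nit, sp_nit), bulk = c(bulk_nit, bulk_nit)))
}

no_reduction <- function() list(eps_sp = -5, eps_bulk = -7, r_max = 0)

# A bare signature row for partition tests.
make_signature <- function(sp, bulk, ts = as.POSIXct("2024-05-14 08:00:00",
                                                     tz = "UTC")) {
  tibble::tibble(timestamp = ts, d15_sp = sp, d15_bulk = bulk, status = "ok",
                 flux = 103, se_flux = 2)
}

# Flux-estimate rows without running regressions, for aggregation tests.
make_estimate <- function(flux, se = 0, chamber = "CH1", treatment = "NPK",
                          ts = as.POSIXct("2024-05-14 08:00:00", tz = "UTC"),
                          accepted = TRUE, r2 = 0.99) {
  tibble::tibble(chamber_id = chamber, treatment = treatment, timestamp = ts,
                 flux = flux, slope = NA_real_, se_flux = se, r2 = r2,
                 accepted = accepted, n_bags = 4L)
}
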