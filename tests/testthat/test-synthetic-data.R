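test_that("zero flux without noise reproduces ambient air in every bag", {
  sc <- true_scenario(flux_true = 0)
  ev <- generate_closure(sc)
  expect_equal(ev$bags$conc_n2o, rep(sc$ambient_conc, 4))
  expect_equal(ev$bags$d15a, rep(sc$ambient_d15a, 4))
  expect_equal(ev$bags$d15b, rep(sc$ambient_d15b, 4))
  expect_equal(ev$bags$d18O, rep(sc$ambient_d18O, 4))
})

test_that("noiseless closures lie exactly on the Keeling line", {
  for (flux in c(80, 103, 368)) {
    sc <- true_scenario(flux_true = flux, source_d15a = 2.5,
                        source_d15b = -7.5, source_d18O = 28)
    ev <- generate_closure(sc)
    # exact mixing identity: intercept == source delta
    expect_equal(fit_keeling(ev, "d15a")$intercept, 2.5, tolerance = 1e-9)
    expect_equal(fit_keeling(ev, "d15b")$intercept, -7.5, tolerance = 1e-9)
    expect_equal(fit_keeling(ev, "d18O")$intercept, 28, tolerance = 1e-9)
    # collinearity in (1/C, delta) space: residual variance ~ 0
    expect_gt(fit_keeling(ev, "d15a")$r2, 1 - 1e-12)
  }
})

test_that("generator and flux estimator are exact inverses without noise", {
  for (flux in c(10, 75, 103, 400)) {
    ev <- generate_closure(true_scenario(flux_true = flux))
    est <- compute_flux(ev)
    expect_equal(est$flux, flux, tolerance = 1e-9)
  }
})

test_that("bag time validation rejects bad sequences", {
  sc <- true_scenario()
  expect_error(generate_closure(sc, bag_times = c(5, 5, 10, 12)),
               "strictly increasing")
  expect_error(generate_closure(sc, bag_times = c(-1, 5, 10, 12)),
               "bag_times")
  expect_error(generate_closure(sc, bag_times = c(5, 10, 16)),
               "closure_minutes")
  expect_error(true_scenario(flux_true = -5), "flux_true")
  expect_error(true_scenario(noise_conc = -1), "noise")
})

test_that("mix_and_reduce reproduces endmembers, midpoints and the Rayleigh shift", {
  pure <- pathway_mix_spec(f_den = 1, endmember_sp_den = -2,
                           endmember_bulk_den = -25, reduction_r = 0)
  expect_equal(mix_and_reduce(pure)$sp_emitted, -2)
  expect_equal(mix_and_reduce(pure)$bulk_emitted, -25)

  mid <- pathway_mix_spec(f_den = 0.5, endmember_sp_den = -5,
                          endmember_sp_nit = 35, reduction_r = 0)
  expect_equal(mix_and_reduce(mid)$sp_emitted, 15)

  # closed-system Rayleigh: -5 * ln(0.5) = 3.465736 (hand evaluation)
  ray <- pathway_mix_spec(f_den = 1, endmember_sp_den = 0,
                          eps_sp_red = -5, reduction_r = 0.5)
  expect_equal(mix_and_reduce(ray)$sp_emitted, 3.465736, tolerance = 1e-6)

  expect_error(pathway_mix_spec(reduction_r = 1), "fully consumed")
  expect_error(pathway_mix_spec(f_den = 1.2), "f_den")
})

test_that("emitted SP increases with reduction extent and nitrification share", {
  sp_at <- function(f, r) mix_and_reduce(pathway_mix_spec(
    f_den = f, endmember_sp_den = -5, endmember_sp_nit = 35,
    reduction_r = r))$sp_emitted
  rs <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(vapply(rs, function(r) sp_at(0.8, r), numeric(1))) > 0))
  fs <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(fs, function(f) sp_at(f, 0.2), numeric(1))) < 0))
})

test_that("campaigns are scheduled on a 4-h grid with the mixed source", {
  spec <- pathway_mix_spec(f_den = 1, endmember_sp_den = -3,
                           endmember_bulk_den = -22, reduction_r = 0)
  evs <- generate_campaign(6, flux_series = 103, mix_spec = spec, seed = 11)
  expect_length(evs, 6)
  gaps <- diff(vapply(evs, function(e) as.numeric(e$timestamp), numeric(1)))
  expect_equal(gaps, rep(4 * 3600, 5))
  # every closure carries the denitrification endmember SP exactly
  for (ev in evs) {
    sp <- fit_keeling(ev, "d15a")$intercept - fit_keeling(ev, "d15b")$intercept
    expect_equal(sp, -3, tolerance = 1e-9)
  }
  expect_error(generate_campaign(6, flux_series = c(1, 2)), "length")
})

test_that("identical seeds give byte-identical campaigns and tables", {
  a <- generate_campaign(5, 103, scenario = true_scenario(noise_conc = 1,
                                                          noise_delta = 0.3),
                         seed = 99)
  b <- generate_campaign(5, 103, scenario = true_scenario(noise_conc = 1,
                                                          noise_delta = 0.3),
                         seed = 99)
  expect_identical(bags_table(a), bags_table(b))
  v1 <- generate_vwc_series(10, noise = 0.01, seed = 5)
  v2 <- generate_vwc_series(10, noise = 0.01, seed = 5)
  expect_identical(v1, v2)
  w1 <- generate_weather_daily(30, seed = 5)
  w2 <- generate_weather_daily(30, seed = 5)
  expect_identical(w1, w2)
})

test_that("vwc generator hits the requested threshold day counts exactly", {
  # empty excursion sets -> zero day counts
  quiet <- generate_vwc_series(20)
  daily <- soil_water_records(daily_average_and_gapfill(
    dplyr::transmute(quiet, timestamp = timestamp, vwc = vwc)))
  expect_equal(sum(daily$wfps >= 78.87), 0)
  expect_equal(sum(daily$wfps <= 39.33), 0)

  # 17 wet days (the field-capacity day-count scale) and 5 dry days
  v <- generate_vwc_series(60, wet_days = 1:17, dry_days = 41:45)
  d <- soil_water_records(daily_average_and_gapfill(
    dplyr::transmute(v, timestamp = timestamp, vwc = vwc)))
  expect_equal(sum(d$wfps >= 78.87), 17)
  expect_equal(sum(d$wfps <= 39.33), 5)

  expect_error(generate_vwc_series(10, wet_days = 1:3, dry_days = 3:5),
               "overlap")
})

test_that("a constant series sitting at field capacity counts every day", {
  porosity <- 1 - 1.39 / 2.65
  vwc_at_fc <- porosity * 78.87 / 100 + 1e-9
  ts <- as.POSIXct("2023-01-01", tz = "UTC") + seq(0, 86400 * 10 - 900, by = 900)
  d <- soil_water_records(daily_average_and_gapfill(
    tibble::tibble(timestamp = ts, vwc = vwc_at_fc)))
  expect_equal(sum(d$wfps >= 78.87), 10)
})
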