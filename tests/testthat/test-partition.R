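test_that("pure-endmember signatures partition to fraction one", {
  sig <- make_signature(sp = 0, bulk = -20)
  res <- monte_carlo_partition(sig, point_boxes(), no_reduction(),
                               n_draws = 2000, seed = 1, sd_sp_obs = 0)
  expect_equal(res$f_den_mean, 1, tolerance = 1e-12)
  expect_equal(res$f_nit_mean, 0, tolerance = 1e-12)
})

test_that("point endmembers at r = 0 reduce to the algebraic mixing solution", {
  # SP 15 between endmembers -5 and +35: f_den = (35-15)/40 = 0.5
  sig <- make_signature(sp = 15, bulk = -20)
  res <- monte_carlo_partition(sig, point_boxes(-5, 35, -20, -20),
                               no_reduction(), n_draws = 2000, seed = 2,
                               sd_sp_obs = 0)
  expect_equal(res$f_den_mean, 0.5, tolerance = 1e-12)
})

test_that("the MC mean converges to the algebraic solution with obs uncertainty", {
  sig <- make_signature(sp = 15, bulk = -30)
  res <- monte_carlo_partition(sig, point_boxes(-5, 35, -30, -30),
                               no_reduction(), n_draws = 1e5, seed = 3,
                               sd_sp_obs = 0.5)
  expect_equal(res$f_den_mean, 0.5, tolerance = 0.01)
})

test_that("partition errors on invalid inputs", {
  sig <- make_signature(15, -20)
  expect_error(monte_carlo_partition(sig, point_boxes(5, 5), no_reduction(),
                                     n_draws = 1000, seed = 1),
               "unidentifiable")
  rej <- dplyr::mutate(sig, status = "rejected")
  expect_error(monte_carlo_partition(rej, point_boxes(), no_reduction(),
                                     n_draws = 1000), "rejected")
  expect_error(monte_carlo_partition(sig, point_boxes(), no_reduction(),
                                     n_draws = 10), "n_draws")
  bad_red <- list(eps_sp = 5, eps_bulk = -7, r_max = 0)
  expect_error(monte_carlo_partition(sig, point_boxes(), bad_red,
                                     n_draws = 1000), "negative")
})

test_that("per-draw fractions sum to one and seeds reproduce results exactly", {
  sig <- make_signature(10, -25)
  boxes <- default_endmember_boxes()
  red <- list(eps_sp = -5, eps_bulk = -7, r_max = 0.5)
  a <- monte_carlo_partition(sig, boxes, red, n_draws = 3000, seed = 7)
  b <- monte_carlo_partition(sig, boxes, red, n_draws = 3000, seed = 7)
  expect_identical(a, b)
  expect_equal(a$f_den_mean + a$f_nit_mean, 1, tolerance = 1e-12)
  # CI pairs mirror each other through f_nit = 1 - f_den
  expect_equal(a$ci_nit_lo, 1 - a$ci_den_hi, tolerance = 1e-9)
  expect_equal(a$ci_nit_hi, 1 - a$ci_den_lo, tolerance = 1e-9)
})

test_that("f_den_mean decreases as the observed SP moves toward nitrification", {
  boxes <- default_endmember_boxes()
  means <- vapply(seq(0, 30, by = 5), function(sp) {
    monte_carlo_partition(make_signature(sp, -25), boxes, no_reduction(),
                          n_draws = 4000, seed = 5)$f_den_mean
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("raw CI percentiles may exceed [0,1] while means stay clipped", {
  # an observation beyond the denitrification endmember pushes raw draws
  # above one, mirroring unconstrained mixing fractions
  sig <- make_signature(sp = -4, bulk = -25)
  res <- monte_carlo_partition(sig, point_boxes(0, 35.5), no_reduction(),
                               n_draws = 5000, seed = 11, sd_sp_obs = 2)
  expect_gt(res$ci_den_hi, 1)
  expect_true(res$f_den_mean >= 0 && res$f_den_mean <= 1)
})

test_that("ignoring reduction misattributes reduced N2O to nitrification", {
  # truth: pure denitrification (f_den = 1) with half of the pool reduced;
  # the emitted SP is shifted upward by -eps*ln(0.5)
  spec <- pathway_mix_spec(f_den = 1, endmember_sp_den = 0,
                           endmember_sp_nit = 35.5, endmember_bulk_den = -20,
                           endmember_bulk_nit = -40, reduction_r = 0.5)
  em <- mix_and_reduce(spec)
  sig <- make_signature(em$sp_emitted, em$bulk_emitted)
  with_corr <- monte_carlo_partition(sig, point_boxes(),
                                     list(eps_sp = -5, eps_bulk = -7,
                                          r_max = 0.9),
                                     n_draws = 8000, seed = 13)
  no_corr <- monte_carlo_partition(sig, point_boxes(), no_reduction(),
                                   n_draws = 8000, seed = 13)
  expect_gt(no_corr$f_nit_mean, with_corr$f_nit_mean)
  expect_gt(no_corr$f_nit_mean, 0.05)   # spurious nitrification share
})

test_that("reduction lines start at the origin point and keep constant slope", {
  red <- list(eps_sp = -5, eps_bulk = -7, r_max = 0.9)
  line <- reduction_line(c(2, -25), red, r_grid = c(0, 0.25, 0.5, 0.75))
  expect_equal(line$d15_sp[1], 2)
  expect_equal(line$d15_bulk[1], -25)
  expect_equal(line$d15_sp[3], 2 - 5 * log(0.5), tolerance = 1e-9)  # +3.466
  slopes <- diff(line$d15_sp) / diff(line$d15_bulk)
  expect_equal(slopes, rep(5 / 7, 3), tolerance = 1e-12)
  expect_error(reduction_line(c(0, 0), red, r_grid = c(0, 1)), "\\[0, 1\\)")
})

test_that("7-day antecedent rain uses the (t-7d, t] window", {
  ts <- as.POSIXct("2024-07-17 08:00:00", tz = "UTC")
  sig <- dplyr::mutate(make_signature(5, -25, ts = ts), status = "ok")
  mk_weather <- function(rain_dates) {
    dates <- seq(as.Date("2024-06-30"), as.Date("2024-07-20"), by = "day")
    tibble::tibble(date = dates, precip_mm = as.numeric(dates %in% rain_dates))
  }
  day <- as.Date("2024-07-17")
  # all-zero series
  expect_equal(dual_isotope_coordinates(sig, mk_weather(as.Date(character())))$rain7d, 0)
  # 1 mm on each of the 7 days up to and including sampling
  expect_equal(dual_isotope_coordinates(sig, mk_weather(seq(day - 6, day, by = "day")))$rain7d, 7)
  # rain 8 days before sampling falls outside the window (brute-force check)
  w <- mk_weather(day - 8)
  expect_equal(dual_isotope_coordinates(sig, w)$rain7d,
               sum(w$precip_mm[w$date > day - 7 & w$date <= day]))
  expect_equal(dual_isotope_coordinates(sig, w)$rain7d, 0)
  # day boundary: rain exactly 7 days before is excluded, 6 days is included
  expect_equal(dual_isotope_coordinates(sig, mk_weather(day - 7))$rain7d, 0)
  expect_equal(dual_isotope_coordinates(sig, mk_weather(day - 6))$rain7d, 1)
  # window not covered -> NA with warning
  short <- mk_weather(day)[15:21, ]
  expect_warning(out <- dual_isotope_coordinates(sig, short), "window")
  expect_true(is.na(out$rain7d))
})
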