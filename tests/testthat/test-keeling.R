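test_that("the Keeling intercept recovers the source of an exact mixture", {
  sc <- true_scenario(flux_true = 200, source_d15a = 4.2, source_d15b = -6.4,
                      source_d18O = 31)
  ev <- generate_closure(sc)
  expect_equal(fit_keeling(ev, "d15a")$intercept, 4.2, tolerance = 1e-9)
  expect_equal(fit_keeling(ev, "d15b")$intercept, -6.4, tolerance = 1e-9)
  expect_equal(fit_keeling(ev, "d18O")$intercept, 31, tolerance = 1e-9)
})

test_that("ambient-only closures and short series fail cleanly", {
  flat <- generate_closure(true_scenario(flux_true = 0))
  expect_error(fit_keeling(flat, "d15a"), "degenerate")
  two <- closure_event(bag_samples(c(3.5, 7.25), c(330, 360),
                                   d15a = c(15, 14)))
  expect_error(fit_keeling(two, "d15a"), "insufficient")
  # missing deltas on a channel count as missing bags
  ev <- generate_closure(true_scenario(flux_true = 200))
  ev$bags$d18O <- NA_real_
  expect_error(fit_keeling(ev, "d18O"), "insufficient")
})

test_that("quality classes follow the ambient-agreement thresholds", {
  # a fit predicting exactly `dev` permil away from ambient reference at
  # ambient concentration: intercept = ref + dev, zero slope
  fit_with_dev <- function(dev) list(intercept = 18.7 + dev, slope = 0,
                                     r2 = 1, n = 4)
  cls <- function(dev) classify_quality(fit_with_dev(dev), 330, 18.7)$quality
  expect_equal(cls(3), "Q1")
  expect_equal(cls(5), "Q2")
  expect_equal(cls(7), "Q3")
  expect_equal(cls(9), "rejected")
  expect_equal(cls(-9), "rejected")
  # boundaries are inclusive
  expect_equal(cls(4), "Q1")
  expect_equal(cls(6), "Q2")
  expect_equal(cls(8), "Q3")
  # the signed deviation is reported
  expect_equal(classify_quality(fit_with_dev(-5), 330, 18.7)$ambient_dev, -5)
})

test_that("duplicate-analyzer intercepts are averaged before SP and bulk", {
  fits <- tibble::tibble(
    analyzer_id = c("A1", "A2", "A1", "A2"),
    channel = c("d15a", "d15a", "d15b", "d15b"),
    intercept = c(16.0, 16.4, -1.9, -1.7),
    slope = 0, r2 = 1, n = 4L, ambient_dev = c(1, 2, -1, 0.5),
    quality = c("Q1", "Q2", "Q1", "Q1"))
  flux <- make_estimate(103, 2)
  sig <- finalize_signature(fits, flux)
  expect_equal(sig$status, "ok")
  expect_equal(sig$d15a_src, 16.2)
  expect_equal(sig$d15b_src, -1.8)
  expect_equal(sig$d15_bulk, 7.2)   # (16.2 - 1.8)/2
  expect_equal(sig$d15_sp, 18.0)    # 16.2 + 1.8
  expect_equal(sig$quality, "Q2")   # worst nitrogen-channel class
  expect_equal(sig$n_analyzers, 2L)
})

test_that("signature identities hold on stored alpha/beta intercepts", {
  set.seed(31)
  sc <- true_scenario(flux_true = 250, source_d15a = 1, source_d15b = -4,
                      noise_conc = 1, noise_delta = 0.3)
  for (i in 1:20) {
    sig <- process_closure(generate_closure(sc))$signature
    if (sig$status != "ok") next
    expect_identical(sig$d15_bulk, (sig$d15a_src + sig$d15b_src) / 2)
    expect_identical(sig$d15_sp, sig$d15a_src - sig$d15b_src)
  }
})

test_that("the flux gate rejects low or poorly-fit fluxes regardless of fit quality", {
  fits <- tibble::tibble(analyzer_id = "A1", channel = c("d15a", "d15b"),
                         intercept = c(16, -2), slope = 0, r2 = 1, n = 4L,
                         ambient_dev = 0, quality = "Q1")
  below <- finalize_signature(fits, make_estimate(60, 1))
  expect_equal(below$status, "rejected")
  expect_match(below$reason, "below 75")
  bad_r2 <- finalize_signature(fits, make_estimate(103, 1, accepted = FALSE,
                                                   r2 = 0.5))
  expect_equal(bad_r2$status, "rejected")
  expect_match(bad_r2$reason, "R2")
})

test_that("a failed d18O channel does not reject the nitrogen signature", {
  fits <- tibble::tibble(analyzer_id = "A1",
                         channel = c("d15a", "d15b", "d18O"),
                         intercept = c(16, -2, 40), slope = 0, r2 = 1, n = 4L,
                         ambient_dev = c(0, 0, 12),
                         quality = c("Q1", "Q1", "rejected"))
  sig <- finalize_signature(fits, make_estimate(103, 1))
  expect_equal(sig$status, "ok")
  expect_true(is.na(sig$d18o_src))
  expect_equal(sig$quality, "Q1")
})

test_that("noiseless above-gate closures all classify Q1 with exact intercepts", {
  evs <- generate_campaign(5, flux_series = c(100, 150, 200, 250, 300),
                           mix_spec = pathway_mix_spec(f_den = 0.85),
                           seed = 3)
  truth <- mix_and_reduce(pathway_mix_spec(f_den = 0.85))
  for (ev in evs) {
    sig <- process_closure(ev)$signature
    expect_equal(sig$status, "ok")
    expect_equal(sig$quality, "Q1")
    expect_equal(sig$d15_sp, truth$sp_emitted, tolerance = 1e-9)
    expect_equal(sig$d15_bulk, truth$bulk_emitted, tolerance = 1e-9)
  }
})

test_that("raising the flux gate never admits more signatures", {
  set.seed(17)
  evs <- generate_campaign(12, flux_series = runif(12, 20, 300),
                           scenario = true_scenario(noise_conc = 1,
                                                    noise_delta = 0.3),
                           seed = 17)
  cfg <- pipeline_config()
  n_ok <- function(fmin) {
    sum(vapply(evs, function(ev) {
      fl <- compute_flux(ev)
      finalize_signature(keeling_fits(ev, cfg), fl,
                         flux_min = fmin)$status == "ok"
    }, logical(1)))
  }
  counts <- vapply(c(0, 50, 75, 150, 300, 1000), n_ok, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("Keeling intercept errors match OLS propagation at realistic noise", {
  # at the 103-scale flux the intercept extrapolation amplifies per-bag
  # delta noise; the empirical sd must match the analytic leverage factor
  sc <- true_scenario(flux_true = 103, noise_delta = 0.3)
  ev0 <- generate_closure(sc)
  x <- 1 / ev0$bags$conc_n2o
  lev <- sqrt(1 / 4 + mean(x)^2 / sum((x - mean(x))^2))
  set.seed(42)
  errs <- vapply(seq_len(400), function(i) {
    fit_keeling(generate_closure(sc), "d15a")$intercept - sc$source_d15a
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.5)                   # unbiased
  expect_equal(sd(errs), 0.3 * lev, tolerance = 0.15)  # ~2.7 permil
})
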