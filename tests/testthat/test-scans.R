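# Deterministic scan drivers on reduced grids (the full figure-style grids
# are exercised by the acceptance suite).

test_that("peak-amplitude scan: dose-0 column ignores k_soff", {
  sc <- scan_peak_amplitude(dose_uM = 0, k_soff = c(0.02, 1, 20), k_s = 0,
                            t_end = 1500)
  expect_equal(nrow(sc), 3)
  expect_lt(diff(range(sc$value)), 1e-8)
})

test_that("peak amplitude falls with dose and rises with stripping", {
  sc <- scan_peak_amplitude(dose_uM = c(0, 0.5, 1), k_soff = c(0.2, 1),
                            k_s = c(0, 10))
  wide <- tidyr::pivot_wider(sc[, c("dose_uM", "k_soff", "k_s", "value")],
                             names_from = "k_s", values_from = "value",
                             names_prefix = "ks")
  # stripping surface pointwise above the no-stripping surface
  expect_true(all(wide$ks10 >= wide$ks0 - 1e-9))
  for (ks in unique(sc$k_soff)) {
    for (kss in c(0, 10)) {
      col <- sc$value[sc$k_soff == ks & sc$k_s == kss][order(
        sc$dose_uM[sc$k_soff == ks & sc$k_s == kss])]
      expect_true(all(diff(col) <= 1e-9))
    }
  }
  expect_true(all(sc$lambda_s == 0))
})

test_that("duration scan: degradation shortens, stripping shortens", {
  sc <- scan_duration(lambda_s = c(0.001, 0.005, 0.02), k_soff = 0.2,
                      k_s = c(0, 10), t_end = 4000)
  for (kss in c(0, 10)) {
    col <- sc[sc$k_s == kss, ]
    col <- col[order(col$lambda_s), ]
    expect_true(all(diff(col$value) < 0))
  }
  wide <- tidyr::pivot_wider(sc[, c("lambda_s", "k_s", "value")],
                             names_from = "k_s", values_from = "value",
                             names_prefix = "ks")
  expect_true(all(wide$ks10 <= wide$ks0 + 1e-9))
})

test_that("slow unbinding prolongs the duration of action", {
  sc <- scan_duration(lambda_s = c(0.005, 0.02), k_soff = c(0.02, 1),
                      k_s = 0, t_end = 4000)
  wide <- tidyr::pivot_wider(sc[, c("lambda_s", "k_soff", "value")],
                             names_from = "k_soff", values_from = "value",
                             names_prefix = "ks")
  expect_true(all(wide$ks0.02 >= wide$ks1))
})

test_that("dose response is non-decreasing and ordered by degradation", {
  sc <- dose_response(dose_uM = c(0.25, 0.5, 1, 2),
                      lambda_s = c(0.001, 0.02), k_soff = 1, k_s = 0,
                      t_end = 4000)
  for (l in unique(sc$lambda_s)) {
    col <- sc[sc$lambda_s == l, ]
    col <- col[order(col$dose_uM), ]
    expect_true(all(diff(col$value) >= -1e-9))
  }
  rng <- tapply(sc$value, sc$lambda_s, function(v) diff(range(v)))
  # dose sensitivity is larger when degradation is slow
  expect_gt(rng[["0.001"]], rng[["0.02"]])
})

test_that("plateau onset detector applies the per-doubling rule", {
  lam <- c(1, 2, 4, 8, 16) * 1e-3
  expect_equal(plateau_onset(lam, c(900, 700, 600, 580, 575)), 4e-3)
  expect_equal(plateau_onset(lam, c(900, 450, 225, 112, 56)), NA_real_)
  expect_equal(plateau_onset(lam, c(100, 100, 100, 100, 100)), 1e-3)
  # a late bump resets the onset
  expect_equal(plateau_onset(lam, c(900, 700, 690, 300, 295)), 8e-3)
})

test_that("scan results are reproducible and tidy", {
  sc1 <- scan_dephasing(dose_uM = c(0, 1), k_soff = 1, n_replicates = 2,
                        base_seed = 7, t_end = 1200, burn_in = 300)
  sc2 <- scan_dephasing(dose_uM = c(0, 1), k_soff = 1, n_replicates = 2,
                        base_seed = 7, t_end = 1200, burn_in = 300)
  expect_identical(sc1, sc2)
  expect_named(sc1, c("dose_uM", "k_soff", "lambda_s", "k_s", "alpha",
                      "omega", "seed", "observable", "value", "capped",
                      "se", "n_used", "n_capped"))
  expect_true(all(sc1$observable == "tau_phi_min"))
  expect_equal(sc1$omega, rep(1e3, 2))
})

test_that("deterministic observables are insensitive to the bin count", {
  peaks <- vapply(c(9, 15, 31), function(nb) {
    sc <- scan_peak_amplitude(dose_uM = 0.5, k_soff = 0.2, k_s = 10,
                              n_bins = nb)
    sc$value
  }, numeric(1))
  expect_lt(diff(range(peaks)) / mean(peaks), 0.02)
  durs <- vapply(c(9, 15, 31), function(nb) {
    sc <- scan_duration(lambda_s = 0.005, k_soff = 0.2, k_s = 0,
                        n_bins = nb, t_end = 3000)
    sc$value
  }, numeric(1))
  expect_lt(diff(range(durs)) / mean(durs), 0.02)
})

test_that("resonance summary picks the largest relative drop", {
  toy <- tibble::tibble(
    dose_uM = rep(c(0, 1), each = 3),
    k_soff = rep(c(0.2, 1, 20), 2),
    value = c(500, 500, 500, 400, 100, 450)
  )
  r <- resonant_ksoff(toy)
  expect_equal(r$k_soff, 1)
  expect_equal(r$drops$rel_drop[r$drops$k_soff == 1], 0.8)
})
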