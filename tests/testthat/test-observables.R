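make_traj <- function(time, N_n_uM, omega = 1e5) {
  df <- tibble::tibble(time = time, N_n = N_n_uM * omega)
  nfkbdecoy:::new_trajectory(df, params = decoy_params(),
                             bins = build_decoy_bins(), units = "copies")
}

test_that("peak amplitude is the post-burn-in maximum in uM", {
  tr <- make_traj(seq(0, 1000, 1), rep(0.3, 1001))
  expect_equal(peak_amplitude(tr, burn_in = 500), 0.3)
  tr2 <- make_traj(seq(0, 1000, 1), c(rep(1, 501), rep(0.2, 500)))
  expect_equal(peak_amplitude(tr2, burn_in = 500), 0.2)
  expect_error(peak_amplitude(tr, burn_in = 1000), "burn-in")
})

test_that("a saturating dose of slow decoys abolishes the peak", {
  p <- decoy_params(AD_dose = 2e5, k_soff = 0.02, lambda_s = 0, k_s = 10)
  tr <- simulate_ode(p, t_end = 3000)
  expect_lt(peak_amplitude(tr), 0.01)
})

test_that("duration of action interpolates the first up-crossing", {
  tr <- make_traj(c(0, 1, 2, 3), c(0, 0.05, 0.15, 0.3))
  d <- duration_of_action(tr, threshold = 0.1)
  expect_equal(d$duration, 1.5)
  expect_false(d$capped)
  # already above threshold at t = 0
  d0 <- duration_of_action(make_traj(0:3, c(0.2, 0.3, 0.1, 0)))
  expect_equal(d0$duration, 0)
  # never crossing: capped at the horizon
  dc <- duration_of_action(make_traj(0:10, rep(0.01, 11)))
  expect_equal(dc$duration, 10)
  expect_true(dc$capped)
  expect_error(duration_of_action(tr, threshold = 0), "threshold")
})

test_that("frozen dynamics give a capped duration", {
  p <- decoy_params(alpha = 0, k_b = 0)
  tr <- simulate_ode(p, t_end = 100, dt_out = 1)
  d <- duration_of_action(tr)
  expect_true(d$capped)
  expect_equal(d$duration, 100)
})

test_that("duration is stable under grid refinement", {
  p <- decoy_params(AD_dose = 1e5, k_soff = 0.02, lambda_s = 0.001, k_s = 0)
  b <- build_decoy_bins()
  init <- dose_state(equilibrium_state(p, b), p$AD_dose)
  d1 <- duration_of_action(simulate_ode(p, b, init, t_end = 3000,
                                        dt_out = 0.5))
  d2 <- duration_of_action(simulate_ode(p, b, init, t_end = 3000,
                                        dt_out = 0.25))
  expect_false(d1$capped)
  expect_lt(abs(d1$duration - d2$duration), 0.5)
})

test_that("normalized autocorrelation is unit at lag zero", {
  a <- normalized_autocorrelation(damped_cosine(200, 100), 1000)
  expect_equal(a$acf[1], 1)
  expect_equal(a$lag, 0:1000)
  # periodicity: a pure cosine has near-unit correlation one period out
  ap <- normalized_autocorrelation(cos(2 * pi * (0:99999) / 100), 200)
  expect_gte(ap$acf[ap$lag == 100], 0.999 - 1e-9)
  # white noise stays within the 1/sqrt(n) band
  set.seed(3)
  aw <- normalized_autocorrelation(rnorm(1e5), 100)
  expect_lt(max(abs(aw$acf[-1])), 0.02)
  expect_error(normalized_autocorrelation(rep(1, 100), 20), "variance")
  expect_error(normalized_autocorrelation(rnorm(10), 20), "twice")
})

test_that("dephasing fit recovers constructed damped cosines within 5%", {
  for (tau in c(50, 200, 800)) {
    for (Tp in c(60, 100, 160)) {
      f <- dephasing_time(
        normalized_autocorrelation(damped_cosine(tau, Tp), 1500), dt = 1)
      expect_lt(abs(f$tau_phi - tau) / tau, 0.05)
      expect_lt(abs(f$period - Tp) / Tp, 0.02)
      expect_false(f$capped)
    }
  }
})

test_that("dephasing fit recovers tau under white noise", {
  set.seed(1)
  taus <- vapply(1:20, function(i) {
    sig <- damped_cosine(50, 100, noise_sd = 0.05)
    dephasing_time(normalized_autocorrelation(sig, 1500), dt = 1)$tau_phi
  }, numeric(1))
  expect_lt(abs(mean(taus) - 50), 10)
})

test_that("undamped signals are reported as capped", {
  f <- dephasing_time(
    normalized_autocorrelation(cos(2 * pi * (0:2999) / 100), 1500), dt = 1)
  expect_true(f$capped)
  expect_gte(f$tau_phi, 1500)
  # the deterministic limit cycle cannot dephase
  fd <- trajectory_dephasing(simulate_ode(decoy_params(), t_end = 3000))
  expect_true(fd$capped)
})

test_that("non-oscillatory signals raise an informative error", {
  set.seed(5)
  expect_error(
    dephasing_time(normalized_autocorrelation(rnorm(3000), 1500), dt = 1),
    "oscillat")
})

test_that("direct damped-cosine fit agrees as a cross-check", {
  a <- normalized_autocorrelation(damped_cosine(200, 100), 1500)
  fe <- dephasing_time(a, 1, method = "envelope")
  fd <- dephasing_time(a, 1, method = "direct")
  expect_lt(abs(fe$tau_phi - fd$tau_phi) / fe$tau_phi, 0.1)
})

test_that("tidy and glance summarize a fit", {
  f <- dephasing_time(normalized_autocorrelation(damped_cosine(200, 100),
                                                 1500), dt = 1)
  td <- generics::tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("tau_phi", "period", "residual", "method", "capped"))
  gl <- generics::glance(f)
  expect_gt(gl$n_peaks, 3)
})
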