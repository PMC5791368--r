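test_that("propensity times stoichiometry reproduces the derivative", {
  p <- small_params(AD_dose = 1e3, lambda_s = 0.01, k_soff = 0.3)
  b <- build_decoy_bins(D_total = p$D_total)
  net <- compile_network(build_reactions(p, b))
  set.seed(11)
  for (i in 1:100) {
    s <- stats::setNames(as.numeric(rpois(length(net$species), 50)),
                         net$species)
    a <- propensities(s, p, b, net)
    expect_true(all(a >= 0))
    lhs <- as.numeric(net$stoich %*% a)
    rhs <- ode_rhs(s, p, b)
    expect_equal(lhs, unname(rhs), tolerance = 1e-12)
  }
})

test_that("only complex dissociation and degradation fire at the start", {
  p <- decoy_params()
  b <- build_decoy_bins()
  a <- propensities(default_initial_state(p, b), p, b)
  nz <- names(a[a > 0])
  expect_setequal(nz, c("dissoc_cyt", "ikb_degradation"))
  expect_equal(unname(a["dissoc_cyt"]), 0.03 * 1e5)
  expect_equal(unname(a["ikb_degradation"]), 0.55 * 1e5)
  # first-order arithmetic for ODN decay
  p2 <- decoy_params(lambda_s = 0.02, AD_dose = 1000)
  s <- default_initial_state(p2, b)
  a2 <- propensities(s, p2, b)
  expect_equal(unname(a2["odn_degrade_unbound"]), 20)
})

test_that("identical seeds give bit-identical trajectories", {
  p <- small_params(AD_dose = 500, k_soff = 1, lambda_s = 0.01)
  t1 <- simulate_ssa(p, t_end = 100, seed = 42)
  t2 <- simulate_ssa(p, t_end = 100, seed = 42)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_ssa(p, t_end = 100, seed = 43)
  expect_false(identical(t3$N_n, t1$N_n))
  expect_error(simulate_ssa(p, t_end = 100), "seed")
})

test_that("a state with no possible reactions stays frozen", {
  p <- small_params(alpha = 0, k_b = 0)
  tr <- simulate_ssa(p, t_end = 50, seed = 1)
  expect_equal(attr(tr, "n_events"), 0)
  expect_true(all(tr$NI_c == p$N_total))
})

test_that("stochastic trajectories conserve totals exactly", {
  p <- small_params(AD_dose = 1e3, k_soff = 0.2, lambda_s = 0.005)
  b <- build_decoy_bins(D_total = p$D_total)
  tr <- simulate_ssa(p, b, t_end = 300, seed = 5)
  tot <- rowSums(tr[, nfkb_cols(15)])
  expect_true(all(tot == p$N_total))
  expect_true(all(tr$ON + tr$OFF == 1))
  du <- as.matrix(tr[, grep("^D_U_", names(tr))])
  db <- as.matrix(tr[, grep("^D_B_", names(tr))])
  expect_true(all(sweep(du + db, 2, b$count) == 0))
  expect_true(all(as.matrix(tr[, -1]) >= 0))
  expect_true(all(as.matrix(tr[, -1]) == round(as.matrix(tr[, -1]))))
})

test_that("pure death process matches its analytic mean", {
  # isolate ODN degradation: no NF-kB available to bind
  p <- decoy_params(AD_dose = 1000, lambda_s = 0.02, alpha = 0, k_b = 0)
  b <- build_decoy_bins()
  finals <- vapply(1:1000, function(s) {
    tr <- simulate_ssa(p, b, t_end = 50, seed = s)
    tr$AD_U[tr$time == 50]
  }, numeric(1))
  m <- mean(finals)
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(m - 1000 * exp(-1)), 3 * se)
})

test_that("waiting times are exponential at the total propensity", {
  # linear death process: T_k * a_k ~ iid Exp(1)
  p <- decoy_params(AD_dose = 10000, lambda_s = 0.02, alpha = 0, k_b = 0)
  b <- build_decoy_bins()
  tr <- simulate_ssa(p, b, t_end = 1e5, seed = 9, log_events = 10000)
  ev <- attr(tr, "event_times")
  k <- length(ev)
  waits <- diff(c(0, ev))
  rates <- 0.02 * (10000 - seq_len(k) + 1)
  u <- waits * rates
  ks <- suppressWarnings(stats::ks.test(u, "pexp"))
  expect_gt(ks$p.value, 0.001)
})

test_that("ensemble mean tracks the deterministic solution", {
  p <- small_params(AD_dose = 300, k_soff = 1, lambda_s = 0.005)
  b <- build_decoy_bins(D_total = p$D_total)
  ode <- simulate_ode(p, b, t_end = 200, dt_out = 1)
  ens <- simulate_ssa_ensemble(p, b, t_end = 200, record_dt = 1,
                               n_replicates = 200, base_seed = 100)
  nn <- vapply(ens, function(tr) tr$N_n, numeric(201))
  checks <- seq(11, 201, by = 10)
  m <- rowMeans(nn[checks, , drop = FALSE])
  se <- apply(nn[checks, , drop = FALSE], 1, stats::sd) / sqrt(ncol(nn))
  dev <- abs(m - ode$N_n[checks])
  # law of large numbers: the ODE is the oracle for the ensemble mean, up to
  # the finite-volume resolution of the mean-field limit (~2% at omega 1e3)
  expect_true(all(dev <= 3 * se + pmax(1, 0.02 * ode$N_n[checks])))
})

test_that("fluctuations shrink with increasing system volume", {
  sds <- vapply(c(1e2, 1e3, 1e4), function(om) {
    p <- scale_volume(decoy_params(), om)
    b <- build_decoy_bins(D_total = p$D_total)
    reps <- vapply(1:12, function(s) {
      tr <- simulate_ssa(p, b, t_end = 250, record_dt = 1, seed = 200 + s)
      mean(tr$N_n[tr$time >= 50] / om)
    }, numeric(1))
    stats::sd(reps)
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})
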