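test_that("parameter construction validates and aliases work", {
  p <- decoy_params()
  expect_s3_class(p, "decoy_params")
  expect_equal(p$k_off, 1)
  expect_equal(p$omega, 1e5)
  expect_equal(decoy_params(k_Iin = 0.05)$k_in, 0.05)
  expect_equal(update_params(p, k_Iout = 0.03)$k_out, 0.03)
  expect_error(decoy_params(k_off = -1), "non-negative")
  expect_error(decoy_params(sigma = 0), "sigma")
  expect_error(decoy_params(N_total = 1.5), "integer")
  expect_error(decoy_params(nonsense = 1), "unknown parameter")
  expect_error(update_params(p, nonsense = 1), "unknown parameter")
})

test_that("volume rescaling preserves concentrations", {
  p <- decoy_params(AD_dose = 1e5)
  q <- scale_volume(p, 1e3)
  expect_equal(q$N_total, 1e3)
  expect_equal(q$D_total, 200)
  expect_equal(q$AD_dose, 1e3)
  expect_equal(q$G_total, 1)
  expect_equal(q$AD_dose / q$omega, p$AD_dose / p$omega)
})

test_that("decoy bin spectrum is an exact partition of D_total", {
  b <- build_decoy_bins(0, 1, n_bins = 15, span_in_sigmas = 3, D_total = 2e4)
  expect_equal(sum(b$count), 2e4)
  expect_true(all(diff(b$k_doff) > 0))
  expect_true(all(b$k_doff > 0))
  expect_true(all(b$count >= 0))
  # median of LogNormal(0, 1) is 1: the central bin midpoint
  expect_equal(b$k_doff[8], 1)
  # Gaussian mass of the central bin [-0.2, 0.2] renormalized over [-3, 3]
  expected_central <- (pnorm(0.2) - pnorm(-0.2)) /
    (pnorm(3) - pnorm(-3)) * 2e4
  expect_equal(b$count[8], round(expected_central), tolerance = 1e-6)
  expect_equal(b$count[8], 3179L)
  # conservation holds for odd settings too
  for (nb in c(1, 7, 31)) {
    expect_equal(sum(build_decoy_bins(n_bins = nb, D_total = 12345)$count),
                 12345)
  }
})

test_that("a single bin degenerates to one class at exp(delta_G_hat)", {
  b <- build_decoy_bins(delta_G_hat = 0.7, n_bins = 1, D_total = 500)
  expect_equal(nrow(b), 1L)
  expect_equal(b$k_doff, exp(0.7))
  expect_equal(b$count, 500L)
  expect_error(build_decoy_bins(sigma = -1), "sigma")
  expect_error(build_decoy_bins(D_total = 0), "D_total")
})

test_that("reaction set enumerates Table-style rows per bin", {
  p <- decoy_params()
  b <- build_decoy_bins(n_bins = 15)
  rx <- build_reactions(p, b)
  # 15 bulk + 5 ODN + 3 per bin
  expect_equal(nrow(rx), 15 + 5 + 3 * 15)
  rx3 <- build_reactions(p, build_decoy_bins(n_bins = 3))
  expect_equal(nrow(rx3), 15 + 5 + 9)
  # bimolecular reactions have exactly two reactant units
  expect_true(all(vapply(rx$reactants[rx$order == 2], sum, numeric(1)) == 2))
  # stripping reactions exist with zero rate when k_s = 0
  rx0 <- build_reactions(update_params(p, k_s = 0), b)
  strips <- grepl("strip", rx0$name)
  expect_true(any(strips))
  expect_true(all(rx0$rate[strips] == 0))
})

test_that("every reaction conserves NF-kB, gene and per-bin site totals", {
  p <- decoy_params(lambda_s = 0.01, AD_dose = 1e4)
  b <- build_decoy_bins(n_bins = 5)
  net <- compile_network(build_reactions(p, b))
  sp <- net$species
  nfkb <- sp %in% nfkbdecoy:::nfkb_species(5)
  gene <- sp %in% c("ON", "OFF")
  for (j in seq_len(ncol(net$stoich))) {
    expect_equal(sum(net$stoich[nfkb, j]), 0,
                 info = colnames(net$stoich)[j])
    expect_equal(sum(net$stoich[gene, j]), 0)
    for (i in 1:5) {
      idx <- formatC(i, width = 2, flag = "0")
      pair <- sp %in% paste0(c("D_U_", "D_B_"), idx)
      expect_equal(sum(net$stoich[pair, j]), 0)
    }
  }
  # the literal 'destroy' variant deliberately breaks NF-kB conservation
  pd <- decoy_params(lambda_s = 0.01, AD_dose = 1e4,
                     bound_degradation = "destroy")
  netd <- compile_network(build_reactions(pd, b))
  expect_equal(sum(netd$stoich[nfkb, "odn_degrade_bound"]), -1)
})

test_that("default initial state matches the dosed starting condition", {
  p <- decoy_params(AD_dose = 5e4)
  b <- build_decoy_bins()
  s <- default_initial_state(p, b)
  expect_equal(unname(s["NI_c"]), 1e5)
  expect_equal(unname(s["OFF"]), 1)
  expect_equal(sum(s[grep("^D_U_", names(s))]), 2e4)
  expect_equal(unname(s["AD_U"]), 5e4)
  expect_equal(unname(s["N_n"]), 0)
  expect_equal(sum(s[grep("^D_B_", names(s))]), 0)
  tot <- conservation_totals(s, 15)
  expect_equal(tot$nfkb, 1e5)
  expect_equal(tot$gene, 1)
  expect_equal(tot$decoy_sites, b$count)
  s0 <- default_initial_state(decoy_params(), b)
  expect_equal(unname(s0["AD_U"]), 0)
})
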