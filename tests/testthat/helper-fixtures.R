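# Shared fixtures: built in code, no stored data.

# Desk-scale stochastic parameter set: published concentrations at 1/100 the
# copy numbers.
small_params <- function(...) {
  scale_volume(decoy_params(...), omega = 1e3)
}

# A damped-cosine test signal on a 1-min grid.
damped_cosine <- function(tau, period, t_end = 2999, noise_sd = 0) {
  t <- 0:t_end
  exp(-t / tau) * cos(2 * pi * t / period) +
    if (noise_sd > 0) stats::rnorm(length(t), 0, noise_sd) else 0
}

# NF-kB-carrying columns of a trajectory.
nfkb_cols <- function(n_bins) nfkbdecoy:::nfkb_species(n_bins)

expect_conserved_nfkb <- function(traj, total, tol = 1e-6) {
  tot <- rowSums(traj[, nfkb_cols(nrow(attr(traj, "bins")))])
  expect_lt(max(abs(tot - total)) / total, tol)
}
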