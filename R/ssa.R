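#' Exact stochastic simulation of the circuit
#'
#' Samples one realization of the chemical master equation over the compiled
#' reaction set with the Gillespie direct method: exponentially distributed
#' waiting times at the total propensity, reaction choice proportional to the
#' individual propensities, integer copy-number updates. States are recorded
#' by zero-order hold on a uniform grid rather than per event. The simulation
#' draws from R's RNG, so a given `seed` reproduces the trajectory bit for
#' bit.
#'
#' Published-scale runs (`omega = 1e5`) are exact but slow; for desk-scale
#' stochastic work use [scale_volume()] to shrink the system (e.g. to
#' `omega = 1e3`) while preserving all concentrations.
#'
#' @param params A [decoy_params()] object.
#' @param bins A [build_decoy_bins()] object; defaults to the 15-bin spectrum
#'   of `params`.
#' @param initial Named initial state (copies, integer-valued); defaults to
#'   [default_initial_state()].
#' @param t_end Horizon in minutes.
#' @param record_dt Recording grid spacing in minutes (default 1).
#' @param seed Integer seed; required, so no hidden RNG state leaks between
#'   runs.
#' @param max_events Safety cap on the number of reaction events (default
#'   2e9); exceeding it is an error suggesting a smaller volume factor.
#' @param log_events If > 0, also return the first `log_events` event times
#'   (used for waiting-time diagnostics).
#' @return A `decoy_trajectory` of integer states with attributes `seed` and
#'   `n_events` (and `event_times` if requested).
#' @examples
#' p <- scale_volume(decoy_params(), omega = 1e3)
#' traj <- simulate_ssa(p, t_end = 50, seed = 1)
#' attr(traj, "n_events")
#' @export
simulate_ssa <- function(params, bins = NULL, initial = NULL,
                         t_end, record_dt = 1, seed,
                         max_events = 2e9, log_events = 0) {
  stopifnot(inherits(params, "decoy_params"))
  if (missing(seed) || !is.numeric(seed)) {
    stop("'seed' must be given explicitly", call. = FALSE)
  }
  if (t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  if (is.null(bins)) bins <- default_bins(params)
  if (is.null(initial)) initial <- default_initial_state(params, bins)
  sp <- species_names(nrow(bins))
  initial <- initial[sp]
  if (anyNA(initial) || any(initial < 0) ||
      any(abs(initial - round(initial)) > 1e-8)) {
    stop("initial state must be non-negative integers over all species",
         call. = FALSE)
  }

  net <- compile_network(build_reactions(params, bins))
  r1 <- net$r1 - 1L
  r2 <- ifelse(is.na(net$r2), -1L, net$r2 - 1L)

  set.seed(as.integer(seed))
  res <- ssa_run_cpp(as.integer(round(initial)), net$stoich, net$rate,
                     as.integer(r1), as.integer(r2),
                     t_end, record_dt, max_events, as.integer(log_events))

  states <- res$states
  colnames(states) <- sp
  traj <- new_trajectory(
    tibble::as_tibble(cbind(time = res$times, as.data.frame(states))),
    params = params, bins = bins, units = "copies",
    seed = as.integer(seed), n_events = res$n_events
  )
  if (log_events > 0) attr(traj, "event_times") <- res$event_times
  traj
}

#' Run an ensemble of stochastic replicates
#'
#' Convenience wrapper running [simulate_ssa()] for replicate seeds
#' `base_seed + 0:(n_replicates - 1)` and returning the trajectories as a
#' list. Replicate `r` of any scan always uses `base_seed + r`, so ensembles
#' are reproducible from the pair (configuration, base seed).
#'
#' @param params,bins,initial,t_end,record_dt Passed to [simulate_ssa()].
#' @param n_replicates Number of replicates.
#' @param base_seed Seed of replicate 0.
#' @return List of `decoy_trajectory` objects.
#' @examples
#' p <- scale_volume(decoy_params(), omega = 100)
#' ens <- simulate_ssa_ensemble(p, t_end = 20, n_replicates = 3, base_seed = 1)
#' @export
simulate_ssa_ensemble <- function(params, bins = NULL, initial = NULL,
                                  t_end, record_dt = 1,
                                  n_replicates, base_seed) {
  purrr::map(seq_len(n_replicates) - 1L, function(r) {
    simulate_ssa(params, bins, initial, t_end = t_end,
                 record_dt = record_dt, seed = base_seed + r)
  })
}
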