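#' Default scan grids
#'
#' Figure-like resolutions for the deterministic response surfaces: 21 doses
#' spanning 0-2 uM, 13 logarithmically spaced unbinding rates spanning
#' 0.02-20 min^-1, and 11 degradation rates spanning 0-0.02 min^-1.
#'
#' @return Numeric vector.
#' @name default_grids
#' @examples
#' default_dose_grid()
NULL

#' @rdname default_grids
#' @export
default_dose_grid <- function() seq(0, 2, length.out = 21)

#' @rdname default_grids
#' @export
default_ksoff_grid <- function() 10^seq(log10(0.02), log10(20), length.out = 13)

#' @rdname default_grids
#' @export
default_lambda_grid <- function() seq(0, 0.02, length.out = 11)

scan_row <- function(params, observable, value, capped = FALSE,
                     se = NA_real_, n_used = NA_integer_,
                     n_capped = NA_integer_, seed = NA_integer_) {
  tibble::tibble(
    dose_uM = params$AD_dose / params$omega,
    k_soff = params$k_soff, lambda_s = params$lambda_s, k_s = params$k_s,
    alpha = params$alpha, omega = params$omega, seed = seed,
    observable = observable, value = value, capped = capped,
    se = se, n_used = n_used, n_capped = n_capped
  )
}

#' Peak-amplitude response surface
#'
#' Deterministic peak nuclear NF-kB amplitude over a dose x unbinding-rate
#' grid, with and without molecular stripping. ODN degradation is off
#' (`lambda_s = 0`): the surface isolates the equilibrium sequestration
#' effect of dose and unbinding kinetics.
#'
#' @param dose_uM Dose grid in uM (default [default_dose_grid()]).
#' @param k_soff Unbinding-rate grid in min^-1 (default
#'   [default_ksoff_grid()]).
#' @param k_s Stripping rates to compare (default `c(0, 10)` uM^-1 min^-1).
#' @param params Base parameter set.
#' @param n_bins Decoy-spectrum bins (default 15).
#' @param t_end,burn_in,dt_out Simulation horizon, burn-in and output grid
#'   (minutes).
#' @return Tidy `ScanResult` tibble: one row per (dose, k_soff, k_s) with
#'   `observable = "peak_uM"`.
#' @examples
#' \donttest{
#' scan_peak_amplitude(dose_uM = c(0, 1), k_soff = c(0.02, 1), k_s = 0)
#' }
#' @export
scan_peak_amplitude <- function(dose_uM = default_dose_grid(),
                                k_soff = default_ksoff_grid(),
                                k_s = c(0, 10),
                                params = decoy_params(),
                                n_bins = 15,
                                t_end = 3000, burn_in = 500, dt_out = 0.5) {
  grid <- tidyr::expand_grid(dose_uM = dose_uM, k_soff = k_soff, k_s = k_s)
  bins <- default_bins(params, n_bins)
  purrr::pmap_dfr(grid, function(dose_uM, k_soff, k_s) {
    p <- update_params(params, AD_dose = round(dose_uM * params$omega),
                       k_soff = k_soff, k_s = k_s, lambda_s = 0)
    traj <- simulate_ode(p, bins, t_end = t_end, dt_out = dt_out)
    scan_row(p, "peak_uM", peak_amplitude(traj, burn_in))
  })
}

#' Duration-of-action surface over degradation and unbinding rates
#'
#' Deterministic duration of action (first up-crossing of free nuclear NF-kB
#' above the threshold, from the dosed initial condition) over a
#' degradation-rate x unbinding-rate grid, with and without molecular
#' stripping.
#'
#' @param lambda_s Degradation-rate grid in min^-1 (default
#'   [default_lambda_grid()]).
#' @param k_soff Unbinding-rate grid in min^-1 (default
#'   [default_ksoff_grid()]).
#' @param k_s Stripping rates to compare (default `c(0, 10)`).
#' @param dose_uM Dose in uM (default 1).
#' @param params Base parameter set.
#' @param n_bins Decoy-spectrum bins (default 15).
#' @param t_end Horizon in minutes (default 6000; durations that never cross
#'   are capped there).
#' @param dt_out Output grid (default 0.5 min).
#' @param threshold Threshold concentration in uM (default 0.1).
#' @param equilibrate If `TRUE` (default), dose the running oscillator: the
#'   undosed circuit is first settled on its limit cycle
#'   ([equilibrium_state()]) and the dose added to that state at t = 0.
#'   `FALSE` starts from the cold dosed initial condition instead.
#' @param equilibrate_t Burn-in horizon of the pre-equilibration (min).
#' @return Tidy `ScanResult` tibble with `observable = "duration_min"`.
#' @examples
#' \donttest{
#' scan_duration(lambda_s = c(0.005, 0.02), k_soff = 0.2, k_s = 0)
#' }
#' @export
scan_duration <- function(lambda_s = default_lambda_grid(),
                          k_soff = default_ksoff_grid(),
                          k_s = c(0, 10), dose_uM = 1,
                          params = decoy_params(), n_bins = 15,
                          t_end = 6000, dt_out = 0.5, threshold = 0.1,
                          equilibrate = TRUE, equilibrate_t = 3000) {
  grid <- tidyr::expand_grid(dose_uM = dose_uM, lambda_s = lambda_s,
                             k_soff = k_soff, k_s = k_s)
  bins <- default_bins(params, n_bins)
  # the undosed limit cycle depends only on k_s among the scanned axes
  eq_cache <- list()
  eq_for <- function(k_s) {
    key <- as.character(k_s)
    if (is.null(eq_cache[[key]])) {
      eq_cache[[key]] <<- equilibrium_state(
        update_params(params, k_s = k_s), bins,
        t_burn = equilibrate_t, dt_out = dt_out)
    }
    eq_cache[[key]]
  }
  purrr::pmap_dfr(grid, function(dose_uM, lambda_s, k_soff, k_s) {
    p <- update_params(params, AD_dose = round(dose_uM * params$omega),
                       lambda_s = lambda_s, k_soff = k_soff, k_s = k_s)
    init <- if (equilibrate) {
      dose_state(eq_for(k_s), p$AD_dose)
    } else {
      default_initial_state(p, bins)
    }
    traj <- simulate_ode(p, bins, initial = init, t_end = t_end,
                         dt_out = dt_out)
    d <- duration_of_action(traj, threshold)
    scan_row(p, "duration_min", d$duration, capped = d$capped)
  })
}

#' Duration-of-action dose response
#'
#' Deterministic duration of action as a function of dose, for combinations
#' of degradation rate, unbinding rate and stripping.
#'
#' @param dose_uM Dose grid in uM (default [default_dose_grid()]).
#' @param lambda_s Degradation rates (default `c(0.001, 0.005, 0.02)`).
#' @param k_soff Unbinding rates (default `c(0.02, 1)`).
#' @param k_s Stripping rates (default `c(0, 10)`).
#' @param params,n_bins,t_end,dt_out,threshold,equilibrate,equilibrate_t As
#'   in [scan_duration()].
#' @return Tidy `ScanResult` tibble with `observable = "duration_min"`.
#' @examples
#' \donttest{
#' dose_response(dose_uM = c(0.5, 1), lambda_s = 0.005, k_soff = 1, k_s = 0)
#' }
#' @export
dose_response <- function(dose_uM = default_dose_grid(),
                          lambda_s = c(0.001, 0.005, 0.02),
                          k_soff = c(0.02, 1), k_s = c(0, 10),
                          params = decoy_params(), n_bins = 15,
                          t_end = 6000, dt_out = 0.5, threshold = 0.1,
                          equilibrate = TRUE, equilibrate_t = 3000) {
  scan_duration(lambda_s = lambda_s, k_soff = k_soff, k_s = k_s,
                dose_uM = dose_uM, params = params, n_bins = n_bins,
                t_end = t_end, dt_out = dt_out, threshold = threshold,
                equilibrate = equilibrate, equilibrate_t = equilibrate_t)
}

#' Dephasing-time scan (stochastic)
#'
#' Mean and standard error of the dephasing time of nuclear free NF-kB over
#' a dose x unbinding-rate grid, from ensembles of exact stochastic
#' trajectories at a (typically reduced) volume factor. Capped fits (envelope
#' decay unresolved within the lag window) are excluded from the mean and
#' counted. At dose 0 the ODN reactions can never fire, so the condition is
#' simulated once per replicate and shared across `k_soff` values.
#'
#' @param dose_uM Dose grid in uM (default `c(0, 0.5, 1)`).
#' @param k_soff Unbinding rates (default `c(0.02, 0.2, 1, 20)` min^-1,
#'   spanning slow to fast relative to the promoter's `k_off = 1`).
#' @param n_replicates Replicates per condition (default 20).
#' @param base_seed Seed of replicate 0 (replicate r uses `base_seed + r`).
#' @param omega Volume factor for the stochastic runs (default 1e3
#'   copies/uM, i.e. totals scaled down 100-fold from the published scale).
#' @param params Base parameter set (rescaled internally via
#'   [scale_volume()]).
#' @param k_s Stripping rate (default 10).
#' @param lambda_s ODN degradation rate (default 0: persistent dosing).
#' @param n_bins Decoy-spectrum bins (default 15).
#' @param t_end,burn_in,record_dt Horizon, burn-in and recording grid
#'   (minutes; defaults 3000 / 500 / 1).
#' @return Tidy `ScanResult` tibble with `observable = "tau_phi_min"`,
#'   `value` the ensemble mean, plus `se`, `n_used` and `n_capped`.
#' @examples
#' \donttest{
#' scan_dephasing(dose_uM = c(0, 1), k_soff = 1, n_replicates = 2,
#'                base_seed = 1, t_end = 1500)
#' }
#' @export
scan_dephasing <- function(dose_uM = c(0, 0.5, 1),
                           k_soff = c(0.02, 0.2, 1, 20),
                           n_replicates = 20, base_seed = 1,
                           omega = 1e3, params = decoy_params(),
                           k_s = 10, lambda_s = 0, n_bins = 15,
                           t_end = 3000, burn_in = 500, record_dt = 1) {
  base <- scale_volume(update_params(params, k_s = k_s, lambda_s = lambda_s),
                       omega)
  bins <- default_bins(base, n_bins)

  run_cell <- function(p) {
    taus <- purrr::map(seq_len(n_replicates) - 1L, function(r) {
      traj <- simulate_ssa(p, bins, t_end = t_end, record_dt = record_dt,
                           seed = base_seed + r)
      tryCatch(trajectory_dephasing(traj, burn_in = burn_in),
               error = function(e) NULL)
    })
    ok <- !vapply(taus, is.null, logical(1))
    capped <- vapply(taus[ok], function(f) f$capped, logical(1))
    vals <- vapply(taus[ok], function(f) f$tau_phi, numeric(1))[!capped]
    list(mean = if (length(vals)) mean(vals) else NA_real_,
         se = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals))
              else NA_real_,
         n_used = length(vals), n_capped = sum(capped))
  }

  rows <- list()
  zero_cell <- NULL
  for (d in dose_uM) {
    for (ks in k_soff) {
      p <- update_params(base, AD_dose = round(d * omega), k_soff = ks)
      if (d == 0) {
        if (is.null(zero_cell)) zero_cell <- run_cell(p)
        cell <- zero_cell
      } else {
        cell <- run_cell(p)
      }
      rows[[length(rows) + 1L]] <- scan_row(
        p, "tau_phi_min", cell$mean, capped = cell$n_used == 0,
        se = cell$se, n_used = cell$n_used, n_capped = cell$n_capped,
        seed = as.integer(base_seed)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Plateau onset of a duration-vs-degradation sweep
#'
#' Given duration of action measured on a doubling grid of degradation
#' rates, returns the smallest rate beyond which the duration changes by
#' less than `tol` per doubling (i.e. the onset of the plateau where faster
#' degradation no longer shortens the response).
#'
#' @param lambda_s Increasing degradation-rate grid; each entry should be
#'   twice the previous.
#' @param duration Duration of action at each rate (minutes).
#' @param tol Relative-change tolerance per doubling (default 0.05).
#' @return The plateau-onset rate (min^-1), or `NA` if the sweep never
#'   settles.
#' @examples
#' plateau_onset(c(1, 2, 4, 8, 16) * 1e-3, c(900, 700, 600, 580, 575))
#' @export
plateau_onset <- function(lambda_s, duration, tol = 0.05) {
  stopifnot(length(lambda_s) == length(duration), length(lambda_s) >= 2)
  o <- order(lambda_s)
  lambda_s <- lambda_s[o]; duration <- duration[o]
  rel <- abs(diff(duration)) / duration[-length(duration)]
  settled <- rev(cumprod(rev(rel < tol))) == 1   # all later steps small too
  i <- which(settled)[1]
  if (is.na(i)) NA_real_ else lambda_s[i]
}

#' Duration-of-action plateau over degradation rate
#'
#' Runs the deterministic duration-of-action sweep on a doubling grid of
#' degradation rates at fixed dose, unbinding rate and stripping, and locates
#' the plateau onset with [plateau_onset()].
#'
#' @param params Base parameter set.
#' @param k_soff Unbinding rate (default 0.02 min^-1, the slow/high-affinity
#'   regime where the plateau arises).
#' @param dose_uM Dose in uM (default 1).
#' @param k_s Stripping rate (default 0).
#' @param lambda_grid Doubling grid of degradation rates (default
#'   `5e-4 * 2^(0:5)`).
#' @param n_bins,t_end,dt_out,equilibrate,equilibrate_t As in
#'   [scan_duration()].
#' @param tol Plateau tolerance per doubling (default 0.05).
#' @return List with the `scan` tibble and the `onset` rate (min^-1).
#' @examples
#' \donttest{
#' duration_plateau(lambda_grid = c(0.004, 0.008, 0.016))$onset
#' }
#' @export
duration_plateau <- function(params = decoy_params(), k_soff = 0.02,
                             dose_uM = 1, k_s = 0,
                             lambda_grid = 5e-4 * 2^(0:5),
                             n_bins = 15, t_end = 6000, dt_out = 0.5,
                             tol = 0.05,
                             equilibrate = TRUE, equilibrate_t = 3000) {
  scan <- scan_duration(lambda_s = lambda_grid, k_soff = k_soff, k_s = k_s,
                        dose_uM = dose_uM, params = params, n_bins = n_bins,
                        t_end = t_end, dt_out = dt_out,
                        equilibrate = equilibrate,
                        equilibrate_t = equilibrate_t)
  list(scan = scan,
       onset = plateau_onset(scan$lambda_s, scan$value, tol = tol))
}

#' Unbinding rate with the largest dephasing-time reduction
#'
#' From a [scan_dephasing()] result, computes per unbinding rate the relative
#' drop of the mean dephasing time from dose 0 to the largest dose, and
#' returns the rate at which the drop is largest — the resonance between the
#' ODN unbinding rate and the promoter unbinding rate.
#'
#' @param scan A [scan_dephasing()] tibble.
#' @return List with `k_soff` (the resonant rate) and the per-rate `drops`
#'   tibble.
#' @examples
#' \donttest{
#' sc <- scan_dephasing(n_replicates = 2, t_end = 1500, base_seed = 1)
#' resonant_ksoff(sc)$k_soff
#' }
#' @export
resonant_ksoff <- function(scan) {
  stopifnot(all(c("dose_uM", "k_soff", "value") %in% names(scan)))
  dmax <- max(scan$dose_uM)
  drops <- scan |>
    dplyr::filter(.data$dose_uM %in% c(0, dmax)) |>
    dplyr::select("dose_uM", "k_soff", "value") |>
    tidyr::pivot_wider(names_from = "dose_uM", values_from = "value",
                       names_prefix = "dose_") |>
    dplyr::mutate(rel_drop = (.data$dose_0 - .data[[paste0("dose_", dmax)]]) /
                    .data$dose_0)
  list(k_soff = drops$k_soff[which.max(drops$rel_drop)], drops = drops)
}
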