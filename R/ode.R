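MAXBINS <- 64L
NPARMS <- 23L + 2L * MAXBINS

pack_parms <- function(params, bins) {
  n <- nrow(bins)
  if (n > MAXBINS) stop("at most ", MAXBINS, " decoy bins supported",
                        call. = FALSE)
  p <- params
  om <- p$omega
  lambda_b <- if (p$bound_degradation == "none") 0 else p$lambda_s
  release <- as.numeric(p$bound_degradation == "release")
  v <- numeric(NPARMS)
  v[1:23] <- c(p$k_on / om, p$k_off, p$k_s / om, p$k_tr * om, p$k_tl, p$k_d,
               p$k_in, p$k_out, p$k_Nin, p$k_f / om, p$k_b, p$k_fn / om,
               p$k_bn, p$k_NIout, p$alpha, p$k_son / om, p$k_soff,
               p$lambda_s, lambda_b, release, p$k_don / om,
               p$G_total, n)
  v[24:(23 + n)] <- bins$k_doff
  v[(24 + n):(23 + 2 * n)] <- bins$count
  v
}

#' Deterministic derivative of the full state
#'
#' Evaluates the mass-action time derivative of every species at a state, in
#' copies per minute, under the copy-number unit convention. The sum of the
#' derivatives over all NF-kB-carrying species is zero by construction, as are
#' the gene-state and per-bin decoy-site sums.
#'
#' @param state Named non-negative state vector over [species_names()].
#' @param params A [decoy_params()] object.
#' @param bins A [build_decoy_bins()] object.
#' @return Named numeric derivative vector (copies/min).
#' @examples
#' p <- decoy_params(); b <- build_decoy_bins()
#' d <- ode_rhs(default_initial_state(p, b), p, b)
#' sum(d[nfkbdecoy::species_names(nrow(b)) |> grep(pattern = "^N", value = TRUE)])
#' @export
ode_rhs <- function(state, params, bins) {
  stopifnot(inherits(params, "decoy_params"), inherits(bins, "decoy_bins"))
  sp <- species_names(nrow(bins))
  state <- state[sp]
  if (anyNA(state)) stop("state is missing species entries", call. = FALSE)
  if (any(state < 0)) stop("state entries must be non-negative", call. = FALSE)
  d <- rhs_full_cpp(as.numeric(state), pack_parms(params, bins))
  stats::setNames(d, sp)
}

#' Integrate the deterministic model
#'
#' Solves the mass-action rate equations of the circuit with a stiff
#' variable-order, variable-step solver (VODE, full internally generated
#' Jacobian), in copy-number units, on a uniform output grid. The exactly
#' conserved coordinates (the OFF gene state and the unbound decoy pools) are
#' eliminated before integration and reconstructed on output, so the gene and
#' decoy-site invariants hold identically and NF-kB conservation is limited
#' only by integrator drift. Tiny negative round-off values in the output are
#' clipped to zero with a warning; negatives larger than `10 * atol` are an
#' error.
#'
#' @param params A [decoy_params()] object.
#' @param bins A [build_decoy_bins()] object; defaults to the 15-bin spectrum
#'   of `params`.
#' @param initial Named initial state (copies); defaults to
#'   [default_initial_state()].
#' @param t_end Integration horizon in minutes (default 3000).
#' @param dt_out Output grid spacing in minutes (default 0.5, giving > 100
#'   points per ~100-min oscillation cycle).
#' @param rtol,atol Relative/absolute integrator tolerances in copy units
#'   (defaults 1e-8 / 1e-10).
#' @return A `decoy_trajectory`: a tibble with `time` (min) and one column per
#'   species, in copies, carrying `params`, `bins`, `units` and the clipping
#'   count as attributes.
#' @examples
#' traj <- simulate_ode(decoy_params(), t_end = 300)
#' max(traj$N_n) / 1e5   # peak nuclear NF-kB in uM
#' @export
simulate_ode <- function(params, bins = NULL, initial = NULL,
                         t_end = 3000, dt_out = 0.5,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "decoy_params"))
  if (is.null(bins)) bins <- default_bins(params)
  if (t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  if (dt_out <= 0) stop("'dt_out' must be > 0", call. = FALSE)
  n <- nrow(bins)
  sp <- species_names(n)
  if (is.null(initial)) initial <- default_initial_state(params, bins)
  initial <- initial[sp]
  if (anyNA(initial)) stop("initial state is missing species", call. = FALSE)

  db_cols <- grep("^D_B_", sp, value = TRUE)
  y0 <- c(initial[c("N_n", "N_c", "I_n", "I_c", "NI_n", "NI_c", "mRNA", "ON",
                    "AD_U", "AD_B")], initial[db_cols])
  times <- seq(0, t_end, by = dt_out)
  parms <- pack_parms(params, bins)

  sol <- deSolve::vode(y = unname(y0), times = times, func = "derivs_decoy",
                       parms = parms, dllname = "nfkbdecoy",
                       initfunc = "initmod_decoy",
                       rtol = rtol, atol = atol, mf = 22L,
                       maxsteps = 100000L)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed at t = ", max(sol[, 1]),
         " min (istate = ", attr(sol, "istate")[1], ")", call. = FALSE)
  }
  red <- sol[, -1, drop = FALSE]

  neg <- red < 0
  n_clip <- sum(neg)
  if (n_clip > 0) {
    worst <- max(-red[neg])
    if (worst > 10 * atol) {
      stop("negative state values down to -", signif(worst, 3),
           " copies exceed the round-off clip limit", call. = FALSE)
    }
    warning("clipped ", n_clip, " negative round-off values (max magnitude ",
            signif(worst, 3), " copies) to zero", call. = FALSE)
    red[neg] <- 0
  }

  full <- matrix(0, nrow = nrow(red), ncol = length(sp),
                 dimnames = list(NULL, sp))
  full[, c("N_n", "N_c", "I_n", "I_c", "NI_n", "NI_c", "mRNA", "ON",
           "AD_U", "AD_B")] <- red[, 1:10]
  full[, "OFF"] <- params$G_total - red[, 8]
  du_cols <- grep("^D_U_", sp, value = TRUE)
  for (i in seq_len(n)) {
    full[, db_cols[i]] <- red[, 10 + i]
    full[, du_cols[i]] <- bins$count[i] - red[, 10 + i]
  }

  new_trajectory(tibble::as_tibble(cbind(time = times, as.data.frame(full))),
                 params = params, bins = bins, units = "copies",
                 n_clipped = n_clip)
}

new_trajectory <- function(df, params, bins, units, ...) {
  attr(df, "params") <- params
  attr(df, "bins") <- bins
  attr(df, "units") <- units
  extra <- list(...)
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("decoy_trajectory", class(df))
  df
}

#' Convert a trajectory between copies and uM
#'
#' Divides (or multiplies) every species column by the volume factor of the
#' trajectory's parameter snapshot and updates the units tag.
#'
#' @param traj A `decoy_trajectory`.
#' @param units Target units, `"uM"` or `"copies"`.
#' @return The converted trajectory.
#' @examples
#' traj <- simulate_ode(decoy_params(), t_end = 100)
#' head(trajectory_units(traj, "uM")$N_n)
#' @export
trajectory_units <- function(traj, units = c("uM", "copies")) {
  units <- match.arg(units)
  cur <- attr(traj, "units")
  if (cur == units) return(traj)
  om <- attr(traj, "params")$omega
  fac <- if (units == "uM") 1 / om else om
  sp <- setdiff(names(traj), "time")
  traj[sp] <- lapply(traj[sp], function(x) x * fac)
  attr(traj, "units") <- units
  traj
}

# Nuclear free NF-kB in uM, with the time grid, from any trajectory.
nn_uM <- function(traj) {
  om <- attr(traj, "params")$omega
  fac <- if (attr(traj, "units") == "uM") 1 else 1 / om
  list(time = traj$time, value = traj$N_n * fac)
}

#' @export
print.decoy_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<decoy_trajectory> %d time points to %g min (%s), %d species\n",
    nrow(x), max(x$time), attr(x, "units"), ncol(x) - 1L))
  if (!is.null(attr(x, "seed"))) {
    cat(sprintf("  stochastic: seed %d, %g events\n",
                attr(x, "seed"), attr(x, "n_events")))
  }
  cat(sprintf("  dose %g uM, k_soff %g, lambda_s %g, k_s %g, alpha %g\n",
              p$AD_dose / p$omega, p$k_soff, p$lambda_s, p$k_s, p$alpha))
  NextMethod()
}
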