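#' Default dosed initial condition
#'
#' The published starting state: the gene off, all genomic decoy sites
#' unbound, the entire NF-kB pool held in the cytoplasmic NF-kB-IkBa complex,
#' the full ODN dose unbound, and everything else empty. The long-time
#' behaviour of the circuit is a limit cycle, so the initial condition only
#' matters for transient observables such as the duration of action, which is
#' measured from this dosed state at t = 0.
#'
#' @param params A [decoy_params()] object.
#' @param bins A [build_decoy_bins()] object.
#' @return Named numeric vector over [species_names()], in copies.
#' @examples
#' s <- default_initial_state(decoy_params(AD_dose = 1e5), build_decoy_bins())
#' s[c("NI_c", "OFF", "AD_U")]
#' @export
default_initial_state <- function(params, bins) {
  stopifnot(inherits(params, "decoy_params"), inherits(bins, "decoy_bins"))
  if (sum(bins$count) != params$D_total) {
    stop("bins carry ", sum(bins$count), " sites but D_total is ",
         params$D_total, call. = FALSE)
  }
  sp <- species_names(nrow(bins))
  s <- stats::setNames(numeric(length(sp)), sp)
  s["OFF"] <- params$G_total
  s["NI_c"] <- params$N_total
  s["AD_U"] <- params$AD_dose
  s[grep("^D_U_", sp)] <- bins$count
  s
}

#' Limit-cycle state of the undosed circuit
#'
#' Integrates the circuit without synthetic ODNs from the default initial
#' condition long enough to settle on its limit cycle, and returns the final
#' state. Used to dose the running oscillator: pharmacodynamic time courses
#' start from this state with `AD_U` set to the dose.
#'
#' @param params A [decoy_params()] object (its `AD_dose` is ignored).
#' @param bins A [build_decoy_bins()] object.
#' @param t_burn Burn-in horizon in minutes (default 3000).
#' @param dt_out Output step of the burn-in integration (default 0.5 min;
#'   also sets the phase resolution of the returned state).
#' @return Named state vector (copies) on the limit cycle.
#' @examples
#' \donttest{
#' s <- equilibrium_state(decoy_params(), build_decoy_bins())
#' s["N_n"]
#' }
#' @export
equilibrium_state <- function(params, bins, t_burn = 3000, dt_out = 0.5) {
  p0 <- update_params(params, AD_dose = 0)
  tr <- simulate_ode(p0, bins, t_end = t_burn, dt_out = dt_out)
  s <- unlist(tr[nrow(tr), setdiff(names(tr), "time")])
  s
}

#' Dose a state with synthetic ODNs
#'
#' Returns `state` with the unbound ODN pool set to `AD_dose` copies and the
#' bound pool to zero (the dose is delivered unbound at t = 0).
#'
#' @param state Named state vector.
#' @param AD_dose Dose in copies.
#' @return The dosed state.
#' @examples
#' p <- decoy_params(); b <- build_decoy_bins()
#' dose_state(default_initial_state(p, b), 1e5)[["AD_U"]]
#' @export
dose_state <- function(state, AD_dose) {
  state["AD_U"] <- AD_dose
  state["AD_B"] <- 0
  state
}

#' Conservation sums of a state
#'
#' Returns the three conserved totals of the network: NF-kB copies (free,
#' complexed or bound anywhere), gene copies, and per-bin decoy site counts.
#'
#' @param state Named state vector (copies).
#' @param n_bins Number of decoy bins in the state.
#' @return List with `nfkb`, `gene` and `decoy_sites` (vector per bin).
#' @examples
#' p <- decoy_params(); b <- build_decoy_bins()
#' conservation_totals(default_initial_state(p, b), nrow(b))$nfkb
#' @export
conservation_totals <- function(state, n_bins) {
  sp <- names(state)
  du <- grep("^D_U_", sp)
  db <- grep("^D_B_", sp)
  list(
    nfkb = sum(state[nfkb_species(n_bins)]),
    gene = unname(state["ON"] + state["OFF"]),
    decoy_sites = unname(state[du] + state[db])
  )
}
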