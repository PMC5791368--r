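#' Model parameters for the NF-kB decoy circuit
#'
#' Builds the full parameter set of the minimal IkBa/NF-kB negative-feedback
#' circuit with genomic decoy sites and synthetic decoy ODNs. Defaults are the
#' published rate constants of the feedback cycle; doses and kinetic ranges of
#' the synthetic ODNs are the tunable pharmacological inputs.
#'
#' All bimolecular rate constants are given in uM^-1 min^-1 and first-order
#' constants in min^-1. Simulation is carried out in copy numbers: bimolecular
#' constants are divided by the volume factor `omega` (copies per uM) and the
#' transcription rate, given in uM min^-1 per active promoter, is multiplied
#' by `omega`. Outputs are converted back to uM on request.
#'
#' @param k_on,k_don,k_son Binding of nuclear NF-kB to the IkBa promoter,
#'   genomic decoy sites and synthetic decoy ODNs (uM^-1 min^-1). Binding is
#'   taken as diffusion-limited and uniform across site classes (default 10).
#' @param k_off Promoter unbinding rate (min^-1, default 1); sets the
#'   oscillation period of the circuit.
#' @param k_soff Synthetic-ODN unbinding rate (min^-1, default 1; the
#'   pharmacologically interesting range is 0.02-20).
#' @param lambda_s Nuclease degradation rate of synthetic ODNs, acting on both
#'   bound and unbound molecules (min^-1, range 0-0.02, default 0).
#' @param k_s Molecular stripping rate: IkBa-induced dissociation of NF-kB
#'   from any bound site, producing the nuclear NF-kB-IkBa complex directly
#'   (uM^-1 min^-1, range 0-10, default 10).
#' @param k_tr Transcription rate per active promoter (uM min^-1, default 1.03).
#' @param k_tl Translation rate (min^-1, default 0.2448).
#' @param k_d mRNA degradation rate (min^-1, default 0.017).
#' @param k_in,k_out IkBa nuclear import/export (min^-1, defaults 0.018/0.012).
#'   Also accepted under the aliases `k_Iin`/`k_Iout`.
#' @param k_Nin NF-kB nuclear import (min^-1, default 5.4).
#' @param k_NIout Nuclear export of the NF-kB-IkBa complex (min^-1, default 0.83).
#' @param k_f,k_fn NF-kB-IkBa association in cytoplasm/nucleus
#'   (uM^-1 min^-1, defaults 30/30).
#' @param k_b,k_bn Complex dissociation in cytoplasm/nucleus (min^-1, 0.03/0.03).
#' @param alpha IkBa degradation within the cytoplasmic complex, releasing
#'   free cytoplasmic NF-kB (min^-1, published range 0.10-0.55, default 0.55).
#' @param delta_G_hat Mean of ln(k_doff) for the genomic-decoy unbinding-rate
#'   spectrum (dimensionless, default 0).
#' @param sigma Standard deviation of ln(k_doff) (default 1).
#' @param N_total Total NF-kB copies (default 1e5).
#' @param D_total Total genomic decoy sites (default 2e4).
#' @param G_total IkBa gene copies (default 1).
#' @param AD_dose Synthetic ODN dose in copies (0 to 2e5, default 0). A dose of
#'   `omega` copies is 1 uM.
#' @param omega Volume factor, copies per uM (default 1e5).
#' @param bound_degradation What nuclease degradation does to a bound ODN.
#'   `"release"` (default): the bound ODN degrades at `lambda_s` and its
#'   NF-kB returns to the free nuclear pool, so the total ODN pool decays
#'   exactly exponentially and NF-kB is conserved. `"none"`: NF-kB-bound
#'   ODNs are protected from nuclease attack (only the unbound pool
#'   degrades); NF-kB is conserved, and clearance of a high-affinity dose
#'   becomes unbinding-limited. `"destroy"`: the literal bookkeeping in
#'   which the bound complex is removed wholesale, silently destroying its
#'   NF-kB; kept for comparison only.
#' @param ... Additional named values; accepted alias names are `k_Iin` and
#'   `k_Iout`. Unknown names are an error.
#'
#' @return A list of class `decoy_params`.
#' @examples
#' p <- decoy_params(AD_dose = 1e5, k_soff = 0.02, lambda_s = 0.001)
#' p$k_off
#' @export
decoy_params <- function(k_on = 10, k_don = 10, k_son = 10,
                         k_off = 1, k_soff = 1,
                         lambda_s = 0, k_s = 10,
                         k_tr = 1.03, k_tl = 0.2448, k_d = 0.017,
                         k_in = 0.018, k_out = 0.012,
                         k_Nin = 5.4, k_NIout = 0.83,
                         k_f = 30, k_fn = 30, k_b = 0.03, k_bn = 0.03,
                         alpha = 0.55,
                         delta_G_hat = 0, sigma = 1,
                         N_total = 1e5, D_total = 2e4, G_total = 1,
                         AD_dose = 0, omega = 1e5,
                         bound_degradation = c("release", "none", "destroy"),
                         ...) {
  bound_degradation <- match.arg(bound_degradation)
  dots <- list(...)
  aliases <- c(k_Iin = "k_in", k_Iout = "k_out")
  for (nm in names(dots)) {
    if (nm %in% names(aliases)) {
      assign(aliases[[nm]], dots[[nm]])
    } else {
      stop("unknown parameter: '", nm, "'", call. = FALSE)
    }
  }
  p <- list(
    k_on = k_on, k_don = k_don, k_son = k_son,
    k_off = k_off, k_soff = k_soff,
    lambda_s = lambda_s, k_s = k_s,
    k_tr = k_tr, k_tl = k_tl, k_d = k_d,
    k_in = k_in, k_out = k_out,
    k_Nin = k_Nin, k_NIout = k_NIout,
    k_f = k_f, k_fn = k_fn, k_b = k_b, k_bn = k_bn,
    alpha = alpha,
    delta_G_hat = delta_G_hat, sigma = sigma,
    N_total = N_total, D_total = D_total, G_total = G_total,
    AD_dose = AD_dose, omega = omega,
    bound_degradation = bound_degradation
  )
  class(p) <- "decoy_params"
  validate_params(p)
  p
}

rate_names <- c("k_on", "k_don", "k_son", "k_off", "k_soff", "lambda_s",
                "k_s", "k_tr", "k_tl", "k_d", "k_in", "k_out", "k_Nin",
                "k_NIout", "k_f", "k_fn", "k_b", "k_bn", "alpha")

count_names <- c("N_total", "D_total", "G_total", "AD_dose")

validate_params <- function(p) {
  for (nm in rate_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("parameter '", nm, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (!is.numeric(p$sigma) || p$sigma <= 0) {
    stop("parameter 'sigma' must be > 0", call. = FALSE)
  }
  for (nm in count_names) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        abs(v - round(v)) > 1e-8) {
      stop("parameter '", nm, "' must be a single non-negative integer",
           call. = FALSE)
    }
  }
  if (!is.numeric(p$omega) || p$omega <= 0) {
    stop("parameter 'omega' must be > 0", call. = FALSE)
  }
  if (!p$bound_degradation %in% c("release", "none", "destroy")) {
    stop("'bound_degradation' must be \"release\", \"none\" or \"destroy\"",
         call. = FALSE)
  }
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named values replaced, re-validated.
#'
#' @param params A [decoy_params()] object.
#' @param ... Named replacement values (aliases `k_Iin`/`k_Iout` accepted).
#' @return A `decoy_params` object.
#' @examples
#' update_params(decoy_params(), k_soff = 0.02, AD_dose = 1e5)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "decoy_params"))
  dots <- list(...)
  aliases <- c(k_Iin = "k_in", k_Iout = "k_out")
  for (nm in names(dots)) {
    canon <- if (nm %in% names(aliases)) aliases[[nm]] else nm
    if (!canon %in% names(params)) {
      stop("unknown parameter: '", nm, "'", call. = FALSE)
    }
    params[[canon]] <- dots[[nm]]
  }
  validate_params(params)
  params
}

#' Rescale a parameter set to a different system volume
#'
#' Changes the volume factor `omega` (copies per uM) while preserving all
#' concentrations: the copy-number totals `N_total`, `D_total` and `AD_dose`
#' are scaled by the volume ratio (gene copies stay fixed), and all rate
#' constants are untouched since they are stored in concentration units.
#' Used to run stochastic simulations at reduced copy numbers.
#'
#' @param params A [decoy_params()] object.
#' @param omega New volume factor (copies per uM).
#' @return A `decoy_params` object.
#' @examples
#' scale_volume(decoy_params(AD_dose = 1e5), omega = 1e3)$AD_dose
#' @export
scale_volume <- function(params, omega) {
  stopifnot(inherits(params, "decoy_params"), is.numeric(omega), omega > 0)
  ratio <- omega / params$omega
  params$N_total <- round(params$N_total * ratio)
  params$D_total <- round(params$D_total * ratio)
  params$AD_dose <- round(params$AD_dose * ratio)
  params$omega <- omega
  validate_params(params)
  params
}

#' @export
print.decoy_params <- function(x, ...) {
  cat("<decoy_params>\n")
  cat("  rates (uM^-1 min^-1 or min^-1):\n")
  for (nm in rate_names) cat(sprintf("    %-10s %g\n", nm, x[[nm]]))
  cat(sprintf("  decoy spectrum: ln k_doff ~ Normal(%g, %g^2)\n",
              x$delta_G_hat, x$sigma))
  cat(sprintf("  totals: N = %g, D = %g, gene = %g, ODN dose = %g copies\n",
              x$N_total, x$D_total, x$G_total, x$AD_dose))
  cat(sprintf("  volume factor omega = %g copies/uM (dose = %g uM)\n",
              x$omega, x$AD_dose / x$omega))
  cat(sprintf("  bound-ODN degradation: %s\n", x$bound_degradation))
  invisible(x)
}
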