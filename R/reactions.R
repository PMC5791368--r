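#' Species names of the reaction network
#'
#' Fixed ordering used by both simulators: the eleven bulk species followed by
#' the unbound and then bound genomic-decoy pools, one per spectrum bin.
#'
#' @param n_bins Number of decoy bins.
#' @return Character vector of species names.
#' @examples
#' species_names(3)
#' @export
species_names <- function(n_bins) {
  w <- max(2L, nchar(as.character(n_bins)))
  idx <- formatC(seq_len(n_bins), width = w, flag = "0")
  c("N_n", "N_c", "I_n", "I_c", "NI_n", "NI_c", "mRNA", "ON", "OFF",
    "AD_U", "AD_B", paste0("D_U_", idx), paste0("D_B_", idx))
}

# Species carrying an NF-kB molecule (free, complexed, or site-bound).
nfkb_species <- function(n_bins) {
  w <- max(2L, nchar(as.character(n_bins)))
  idx <- formatC(seq_len(n_bins), width = w, flag = "0")
  c("N_n", "N_c", "NI_n", "NI_c", "ON", "AD_B", paste0("D_B_", idx))
}

#' Build the reaction set of the decoy circuit
#'
#' Enumerates every elementary reaction of the IkBa/NF-kB feedback circuit
#' with genomic decoys and synthetic decoy ODNs: promoter binding/unbinding
#' and stripping, transcription, translation, mRNA decay, IkBa and NF-kB
#' transport, association/dissociation in both compartments, alpha-degradation
#' of the cytoplasmic complex, the five ODN reactions (bind, unbind, strip,
#' degrade unbound, degrade bound) and three reactions (bind, unbind, strip)
#' per decoy-spectrum bin. Rate constants are stored in copy-number units:
#' bimolecular constants divided by `omega`, the transcription rate multiplied
#' by `omega`.
#'
#' @param params A [decoy_params()] object.
#' @param bins A [build_decoy_bins()] object.
#' @return A tibble of class `decoy_reactions` with columns `name`,
#'   `rate_name`, `rate` (copy units), `order` and list-columns `reactants`
#'   and `products` (named integer stoichiometries).
#' @examples
#' rxns <- build_reactions(decoy_params(), build_decoy_bins(n_bins = 15))
#' nrow(rxns)   # 15 bulk + 5 ODN + 3 * 15 decoy-bin reactions = 65
#' @export
build_reactions <- function(params, bins) {
  stopifnot(inherits(params, "decoy_params"), inherits(bins, "decoy_bins"))
  p <- params
  om <- p$omega
  n <- nrow(bins)
  sp <- species_names(n)
  w <- max(2L, nchar(as.character(n)))
  idx <- formatC(seq_len(n), width = w, flag = "0")

  rxn <- function(name, rate_name, rate, reactants, products) {
    tibble::tibble(
      name = name, rate_name = rate_name, rate = rate,
      order = sum(reactants),
      reactants = list(reactants), products = list(products)
    )
  }

  bulk <- dplyr::bind_rows(
    rxn("promoter_bind", "k_on", p$k_on / om,
        c(N_n = 1L, OFF = 1L), c(ON = 1L)),
    rxn("promoter_unbind", "k_off", p$k_off,
        c(ON = 1L), c(N_n = 1L, OFF = 1L)),
    rxn("promoter_strip", "k_s", p$k_s / om,
        c(ON = 1L, I_n = 1L), c(OFF = 1L, NI_n = 1L)),
    rxn("transcription", "k_tr", p$k_tr * om,
        c(ON = 1L), c(ON = 1L, mRNA = 1L)),
    rxn("translation", "k_tl", p$k_tl,
        c(mRNA = 1L), c(mRNA = 1L, I_c = 1L)),
    rxn("mrna_decay", "k_d", p$k_d, c(mRNA = 1L), integer()),
    rxn("ikb_import", "k_in", p$k_in, c(I_c = 1L), c(I_n = 1L)),
    rxn("ikb_export", "k_out", p$k_out, c(I_n = 1L), c(I_c = 1L)),
    rxn("nfkb_import", "k_Nin", p$k_Nin, c(N_c = 1L), c(N_n = 1L)),
    rxn("assoc_cyt", "k_f", p$k_f / om,
        c(N_c = 1L, I_c = 1L), c(NI_c = 1L)),
    rxn("dissoc_cyt", "k_b", p$k_b, c(NI_c = 1L), c(N_c = 1L, I_c = 1L)),
    rxn("assoc_nuc", "k_fn", p$k_fn / om,
        c(N_n = 1L, I_n = 1L), c(NI_n = 1L)),
    rxn("dissoc_nuc", "k_bn", p$k_bn, c(NI_n = 1L), c(N_n = 1L, I_n = 1L)),
    rxn("complex_export", "k_NIout", p$k_NIout,
        c(NI_n = 1L), c(NI_c = 1L)),
    rxn("ikb_degradation", "alpha", p$alpha, c(NI_c = 1L), c(N_c = 1L))
  )

  odn <- dplyr::bind_rows(
    rxn("odn_bind", "k_son", p$k_son / om,
        c(AD_U = 1L, N_n = 1L), c(AD_B = 1L)),
    rxn("odn_unbind", "k_soff", p$k_soff,
        c(AD_B = 1L), c(AD_U = 1L, N_n = 1L)),
    rxn("odn_strip", "k_s", p$k_s / om,
        c(AD_B = 1L, I_n = 1L), c(AD_U = 1L, NI_n = 1L)),
    rxn("odn_degrade_unbound", "lambda_s", p$lambda_s,
        c(AD_U = 1L), integer()),
    rxn("odn_degrade_bound", "lambda_s",
        if (p$bound_degradation == "none") 0 else p$lambda_s,
        c(AD_B = 1L),
        if (p$bound_degradation == "release") c(N_n = 1L) else integer())
  )

  decoy <- purrr::map_dfr(seq_len(n), function(i) {
    du <- paste0("D_U_", idx[i]); db <- paste0("D_B_", idx[i])
    dplyr::bind_rows(
      rxn(paste0("decoy_bind_", idx[i]), "k_don", p$k_don / om,
          stats::setNames(c(1L, 1L), c(du, "N_n")),
          stats::setNames(1L, db)),
      rxn(paste0("decoy_unbind_", idx[i]), "k_doff", bins$k_doff[i],
          stats::setNames(1L, db),
          stats::setNames(c(1L, 1L), c(du, "N_n"))),
      rxn(paste0("decoy_strip_", idx[i]), "k_s", p$k_s / om,
          stats::setNames(c(1L, 1L), c(db, "I_n")),
          stats::setNames(c(1L, 1L), c(du, "NI_n")))
    )
  })

  out <- dplyr::bind_rows(bulk, odn, decoy)
  attr(out, "species") <- sp
  attr(out, "n_bins") <- n
  class(out) <- c("decoy_reactions", class(out))
  out
}

#' Compile a reaction set to matrix form
#'
#' Converts a [build_reactions()] tibble into the flat arrays used by the
#' stochastic simulator and by the reaction-route derivative: the
#' stoichiometry matrix (species x reactions), copy-unit rate constants,
#' reaction orders and reactant indices.
#'
#' @param reactions A `decoy_reactions` tibble.
#' @return A list with elements `species`, `stoich`, `rate`, `order`, `r1`,
#'   `r2` (1-based reactant indices, `NA` where absent).
#' @examples
#' net <- compile_network(build_reactions(decoy_params(), build_decoy_bins()))
#' dim(net$stoich)
#' @export
compile_network <- function(reactions) {
  stopifnot(inherits(reactions, "decoy_reactions"))
  sp <- attr(reactions, "species")
  S <- length(sp)
  R <- nrow(reactions)
  stoich <- matrix(0L, nrow = S, ncol = R,
                   dimnames = list(sp, reactions$name))
  r1 <- rep(NA_integer_, R)
  r2 <- rep(NA_integer_, R)
  for (j in seq_len(R)) {
    re <- reactions$reactants[[j]]
    pr <- reactions$products[[j]]
    for (nm in names(re)) stoich[nm, j] <- stoich[nm, j] - re[[nm]]
    for (nm in names(pr)) stoich[nm, j] <- stoich[nm, j] + pr[[nm]]
    ri <- match(names(re), sp)
    if (length(ri) >= 1L) r1[j] <- ri[1L]
    if (length(ri) >= 2L) r2[j] <- ri[2L]
  }
  list(species = sp, stoich = stoich, rate = reactions$rate,
       order = reactions$order, r1 = r1, r2 = r2)
}

#' Reaction propensities at a state
#'
#' Mass-action propensities, one per reaction, in events per minute:
#' `rate * x[r1]` for first-order and `rate * x[r1] * x[r2]` for bimolecular
#' reactions (rates already in copy units). Summing stoichiometry times
#' propensity over reactions reproduces the deterministic derivative, so the
#' stochastic and deterministic simulators share one kinetic law.
#'
#' @param state Named state vector in copies (see [default_initial_state()]).
#' @param params A [decoy_params()] object.
#' @param bins A [build_decoy_bins()] object.
#' @param network Optional pre-compiled network (from [compile_network()]);
#'   computed from `params`/`bins` if missing.
#' @return Named numeric vector of propensities (min^-1).
#' @examples
#' p <- decoy_params(); b <- build_decoy_bins()
#' a <- propensities(default_initial_state(p, b), p, b)
#' a[a > 0]
#' @export
propensities <- function(state, params, bins, network = NULL) {
  if (is.null(network)) network <- compile_network(build_reactions(params, bins))
  x <- as.numeric(state[network$species])
  a <- network$rate * x[network$r1]
  two <- !is.na(network$r2)
  a[two] <- a[two] * x[network$r2[two]]
  stats::setNames(a, colnames(network$stoich))
}
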