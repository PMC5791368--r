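#' Discretize the genomic-decoy unbinding-rate spectrum
#'
#' The unbinding rates of the genomic decoy sites follow a log-normal
#' distribution, `ln(k_doff) ~ Normal(delta_G_hat, sigma^2)`, reflecting the
#' spread of binding free energies of NF-kB genomic sites. For simulation the
#' continuous spectrum is approximated by a histogram: `n_bins` equal-width
#' bins in ln-space spanning `delta_G_hat +/- span_in_sigmas * sigma`, each
#' carrying the Gaussian probability mass of the bin renormalized over the
#' span, converted to integer site counts by largest-remainder rounding so the
#' counts sum to `D_total` exactly. Each bin unbinds at the rate given by its
#' ln-midpoint.
#'
#' @param delta_G_hat Mean of ln(k_doff) (dimensionless, default 0).
#' @param sigma Standard deviation of ln(k_doff) (> 0, default 1).
#' @param n_bins Number of histogram bins (>= 1, default 15).
#' @param span_in_sigmas Half-width of the covered ln-range in units of
#'   `sigma` (default 3).
#' @param D_total Total number of genomic decoy sites (>= 1, default 2e4).
#'
#' @return A tibble of class `decoy_bins` with one row per bin and columns
#'   `bin`, `log_midpoint` (ln k_doff), `k_doff` (min^-1) and `count`
#'   (integer sites). The total `D_total` and the generating parameters are
#'   stored as attributes.
#' @examples
#' bins <- build_decoy_bins(n_bins = 15)
#' sum(bins$count)          # exactly D_total
#' exp(median(rep(bins$log_midpoint, bins$count)))  # ~ 1 min^-1
#' @export
build_decoy_bins <- function(delta_G_hat = 0, sigma = 1, n_bins = 15,
                             span_in_sigmas = 3, D_total = 2e4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(D_total) || length(D_total) != 1L || D_total < 1) {
    stop("'D_total' must be >= 1", call. = FALSE)
  }
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 1) {
    stop("'n_bins' must be >= 1", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  D_total <- round(D_total)

  lo <- delta_G_hat - span_in_sigmas * sigma
  hi <- delta_G_hat + span_in_sigmas * sigma
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2

  mass <- stats::pnorm(edges[-1L], delta_G_hat, sigma) -
    stats::pnorm(edges[-(n_bins + 1L)], delta_G_hat, sigma)
  mass <- mass / sum(mass)                 # renormalize over the span

  counts <- largest_remainder_round(mass * D_total, D_total)

  out <- tibble::tibble(
    bin = seq_len(n_bins),
    log_midpoint = mids,
    k_doff = exp(mids),
    count = counts
  )
  attr(out, "D_total") <- D_total
  attr(out, "delta_G_hat") <- delta_G_hat
  attr(out, "sigma") <- sigma
  attr(out, "span_in_sigmas") <- span_in_sigmas
  class(out) <- c("decoy_bins", class(out))
  out
}

# Round non-negative reals to integers summing exactly to `total`:
# floor everything, then hand out the remaining units to the largest
# fractional parts (ties broken by position).
largest_remainder_round <- function(x, total) {
  stopifnot(all(x >= 0), abs(sum(x) - total) < 1e-6)
  fl <- floor(x)
  rem <- as.integer(round(total - sum(fl)))
  out <- as.integer(fl)
  if (rem > 0L) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1L
  }
  out
}

default_bins <- function(params, n_bins = 15, span_in_sigmas = 3) {
  build_decoy_bins(params$delta_G_hat, params$sigma, n_bins,
                   span_in_sigmas, params$D_total)
}
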