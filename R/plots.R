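#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory
#'
#' Time courses of selected species, in uM by default.
#'
#' @param object A `decoy_trajectory`.
#' @param species Species to show (default free nuclear NF-kB and the total
#'   remaining ODN pool).
#' @param units `"uM"` (default) or `"copies"`.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' autoplot(simulate_ode(decoy_params(), t_end = 500))
#' @export
autoplot.decoy_trajectory <- function(object, species = c("N_n", "AD_U", "AD_B"),
                                      units = "uM", ...) {
  traj <- trajectory_units(object, units)
  species <- intersect(species, names(traj))
  long <- tidyr::pivot_longer(traj[, c("time", species)],
                              -"time", names_to = "species")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)",
                  y = if (units == "uM") "concentration (uM)" else "copies") +
    ggplot2::theme_minimal()
}

#' Plot a dephasing fit
#'
#' The normalized autocorrelation with its envelope points and the fitted
#' exponential decay.
#'
#' @param object A `dephasing_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' sig <- exp(-(0:2999) / 200) * cos(2 * pi * (0:2999) / 100)
#' autoplot(dephasing_time(normalized_autocorrelation(sig, 1500), dt = 1))
#' @export
autoplot.dephasing_fit <- function(object, ...) {
  ggplot2::ggplot(object$acf, ggplot2::aes(.data$time, .data$acf)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(data = object$envelope,
                        ggplot2::aes(.data$time, .data$value),
                        colour = "firebrick") +
    ggplot2::geom_function(fun = function(t) exp(-t / object$tau_phi),
                           colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "lag (min)", y = "normalized ACF",
                  subtitle = sprintf("tau_phi = %.1f min, T = %.1f min%s",
                                     object$tau_phi, object$period,
                                     if (object$capped) " (capped)" else "")) +
    ggplot2::theme_minimal()
}

#' Heatmap of a scan surface
#'
#' A dose x unbinding-rate (or degradation x unbinding-rate) heatmap of a
#' scan result, faceted by stripping rate.
#'
#' @param scan A scan tibble.
#' @param x,y Column names for the axes (defaults `"dose_uM"`, `"k_soff"`).
#' @return A ggplot.
#' @examples
#' \donttest{
#' plot_scan_surface(scan_peak_amplitude(dose_uM = c(0, 1, 2),
#'                                       k_soff = c(0.02, 1)))
#' }
#' @export
plot_scan_surface <- function(scan, x = "dose_uM", y = "k_soff") {
  ggplot2::ggplot(scan, ggplot2::aes(.data[[x]], .data[[y]],
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~k_s, labeller = ggplot2::label_both) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = unique(scan$observable)) +
    ggplot2::theme_minimal()
}

#' Dose-response curves of the duration of action
#'
#' @param scan A [dose_response()] tibble.
#' @return A ggplot.
#' @examples
#' \donttest{
#' plot_dose_response(dose_response(dose_uM = c(0.5, 1, 2),
#'                                  lambda_s = 0.005, k_soff = 1, k_s = 0))
#' }
#' @export
plot_dose_response <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(.data$dose_uM, .data$value,
                                     colour = factor(.data$lambda_s),
                                     linetype = factor(.data$k_soff))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~k_s, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "dose (uM)", y = "duration of action (min)",
                  colour = "lambda_s", linetype = "k_soff") +
    ggplot2::theme_minimal()
}
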