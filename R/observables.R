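#' Peak nuclear NF-kB amplitude
#'
#' Maximum of the free nuclear NF-kB concentration over the post-burn-in
#' window `(burn_in, horizon]`, in uM. On the limit cycle this is the
#' steady-state oscillation amplitude; the burn-in discards the approach from
#' the dosed initial condition.
#'
#' @param traj A `decoy_trajectory`.
#' @param burn_in Burn-in in minutes (default 500).
#' @return Peak concentration (uM), a single number.
#' @examples
#' peak_amplitude(simulate_ode(decoy_params(), t_end = 1500), burn_in = 500)
#' @export
peak_amplitude <- function(traj, burn_in = 500) {
  s <- nn_uM(traj)
  keep <- s$time > burn_in
  if (!any(keep)) {
    stop("trajectory horizon (", max(s$time),
         " min) does not exceed the burn-in (", burn_in, " min)",
         call. = FALSE)
  }
  max(s$value[keep])
}

#' Duration of action of a decoy dose
#'
#' The timespan, measured from the dosed initial condition at t = 0, during
#' which free nuclear NF-kB stays below a therapeutic threshold: the first
#' time the concentration up-crosses the threshold, located by linear
#' interpolation between grid points. If the signal never crosses within the
#' horizon, the horizon is returned with `capped = TRUE`.
#'
#' @param traj A `decoy_trajectory` starting at the dosing time.
#' @param threshold Threshold concentration in uM (> 0, default 0.1).
#' @return One-row tibble with `duration` (min) and `capped`.
#' @examples
#' p <- decoy_params(AD_dose = 1e5, k_soff = 1, lambda_s = 0.005, k_s = 0)
#' duration_of_action(simulate_ode(p, t_end = 1500))
#' @export
duration_of_action <- function(traj, threshold = 0.1) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("'threshold' must be > 0", call. = FALSE)
  }
  s <- nn_uM(traj)
  above <- s$value > threshold
  if (above[1]) {
    return(tibble::tibble(duration = 0, capped = FALSE))
  }
  i <- which(above)[1]
  if (is.na(i)) {
    return(tibble::tibble(duration = max(s$time), capped = TRUE))
  }
  t0 <- s$time[i - 1]; t1 <- s$time[i]
  v0 <- s$value[i - 1]; v1 <- s$value[i]
  tibble::tibble(
    duration = t0 + (threshold - v0) / (v1 - v0) * (t1 - t0),
    capped = FALSE
  )
}

#' Normalized autocorrelation of a uniformly sampled signal
#'
#' Mean-subtracted, variance-normalized autocorrelation with the biased (1/n)
#' normalization, which keeps the estimator stable at large lags;
#' `acf[lag = 0]` is exactly 1.
#'
#' @param signal Numeric vector sampled on a uniform grid.
#' @param max_lag Largest lag in samples; the signal must be at least twice
#'   this long. Defaults to `floor(length(signal) / 2)`.
#' @return Tibble with `lag` (0..max_lag, in samples) and `acf`.
#' @examples
#' normalized_autocorrelation(cos(2 * pi * (0:999) / 100), max_lag = 200)
#' @export
normalized_autocorrelation <- function(signal, max_lag = floor(length(signal) / 2)) {
  n <- length(signal)
  if (n < 2 * max_lag) {
    stop("signal length (", n, ") must be at least twice max_lag (",
         max_lag, ")", call. = FALSE)
  }
  if (stats::var(signal) == 0) {
    stop("signal has zero variance; autocorrelation undefined", call. = FALSE)
  }
  a <- stats::acf(signal, lag.max = max_lag, plot = FALSE, demean = TRUE)
  out <- tibble::tibble(lag = 0:max_lag, acf = as.numeric(a$acf))
  attr(out, "n_signal") <- n
  out
}

#' Dephasing time from an autocorrelation envelope
#'
#' Coherence of the oscillation is quantified by fitting the decaying
#' envelope of the normalized autocorrelation: the ACF of a noisy oscillator
#' behaves as `exp(-t / tau_phi) * cos(2 * pi * t / T)`, and `tau_phi` (the
#' dephasing time) is the least-squares decay constant of `A * exp(-t / tau)`
#' fitted to the envelope traced by the ACF maxima around successive period
#' multiples (the lag-0 point is excluded: it carries the white-noise
#' variance spike). The period `T` comes from the dominant spectral peak of
#' the ACF, refined by the zero-crossing spacing.
#'
#' Capping: the biased (1/n) ACF estimator decays by the deterministic factor
#' `(1 - lag/n)` even for a perfectly coherent signal; if, after removing
#' that taper, the envelope decays by less than 10% across the lag window,
#' the decay is unresolved and `tau_phi` is reported as the window length
#' with `capped = TRUE`.
#'
#' When fewer than two envelope peaks rise above the ACF noise floor
#' (`2/sqrt(n)`), the envelope is unfittable and the function falls back to
#' the `"direct"` method: nonlinear least squares of the damped cosine on the
#' full ACF, which is also available explicitly as a cross-check.
#'
#' @param acf Tibble from [normalized_autocorrelation()].
#' @param dt Sampling interval of the underlying signal (minutes).
#' @param method `"envelope"` (default) or `"direct"`.
#' @return A `dephasing_fit` object: `tau_phi` (min), `period` (min),
#'   `residual` (RMS of the fit), `method` (as actually used), `capped`, and
#'   the envelope points.
#' @examples
#' t <- 0:2999
#' sig <- exp(-t / 200) * cos(2 * pi * t / 100)
#' dephasing_time(normalized_autocorrelation(sig, 1500), dt = 1)
#' @export
dephasing_time <- function(acf, dt, method = c("envelope", "direct")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(acf), all(c("lag", "acf") %in% names(acf)))
  rho <- acf$acf
  tt <- acf$lag * dt
  max_lag_t <- max(tt)
  n_sig <- attr(acf, "n_signal")

  T0 <- acf_period(rho, dt)

  # envelope: walk the ACF peak to peak, one peak per cycle, so that slow
  # period wander (phase diffusion) cannot push later peaks out of fixed
  # windows anchored at multiples of a single global period
  m <- length(rho)
  locmax <- 1 + which(rho[2:(m - 1)] >= rho[1:(m - 2)] &
                        rho[2:(m - 1)] >= rho[3:m])
  env_t <- numeric()
  env_v <- numeric()
  t_prev <- 0
  repeat {
    cand <- locmax[tt[locmax] > t_prev + 0.55 * T0]
    if (length(cand) == 0) break
    win <- cand[tt[cand] <= t_prev + 1.45 * T0]
    i <- if (length(win) > 0) win[which.max(rho[win])] else cand[1]
    env_t <- c(env_t, tt[i])
    env_v <- c(env_v, rho[i])
    t_prev <- tt[i]
  }
  if (length(env_t) < 3) {
    stop("fewer than 3 envelope peaks: signal is not sufficiently oscillatory",
         call. = FALSE)
  }
  period <- stats::median(diff(env_t))

  # taper-corrected peaks decide whether any decay is resolvable at all
  corr <- if (is.null(n_sig)) rep(1, length(env_t)) else 1 - env_t / (n_sig * dt)
  env_c <- env_v / corr
  # robust noise floor of the ACF. White measurement noise shows up as
  # lag-to-lag jitter of the ACF (whereas the intrinsic noise of a stochastic
  # oscillator is band-limited and leaves the ACF smooth); the jitter scale,
  # inflated for the correlation between neighbouring ACF lags, bounds the
  # size of spurious envelope peaks.
  floor_v <- max(1e-4, 5 * stats::mad(diff(rho)))

  if (env_v[1] < floor_v) {
    # no coherent first-period peak: the signal does not oscillate above the
    # ACF noise floor
    stop("signal is not sufficiently oscillatory: first autocorrelation peak ",
         "is below the noise floor", call. = FALSE)
  }

  capped <- FALSE
  if (min(env_c) > 0.9 * env_c[1]) {
    fit <- list(tau = max_lag_t, resid = NA_real_)
    capped <- TRUE
  } else if (method == "envelope") {
    # fit the consecutive run of peaks above the noise floor; a noisy ACF
    # needs one extra peak before the envelope slope is trustworthy
    run <- cumprod(env_v > floor_v) == 1
    min_peaks <- if (floor_v <= 6e-3) 2L else 3L
    if (sum(run) >= min_peaks) {
      fit <- fit_exp_decay(env_t[run], env_v[run])
    } else {
      method <- "direct"
      fit <- fit_damped_cosine(tt, rho, period_init = period)
      period <- fit$period
    }
  } else {
    fit <- fit_damped_cosine(tt, rho, period_init = period)
    period <- fit$period
  }
  if (!capped && fit$tau > max_lag_t) {
    # decay slower than the lag window can resolve
    fit$tau <- max_lag_t
    capped <- TRUE
  }

  structure(
    list(tau_phi = fit$tau, period = period, residual = fit$resid,
         method = method, capped = capped,
         envelope = tibble::tibble(time = env_t, value = env_v),
         acf = tibble::tibble(time = tt, acf = rho)),
    class = "dephasing_fit"
  )
}

# Dominant period of an ACF: periodogram peak (parabolically interpolated),
# refined by the median spacing of the ACF's zero crossings, which for a
# damped cosine sit exactly at the cosine zeros and are insensitive to the
# envelope.
acf_period <- function(rho, dt) {
  m <- length(rho)
  pw <- Mod(stats::fft(rho - mean(rho)))^2
  half <- pw[2:floor(m / 2)]
  k <- which.max(half) + 1L           # 1-based fft bin (k=1 is DC)
  logp <- function(i) log(pw[i] + 1e-300)
  delta <- 0
  if (k > 2 && k < floor(m / 2)) {
    a <- logp(k - 1); b <- logp(k); c <- logp(k + 1)
    den <- a - 2 * b + c
    if (den < 0) delta <- 0.5 * (a - c) / den
  }
  T0 <- m * dt / (k - 1 + delta)

  # spiky waveforms put most power in a harmonic; if the ACF is larger around
  # 2 T0 than around T0, the spectral peak was an overtone
  tt <- (seq_len(m) - 1) * dt
  win_max <- function(Tc) {
    w <- tt >= 0.8 * Tc & tt <= 1.2 * Tc
    if (any(w)) max(rho[w]) else -Inf
  }
  for (rep in 1:2) {
    if (2.4 * T0 <= max(tt) && win_max(2 * T0) > win_max(T0) + 0.05) {
      T0 <- 2 * T0
    }
  }

  # refine by the spacing of the ACF's up-crossings (one per cycle, robust
  # to micro-crossings injected by noise near zero)
  up <- which(rho[-m] < 0 & rho[-1] >= 0)
  if (length(up) >= 3) {
    tc <- (up - 1 + (-rho[up]) / (rho[up + 1] - rho[up])) * dt
    sp <- diff(tc)
    sp <- sp[sp > 0.6 * T0 & sp < 1.4 * T0]
    if (length(sp) >= 2) {
      Tzc <- stats::median(sp)
      if (abs(Tzc - T0) / T0 < 0.25) return(Tzc)
    }
  }
  T0
}

# Least squares of A * exp(-t / tau): log-linear solve, refined by nls.
fit_exp_decay <- function(t, v) {
  keep <- v > 1e-4
  if (sum(keep) < 2) {
    # decay too steep for more than one usable peak: anchor on the largest
    i <- which.max(v[-1]) + 1L
    return(list(tau = -t[i] / log(max(v[i], 1e-12)), resid = NA_real_))
  }
  t <- t[keep]; v <- v[keep]
  fit0 <- stats::lm(log(v) ~ t)
  slope <- stats::coef(fit0)[2]
  tau0 <- if (slope < 0) -1 / slope else max(t)
  A0 <- exp(stats::coef(fit0)[1])
  res <- tryCatch(suppressWarnings({
    nf <- stats::nls(v ~ A * exp(-t / tau),
                     start = list(A = A0, tau = tau0),
                     control = stats::nls.control(warnOnly = TRUE))
    co <- stats::coef(nf)
    list(tau = unname(co["tau"]),
         resid = sqrt(mean(stats::resid(nf)^2)))
  }), error = function(e) NULL)
  if (is.null(res) || res$tau <= 0) {
    res <- list(tau = unname(tau0),
                resid = sqrt(mean((v - A0 * exp(-t / tau0))^2)))
  }
  res
}

fit_damped_cosine <- function(t, rho, period_init) {
  for (tau0 in max(t) / c(20, 6, 2, 60)) {
    res <- tryCatch(suppressWarnings({
      nf <- stats::nls(rho ~ A * exp(-t / tau) * cos(2 * pi * t / Tp),
                       start = list(A = 1, tau = tau0, Tp = period_init),
                       control = stats::nls.control(maxiter = 200))
      co <- stats::coef(nf)
      list(tau = unname(co["tau"]), period = unname(co["Tp"]),
           resid = sqrt(mean(stats::resid(nf)^2)))
    }), error = function(e) NULL)
    if (!is.null(res) && res$tau > 0 && res$period > 0) return(res)
  }
  stop("direct damped-cosine fit failed to converge", call. = FALSE)
}

#' Dephasing time of a trajectory
#'
#' Pipeline convenience: extracts the free nuclear NF-kB signal after a
#' burn-in, computes its normalized autocorrelation and fits the dephasing
#' time.
#'
#' @param traj A `decoy_trajectory` on a uniform grid.
#' @param burn_in Burn-in discarded before the ACF (minutes, default 500).
#' @param max_lag Largest ACF lag in samples (default half the retained
#'   signal).
#' @param method Passed to [dephasing_time()].
#' @return A `dephasing_fit`.
#' @examples
#' p <- scale_volume(decoy_params(), omega = 1e3)
#' \donttest{
#' fit <- trajectory_dephasing(simulate_ssa(p, t_end = 3000, seed = 1))
#' fit$tau_phi
#' }
#' @export
trajectory_dephasing <- function(traj, burn_in = 500, max_lag = NULL,
                                 method = "envelope") {
  s <- nn_uM(traj)
  keep <- s$time > burn_in
  x <- s$value[keep]
  dt <- diff(s$time[1:2])
  if (is.null(max_lag)) max_lag <- floor(length(x) / 2)
  dephasing_time(normalized_autocorrelation(x, max_lag), dt = dt,
                 method = method)
}

#' @export
print.dephasing_fit <- function(x, ...) {
  cat("<dephasing_fit>\n")
  cat(sprintf("  tau_phi: %s%g min%s\n", if (x$capped) ">= " else "",
              x$tau_phi, if (x$capped) " (capped)" else ""))
  cat(sprintf("  period:  %g min\n", x$period))
  cat(sprintf("  method:  %s; fit RMS residual %s\n", x$method,
              format(x$residual, digits = 3)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a dephasing fit
#'
#' @param x A `dephasing_fit`.
#' @param ... Unused.
#' @return One-row tibble with `tau_phi`, `period`, `residual`, `method`,
#'   `capped`.
#' @export
tidy.dephasing_fit <- function(x, ...) {
  tibble::tibble(tau_phi = x$tau_phi, period = x$period,
                 residual = x$residual, method = x$method, capped = x$capped)
}

#' Glance at a dephasing fit
#'
#' @param x A `dephasing_fit`.
#' @param ... Unused.
#' @return One-row tibble with the fit summary and the number of envelope
#'   peaks used.
#' @export
glance.dephasing_fit <- function(x, ...) {
  tibble::tibble(tau_phi = x$tau_phi, period = x$period,
                 residual = x$residual, n_peaks = nrow(x$envelope) - 1L,
                 capped = x$capped)
}
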