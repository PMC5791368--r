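#' Write a trajectory to CSV with a metadata sidecar
#'
#' Writes `time_min` plus one column per species (decoy bins expanded as
#' `D_U_01`, ...) at 10 significant digits, and a JSON sidecar
#' (`<path>.meta.json`) recording the unit tag, the full parameter snapshot
#' and, for stochastic runs, the seed and event count.
#'
#' @param traj A `decoy_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @examples
#' traj <- simulate_ode(decoy_params(), t_end = 10)
#' f <- tempfile(fileext = ".csv")
#' write_trajectory(traj, f)
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "decoy_trajectory"))
  out <- as.data.frame(traj)
  names(out)[names(out) == "time"] <- "time_min"
  out[] <- lapply(out, function(x) signif(x, 10))
  readr::write_csv(out, path)
  p <- attr(traj, "params")
  meta <- list(
    units = attr(traj, "units"),
    params = unclass(p),
    n_bins = nrow(attr(traj, "bins")),
    seed = attr(traj, "seed"),
    n_events = attr(traj, "n_events")
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path; the `<path>.meta.json` sidecar is read if present.
#' @return A `decoy_trajectory` tibble.
#' @examples
#' traj <- simulate_ode(decoy_params(), t_end = 10)
#' f <- tempfile(fileext = ".csv")
#' write_trajectory(traj, f)
#' read_trajectory(f)
#' @export
read_trajectory <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df)[names(df) == "time_min"] <- "time"
  meta_path <- paste0(path, ".meta.json")
  params <- NULL; bins <- NULL; units <- "copies"
  seed <- NULL; n_events <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    units <- meta$units
    pm <- meta$params
    params <- do.call(decoy_params, pm)
    bins <- default_bins(params, meta$n_bins)
    seed <- meta$seed
    n_events <- meta$n_events
  }
  new_trajectory(df, params = params, bins = bins, units = units,
                 seed = seed, n_events = n_events)
}

#' Write a scan result to tidy CSV
#'
#' @param scan A scan tibble (from the `scan_*` drivers).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @examples
#' \donttest{
#' sc <- scan_duration(lambda_s = 0.02, k_soff = 1, k_s = 0, t_end = 1000)
#' write_scan(sc, tempfile(fileext = ".csv"))
#' }
#' @export
write_scan <- function(scan, path) {
  readr::write_csv(scan, path)
  invisible(path)
}

# ---- flat key = value run configuration ----

sim_setting_defaults <- function() {
  list(t_end = 3000, dt_out = 0.5, record_dt = 1, rtol = 1e-8, atol = 1e-10,
       n_bins = 15, span_in_sigmas = 3, seed = 1, mode = "ode",
       threshold = 0.1, burn_in = 500)
}

# Published ranges used for validation; values outside need an explicit
# override.
param_ranges <- list(
  k_soff = c(0.02, 20), lambda_s = c(0, 0.02), k_s = c(0, 10),
  alpha = c(0.10, 0.55), AD_dose = c(0, 2e5)
)

#' Load a run configuration
#'
#' Reads a flat `key = value` text file (one key per rate-constant symbol
#' plus totals, dose, volume factor and simulation settings; `#` starts a
#' comment), merges it over the built-in defaults, then applies any
#' command-line overrides — precedence: overrides > file > defaults. Unknown
#' keys are an error, as are values outside the published parameter ranges
#' unless `allow_out_of_range` is set.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @param overrides Named list of override values (e.g. from CLI flags).
#' @param allow_out_of_range Permit values outside the published ranges.
#' @return List with `params` (a [decoy_params()]) and `settings` (the
#'   simulation settings).
#' @examples
#' f <- tempfile(); writeLines("k_soff = 0.5", f)
#' read_run_config(f)$params$k_soff
#' @export
read_run_config <- function(path = NULL, overrides = list(),
                            allow_out_of_range = FALSE) {
  values <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) {
        stop("cannot parse config line: '", ln, "'", call. = FALSE)
      }
      key <- trimws(kv[1]); val <- trimws(kv[2])
      values[[key]] <- val
    }
  }
  for (nm in names(overrides)) values[[nm]] <- overrides[[nm]]

  settings <- sim_setting_defaults()
  p_defaults <- decoy_params()
  aliases <- c(k_Iin = "k_in", k_Iout = "k_out")
  param_keys <- setdiff(names(unclass(p_defaults)), NULL)
  param_updates <- list()

  for (nm in names(values)) {
    canon <- if (nm %in% names(aliases)) aliases[[nm]] else nm
    v <- values[[nm]]
    if (canon %in% param_keys) {
      v <- if (canon == "bound_degradation") as.character(v) else as.numeric(v)
      if (canon != "bound_degradation" && is.na(v)) {
        stop("config key '", nm, "' has a non-numeric value", call. = FALSE)
      }
      param_updates[[canon]] <- v
    } else if (canon %in% names(settings)) {
      settings[[canon]] <- if (canon == "mode") as.character(v) else as.numeric(v)
    } else {
      stop("unknown config key: '", nm, "'", call. = FALSE)
    }
  }

  if (!allow_out_of_range) {
    for (nm in names(param_updates)) {
      rng <- param_ranges[[nm]]
      v <- param_updates[[nm]]
      if (!is.null(rng) && is.numeric(v) && (v < rng[1] || v > rng[2])) {
        stop("config key '", nm, "' = ", v, " is outside the published range [",
             rng[1], ", ", rng[2],
             "]; pass allow_out_of_range to accept it", call. = FALSE)
      }
    }
  }
  if (!settings$mode %in% c("ode", "ssa")) {
    stop("config key 'mode' must be 'ode' or 'ssa'", call. = FALSE)
  }

  params <- do.call(update_params, c(list(p_defaults), param_updates))
  list(params = params, settings = settings)
}

write_resolved_config <- function(config, path) {
  jsonlite::write_json(
    list(params = unclass(config$params), settings = config$settings),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
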