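#' Piecewise-constant external lactose schedule
#'
#' An environment profile is an ordered set of segments, each holding the
#' external lactose concentration constant from its start time until the
#' next segment (or the horizon).
#'
#' @param start_min Numeric vector of segment start times (min), strictly
#'   increasing and beginning at 0.
#' @param L_ext_mM External lactose (mM) per segment, same length.
#' @param horizon_min Total duration covered (min), greater than the last
#'   start time.
#' @return A tibble of class `lac_profile` with columns `start_min` and
#'   `L_ext_mM` and attribute `horizon_min`.
#' @export
#' @examples
#' environment_profile(c(0, 100), c(0, 5), 500)
environment_profile <- function(start_min, L_ext_mM, horizon_min) {
  stopifnot(
    "start_min and L_ext_mM must have equal length" =
      length(start_min) == length(L_ext_mM),
    "start times must begin at 0" = length(start_min) >= 1 && start_min[1] == 0,
    "start times must be strictly increasing" =
      length(start_min) == 1 || all(diff(start_min) > 0),
    "L_ext must be non-negative" = all(L_ext_mM >= 0),
    "horizon must exceed the last start time" =
      horizon_min > start_min[length(start_min)]
  )
  structure(
    tibble::tibble(start_min = as.numeric(start_min),
                   L_ext_mM = as.numeric(L_ext_mM)),
    horizon_min = as.numeric(horizon_min),
    class = c("lac_profile", class(tibble::tibble()))
  )
}

#' Horizon of an environment profile
#' @param profile A `lac_profile`.
#' @return The total duration (min).
#' @export
profile_horizon <- function(profile) {
  stopifnot(inherits(profile, "lac_profile"))
  attr(profile, "horizon_min")
}

#' External lactose at given times
#' @param profile A `lac_profile`.
#' @param t Times (min), vectorized.
#' @return External lactose (mM) at each time.
#' @export
profile_at <- function(profile, t) {
  idx <- findInterval(t, profile$start_min)
  idx[idx < 1] <- 1
  profile$L_ext_mM[idx]
}

#' Zero-lactose protocol for stationary distributions
#'
#' A single segment at zero external lactose, used for sampling the
#' stationary copy-number distributions. The reference computation runs a
#' single cell line for 11 million minutes and discards the first million;
#' the default here is the tenfold scaled-down version used for desk runs.
#'
#' @param duration Total duration (min).
#' @param burn_in Initial stretch discarded from statistics (min).
#' @return A `lac_profile` with attribute `burn_in_min`.
#' @export
stationary_protocol <- function(duration = 1.1e6, burn_in = 1e5) {
  stopifnot("need duration > burn_in >= 0" = duration > burn_in && burn_in >= 0)
  p <- environment_profile(0, 0, duration)
  attr(p, "burn_in_min") <- as.numeric(burn_in)
  p
}

#' Lactose step protocol for switch-timing experiments
#'
#' External lactose is zero up to `t_on`, steps to `L_on` until `t_off`, and
#' returns to zero until the horizon. The reference protocol uses 10000-min
#' phases (long enough that the system is stationary before each change);
#' shorter phases can be supplied for scaled runs.
#'
#' @param t_on Time of the 0 to `L_on` step (min).
#' @param t_off Time of the `L_on` to 0 step (min).
#' @param horizon Total duration (min).
#' @param L_on External lactose during the on-phase (mM).
#' @return A `lac_profile` with attributes `t_on_min` and `t_off_min`.
#' @export
#' @examples
#' switch_protocol() # steps at 10000 and 20000 min
switch_protocol <- function(t_on = 10000, t_off = 20000, horizon = 30000,
                            L_on = 5) {
  stopifnot(
    "phases must have positive length" = t_on > 0 && t_off > t_on &&
      horizon > t_off,
    "L_on must be positive" = L_on > 0
  )
  p <- environment_profile(c(0, t_on, t_off), c(0, L_on, 0), horizon)
  attr(p, "t_on_min") <- as.numeric(t_on)
  attr(p, "t_off_min") <- as.numeric(t_off)
  p
}

#' Serialize an environment profile to JSON
#'
#' @param profile A `lac_profile`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "lac_profile"))
  cfg <- list(
    start_min = profile$start_min,
    L_ext_mM = profile$L_ext_mM,
    horizon_min = profile_horizon(profile),
    burn_in_min = attr(profile, "burn_in_min"),
    t_on_min = attr(profile, "t_on_min"),
    t_off_min = attr(profile, "t_off_min")
  )
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an environment profile from JSON
#'
#' @param path File written by [write_profile()].
#' @return A `lac_profile`.
#' @export
read_profile <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- environment_profile(cfg$start_min, cfg$L_ext_mM, cfg$horizon_min)
  for (a in c("burn_in_min", "t_on_min", "t_off_min")) {
    if (!is.null(cfg[[a]])) attr(p, a) <- cfg[[a]]
  }
  p
}
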