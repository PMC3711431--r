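# lacI promoter activity under a given regulatory variant
variant_laci_activity <- function(I_star, reg, variant) {
  if (variant$mode == "autoregulated") {
    laci_activity(I_star, reg)
  } else {
    rep_len(variant$fixed_activity, length(I_star))
  }
}

default_cell_state <- function(induced = FALSE, params = parameter_set()) {
  kin <- params$kin
  if (induced) {
    c(I_m = kin$k_c / kin$gamma_m,
      I = params$I_full,
      Y = params$reg$crp_factor * kin$k_y / kin$gamma)
  } else {
    c(I_m = 0, I = 0, Y = 0)
  }
}

#' Time derivatives of the mean-field cell state
#'
#' Right-hand side of the deterministic model. Internal lactose and
#' allolactose are eliminated through [qss_sugar()]; the active repressor
#' then sets the two promoter activities. LacZ is slaved to LacY as
#' `Z = (k_z / k_y) * Y` by default (both genes sit in one operon, so their
#' deterministic ratio is fixed); with `slave_Z = FALSE` the state carries
#' an explicit `Z` component with its own production/dilution terms.
#'
#' @param state Named numeric vector `c(I_m, I, Y)` in nM (plus `Z` when
#'   `slave_Z = FALSE`).
#' @param L_ext External lactose (mM); `Inf` for the saturated-import limit.
#' @param params A [parameter_set()].
#' @param variant A [variant_spec()].
#' @param slave_Z Slave LacZ to LacY (default) or integrate it explicitly.
#' @return Named numeric vector of time derivatives (nM/min).
#' @export
#' @examples
#' lac_derivatives(c(I_m = 0, I = 0, Y = 0), 0) # dI_m/dt = k_c at empty cell
lac_derivatives <- function(state, L_ext, params = parameter_set(),
                            variant = variant_spec("autoregulated"),
                            slave_Z = TRUE) {
  stopifnot("state must be non-negative" = all(state >= 0))
  kin <- params$kin
  Y <- state[["Y"]]
  Z <- if (slave_Z) (kin$k_z / kin$k_y) * Y else state[["Z"]]
  A <- qss_sugar(Y, Z, L_ext, params$transport)$A_uM
  I_star <- active_repressor(state[["I"]], A, params$reg)
  f_I <- variant_laci_activity(I_star, params$reg, variant)
  f_op <- operon_activity(I_star, params$reg)
  d <- c(
    I_m = kin$k_c * f_I - kin$gamma_m * state[["I_m"]],
    I = kin$k_l * state[["I_m"]] - kin$gamma * state[["I"]],
    Y = kin$k_y * f_op - kin$gamma * Y
  )
  if (!slave_Z) d <- c(d, Z = kin$k_z * f_op - kin$gamma * Z)
  d
}

# deSolve rhs shared by the integrators; state = (I_m, I, Y, M) where M
# accumulates metabolized lactose molecules
ode_rhs <- function(t, y, p) {
  kin <- p$params$kin
  Z <- (kin$k_z / kin$k_y) * y[3]
  A <- qss_sugar(y[3], Z, p$L_ext, p$params$transport)$A_uM
  I_star <- active_repressor(y[2], A, p$params$reg)
  f_I <- variant_laci_activity(I_star, p$params$reg, p$variant)
  f_op <- operon_activity(I_star, p$params$reg)
  list(c(
    kin$k_c * f_I - kin$gamma_m * y[1],
    kin$k_l * y[1] - kin$gamma * y[2],
    kin$k_y * f_op - kin$gamma * y[3],
    consumption_flux(Z, A, p$params$transport)
  ))
}

integrate_segment <- function(y, times, L_ext, params, variant,
                              rtol = 1e-8, atol = 1e-10) {
  deSolve::ode(
    y = y, times = times, func = ode_rhs,
    parms = list(L_ext = L_ext, params = params, variant = variant),
    method = "lsoda", rtol = rtol, atol = atol
  )
}

#' Deterministic trajectory under an environment profile
#'
#' Integrates the mean-field equations with a stiff-aware solver
#' (`deSolve::lsoda`, relative tolerance 1e-8, absolute 1e-10 nM),
#' restarting at every change of external lactose.
#'
#' @param params A [parameter_set()].
#' @param variant A [variant_spec()].
#' @param profile A `lac_profile`, or a single external lactose value (mM)
#'   held constant over `times`.
#' @param times Output times (min); default a unit grid over the profile
#'   horizon.
#' @param init Named initial state `c(I_m, I, Y)` (nM); defaults to the
#'   empty cell.
#' @return A tibble with columns `time_min`, `I_m_nM`, `I_nM`, `Y_nM`,
#'   `Z_nM`, `L_uM`, `A_uM` and `metabolized` (cumulative lactose
#'   molecules).
#' @export
simulate_deterministic <- function(params = parameter_set(),
                                   variant = variant_spec("autoregulated"),
                                   profile = 0,
                                   times = NULL,
                                   init = NULL) {
  if (!inherits(profile, "lac_profile")) {
    horizon <- if (is.null(times)) 1000 else max(times)
    profile <- environment_profile(0, profile, horizon + 1)
  }
  if (is.null(times)) times <- seq(0, profile_horizon(profile), by = 1)
  if (is.null(init)) init <- default_cell_state(FALSE, params)
  y <- c(unname(init[c("I_m", "I", "Y")]), 0)
  bounds <- sort(unique(c(
    times[1], times[length(times)],
    profile$start_min[profile$start_min > times[1] &
                        profile$start_min < times[length(times)]]
  )))
  out <- NULL
  for (k in seq_len(length(bounds) - 1)) {
    tt <- sort(unique(c(bounds[k], times[times >= bounds[k] &
                                           times <= bounds[k + 1]],
                        bounds[k + 1])))
    seg <- integrate_segment(y, tt, profile_at(profile, bounds[k]),
                             params, variant)
    y <- unname(seg[nrow(seg), 2:5])
    keep <- seg[, 1] %in% times
    if (!is.null(out)) keep[1] <- FALSE # boundary row already emitted
    out <- rbind(out, cbind(seg[keep, , drop = FALSE],
                            L_ext = profile_at(profile, bounds[k])))
  }
  kin <- params$kin
  Z <- (kin$k_z / kin$k_y) * out[, 4]
  sug <- qss_sugar(out[, 4], Z, out[, "L_ext"], params$transport)
  tibble::tibble(
    time_min = out[, 1], I_m_nM = out[, 2], I_nM = out[, 3],
    Y_nM = out[, 4], Z_nM = Z, L_uM = sug$L_uM, A_uM = sug$A_uM,
    metabolized = out[, 5]
  )
}

#' Deterministic steady state at fixed external lactose
#'
#' Integrates the mean-field equations in 1000-min windows until the
#' relative state change over a window drops below `tol`, mirroring how the
#' reference results were obtained (by numerical integration, not algebraic
#' root finding). By default the integration is run from both the empty
#' (uninduced) and the fully induced initial state; disagreement of the two
#' fixed points beyond `tol` (multistability) triggers a warning.
#'
#' @param L_ext External lactose (mM); `Inf` for the saturated-import limit.
#' @param params A [parameter_set()].
#' @param variant A [variant_spec()].
#' @param init Optional named initial state; when supplied, only this
#'   starting point is used.
#' @param tol Relative change per window defining convergence.
#' @param window Window length (min).
#' @param max_t Horizon (min) after which non-convergence is an error.
#' @return A one-row tibble with `L_ext_mM`, `I_m_nM`, `I_nM`, `Y_nM`,
#'   `Z_nM`, `L_uM`, `A_uM`.
#' @export
#' @examples
#' steady_state(0)$I_nM # about 30 nM autoregulated LacI
steady_state <- function(L_ext, params = parameter_set(),
                         variant = variant_spec("autoregulated"),
                         init = NULL, tol = 1e-9, window = 1000,
                         max_t = 2e5) {
  run_from <- function(y0) {
    y <- c(unname(y0[c("I_m", "I", "Y")]), 0)
    t <- 0
    repeat {
      seg <- integrate_segment(y, c(0, window), L_ext, params, variant,
                               rtol = 1e-10, atol = 1e-12)
      yn <- unname(seg[2, 2:5])
      rel <- max(abs(yn[1:3] - y[1:3]) / pmax(abs(yn[1:3]), 1e-8))
      y <- yn
      t <- t + window
      if (rel < tol) return(y[1:3])
      if (t >= max_t) {
        stop("steady_state did not converge within ", max_t,
             " min (relative change ", signif(rel, 3), ")")
      }
    }
  }
  if (!is.null(init)) {
    fixed <- run_from(init)
  } else {
    lo <- run_from(default_cell_state(FALSE, params))
    hi <- run_from(default_cell_state(TRUE, params))
    if (max(abs(hi - lo) / pmax(abs(hi), 1e-8)) > 100 * tol) {
      warning("steady states from uninduced and induced initial conditions ",
              "disagree; the system may be multistable at L_ext = ", L_ext)
    }
    fixed <- lo
  }
  kin <- params$kin
  Z <- (kin$k_z / kin$k_y) * fixed[3]
  sug <- qss_sugar(fixed[3], Z, L_ext, params$transport)
  tibble::tibble(
    L_ext_mM = L_ext, I_m_nM = fixed[1], I_nM = fixed[2], Y_nM = fixed[3],
    Z_nM = Z, L_uM = sug$L_uM, A_uM = sug$A_uM
  )
}

#' Dose-response curve of steady LacY versus external lactose
#'
#' Computes the deterministic steady state at each external lactose level.
#' The resulting LacY values are checked to be non-decreasing along the
#' grid.
#'
#' @param L_ext_grid Sorted positive external lactose levels (mM).
#' @param params A [parameter_set()].
#' @param variant A [variant_spec()].
#' @param ... Passed to [steady_state()].
#' @return A tibble of class `lac_dose_response` with one [steady_state()]
#'   row per grid point; attribute `variant` records the regulatory mode.
#' @export
dose_response <- function(L_ext_grid, params = parameter_set(),
                          variant = variant_spec("autoregulated"), ...) {
  stopifnot(
    "grid must be positive" = all(L_ext_grid > 0),
    "grid must be sorted increasing" = !is.unsorted(L_ext_grid)
  )
  curve <- purrr::map_dfr(L_ext_grid, steady_state, params = params,
                          variant = variant, ...)
  if (is.unsorted(curve$Y_nM, strictly = FALSE)) {
    warning("steady LacY is not monotone along the grid")
  }
  structure(curve,
            variant = variant$mode,
            class = c("lac_dose_response", class(curve)))
}

#' Input dynamic range of the dose-response
#'
#' The ratio of external lactose levels at which steady LacY reaches 90%
#' and 10% of its maximal level (the Goldbeter-Koshland definition). The
#' maximum defaults to the saturated-import asymptote (`L_ext = Inf`); the
#' quantile points are then located by bisection on [steady_state()] in
#' log-`L_ext`, not by grid interpolation. Alternatively `y_max = "plateau"`
#' uses the plateau of a supplied dose-response `curve`.
#'
#' @param params A [parameter_set()].
#' @param variant A [variant_spec()].
#' @param fractions Lower and upper output fractions (default 0.1 and 0.9).
#' @param y_max `"asymptote"` (default) or `"plateau"`.
#' @param curve A `lac_dose_response`, required for `y_max = "plateau"`;
#'   its last point must be within 1% of the asymptote, otherwise an error
#'   asks for a wider grid.
#' @param rel_tol Relative bisection tolerance in `L_ext`.
#' @return The dynamic-range ratio, with attributes `L_lo_mM`, `L_hi_mM`
#'   and `Y_max_nM`.
#' @export
#' @examples
#' \donttest{
#' dynamic_range(parameter_set("set_A")) # about 14.4 for the wild type
#' }
dynamic_range <- function(params = parameter_set(),
                          variant = variant_spec("autoregulated"),
                          fractions = c(0.1, 0.9),
                          y_max = c("asymptote", "plateau"),
                          curve = NULL,
                          rel_tol = 1e-6) {
  y_max <- match.arg(y_max)
  stopifnot("fractions must be two values in (0, 1), increasing" =
              length(fractions) == 2 && all(fractions > 0 & fractions < 1) &&
              fractions[1] < fractions[2])
  ymax_val <- steady_state(Inf, params, variant)$Y_nM
  if (y_max == "plateau") {
    if (is.null(curve)) stop("y_max = \"plateau\" requires a curve")
    plateau <- max(curve$Y_nM)
    if (plateau < 0.99 * ymax_val) {
      stop("the dose-response grid does not attain the plateau; ",
           "widen the grid (max grid LacY ", round(plateau), " nM vs ",
           "asymptote ", round(ymax_val), " nM)")
    }
    ymax_val <- plateau
  }
  y_at <- function(L) steady_state(L, params, variant)$Y_nM
  locate <- function(target) {
    lo <- 1e-6; hi <- 10
    while (y_at(hi) < target) {
      hi <- hi * 10
      if (hi > 1e6) stop("target LacY not attainable at finite L_ext")
    }
    while (hi / lo - 1 > rel_tol) {
      mid <- sqrt(lo * hi)
      if (y_at(mid) < target) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }
  L_lo <- locate(fractions[1] * ymax_val)
  L_hi <- locate(fractions[2] * ymax_val)
  structure(L_hi / L_lo, L_lo_mM = L_lo, L_hi_mM = L_hi, Y_max_nM = ymax_val)
}

#' Cumulative lactose metabolized along a deterministic trajectory
#'
#' Integrates the LacZ consumption flux over `duration` minutes of exposure
#' to `L_ext`. The default initial condition is the steady state at `L_ext`
#' itself, i.e. a cell in balanced growth on that lactose level, which is
#' the condition under which the export-rate parameter was calibrated
#' (about 2e9 molecules per 80-min generation at 5 mM). Pass the uninduced
#' steady state as `init` to measure the first-exposure transient instead.
#'
#' @param L_ext External lactose (mM).
#' @param duration Exposure time (min).
#' @param params A [parameter_set()].
#' @param variant A [variant_spec()].
#' @param init Optional named initial state `c(I_m, I, Y)`.
#' @return Lactose molecules consumed (1 nM = 1 molecule per cell).
#' @export
cumulative_metabolized <- function(L_ext, duration,
                                   params = parameter_set(),
                                   variant = variant_spec("autoregulated"),
                                   init = NULL) {
  stopifnot("duration must be positive" = duration > 0)
  if (L_ext <= 0) return(0)
  if (is.null(init)) {
    ss <- steady_state(L_ext, params, variant)
    init <- c(I_m = ss$I_m_nM, I = ss$I_nM, Y = ss$Y_nM)
  }
  y <- c(unname(init[c("I_m", "I", "Y")]), 0)
  seg <- integrate_segment(y, c(0, duration), L_ext, params, variant,
                           rtol = 1e-10, atol = 1e-12)
  unname(seg[2, 5])
}
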