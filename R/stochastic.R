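# flatten parameter set + variant into the list consumed by the C++ engine
ssa_pars <- function(params, variant) {
  reg <- params$reg; kin <- params$kin; tp <- params$transport
  list(
    eps_sum = reg$eps1 + reg$eps2 + reg$eps3,
    eps12 = reg$eps1 + reg$eps2,
    KA_uM = reg$K_A, h = reg$h, crp = reg$crp_factor,
    kc = kin$k_c, kl = kin$k_l, ky = kin$k_y, kz = kin$k_z,
    g = kin$gamma, gm = kin$gamma_m,
    vy = tp$v_y, Kext_mM = tp$K_ext, lamKext_uM = tp$lam * tp$K_ext * 1000,
    vz = tp$v_z, K_uM = tp$K * 1000,
    variant = if (variant$mode == "autoregulated") 0L else 1L,
    f_clamp = if (variant$mode == "autoregulated") 0
              else variant$fixed_activity
  )
}

# rounded deterministic steady state, the default starting point for
# stochastic runs (burn-in / equilibration phases absorb the rounding)
default_count_state <- function(params, variant, L_ext = 0) {
  ss <- steady_state(L_ext, params, variant)
  counts <- round(c(ss$I_m_nM, ss$I_nM, ss$Y_nM, ss$Z_nM))
  stats::setNames(counts, c("n_Im", "n_I", "n_Y", "n_Z"))
}

check_counts <- function(init) {
  stopifnot(
    "init must be a named vector with n_Im, n_I, n_Y, n_Z" =
      all(c("n_Im", "n_I", "n_Y", "n_Z") %in% names(init)),
    "counts must be non-negative integers" =
      all(init >= 0) && all(init == round(init))
  )
  as.numeric(init[c("n_Im", "n_I", "n_Y", "n_Z")])
}

#' Reaction-channel propensities at a count state
#'
#' The eight per-minute event rates of the stochastic model (production and
#' decay of *lacI* mRNA, LacI tetramers, LacY and LacZ), evaluated exactly
#' as inside the simulation engine: internal sugars from [qss_sugar()],
#' active repressor from [active_repressor()], promoter activities from the
#' four-state occupancy model.
#'
#' @param state Named counts `c(n_Im, n_I, n_Y, n_Z)`.
#' @param L_ext External lactose (mM).
#' @param params A [parameter_set()].
#' @param variant A [variant_spec()].
#' @return Named numeric vector of eight propensities (per min).
#' @export
lac_propensities <- function(state, L_ext, params = parameter_set(),
                             variant = variant_spec("autoregulated")) {
  n <- check_counts(state)
  a <- cpp_propensities(n, L_ext, ssa_pars(params, variant))
  stats::setNames(a, c("Im_prod", "Im_decay", "I_prod", "I_decay",
                       "Y_prod", "Y_decay", "Z_prod", "Z_decay"))
}

#' Exact stochastic trajectory of molecule counts
#'
#' Gillespie direct-method simulation of the four molecular species under a
#' piecewise-constant external lactose profile. Waiting times are
#' exponential with the total propensity as rate; at every change of the
#' environment the clock is truncated to the boundary and propensities
#' recomputed. With a `seed` the trajectory is bit-reproducible.
#'
#' @param params A [parameter_set()].
#' @param variant A [variant_spec()].
#' @param profile A `lac_profile`, or a single external lactose value (mM)
#'   held constant for `t_end` minutes.
#' @param t_end End time (min); defaults to the profile horizon.
#' @param init Named counts `c(n_Im, n_I, n_Y, n_Z)`; defaults to the
#'   rounded deterministic steady state at zero lactose.
#' @param seed Integer seed for R's RNG (optional).
#' @param sample_interval Record the state every this many minutes; `NULL`
#'   records every event (capped at `max_records`).
#' @param max_records Safety cap on event-level records.
#' @return A tibble of class `lac_trajectory` with columns `t_min`, `n_Im`,
#'   `n_I`, `n_Y`, `n_Z`; attributes `n_events` and `final_state`.
#' @export
#' @examples
#' tr <- simulate_lac(t_end = 500, seed = 1, sample_interval = 10)
simulate_lac <- function(params = parameter_set(),
                         variant = variant_spec("autoregulated"),
                         profile = 0, t_end = NULL, init = NULL,
                         seed = NULL, sample_interval = NULL,
                         max_records = 5e6) {
  if (!inherits(profile, "lac_profile")) {
    profile <- environment_profile(0, profile,
                                   if (is.null(t_end)) 1000 else t_end)
  }
  if (is.null(t_end)) t_end <- profile_horizon(profile)
  stopifnot("profile must cover [0, t_end]" =
              profile_horizon(profile) >= t_end)
  if (is.null(init)) init <- default_count_state(params, variant)
  n0 <- check_counts(init)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_ssa_trajectory(
    n0, profile$start_min, profile$L_ext_mM, t_end,
    ssa_pars(params, variant),
    if (is.null(sample_interval)) -1 else sample_interval,
    as.integer(max_records)
  )
  out <- tibble::tibble(t_min = res$t_min, n_Im = res$n_Im, n_I = res$n_I,
                        n_Y = res$n_Y, n_Z = res$n_Z)
  structure(out,
            n_events = res$n_events,
            final_state = stats::setNames(res$final,
                                          c("n_Im", "n_I", "n_Y", "n_Z")),
            class = c("lac_trajectory", class(out)))
}

#' Stationary copy-number distributions at zero external lactose
#'
#' Runs one long Gillespie trajectory at zero lactose (one tenth of the
#' reference 11-million-minute protocol by default), discards the burn-in, and collects
#' time-weighted statistics: every holding interval contributes its length
#' as weight, so the result estimates the stationary distribution of the
#' underlying jump process (not the event-weighted one).
#'
#' @param params A [parameter_set()].
#' @param variant A [variant_spec()].
#' @param duration Total simulated time (min).
#' @param burn_in Initial stretch discarded (min); must be < `duration`.
#' @param seed Integer seed (optional).
#' @param init Named counts; defaults to the rounded deterministic steady
#'   state.
#' @param hist_max Histogram cap (counts above are pooled into the top bin).
#' @return An object of class `lac_stationary`: a list with `summary`
#'   (tibble: species, mean, sd, cv2, p_zero), `histogram` (tibble:
#'   species, count, probability for LacI and LacY), and `config`.
#' @export
stationary_distribution <- function(params = parameter_set(),
                                    variant = variant_spec("autoregulated"),
                                    duration = 1.1e6, burn_in = 1e5,
                                    seed = NULL, init = NULL,
                                    hist_max = 1e5) {
  stopifnot("need duration > burn_in >= 0" =
              duration > burn_in && burn_in >= 0)
  if (is.null(init)) init <- default_count_state(params, variant)
  n0 <- check_counts(init)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_ssa_stationary(n0, 0, duration, burn_in,
                            ssa_pars(params, variant),
                            as.integer(hist_max))
  w <- res$weight_min
  mean_ <- res$sum1 / w
  var_ <- pmax(res$sum2 / w - mean_^2, 0)
  sd_ <- sqrt(var_)
  cv2 <- ifelse(mean_ > 0, var_ / mean_^2, NA_real_)
  summary <- tibble::tibble(
    species = c("lacI_mRNA", "LacI", "LacY", "LacZ"),
    mean = mean_, sd = sd_, cv2 = cv2,
    p_zero = c(NA, res$t_zero_I / w, res$t_zero_Y / w, NA)
  )
  hist_tbl <- function(h, species) {
    pr <- h / w
    keep <- pr > 0
    tibble::tibble(species = species, count = which(keep) - 1L,
                   probability = pr[keep])
  }
  structure(
    list(
      summary = summary,
      histogram = dplyr::bind_rows(hist_tbl(res$hist_I, "LacI"),
                                   hist_tbl(res$hist_Y, "LacY")),
      config = list(variant = variant$mode, label = params$label,
                    duration = duration, burn_in = burn_in, seed = seed,
                    n_events = res$n_events)
    ),
    class = "lac_stationary"
  )
}

#' @export
print.lac_stationary <- function(x, ...) {
  cat("<lac_stationary> ", x$config$variant, ", ", x$config$label,
      ", ", format(x$config$duration, big.mark = ","), " min (",
      format(x$config$burn_in, big.mark = ","), " burn-in)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' First-passage switch times under a lactose step protocol
#'
#' Runs an ensemble of independent Gillespie simulations of the step
#' protocol and records, per run, the turn-on time (time after the lactose
#' step for LacY to first reach `on_threshold` molecules) and the turn-off
#' time (time after lactose removal to first fall to `off_threshold`).
#' Runs that never cross within their phase are flagged censored and
#' excluded from the mean with a warning. Each run draws its own seed from
#' the root `seed`, so the ensemble is reproducible while runs stay
#' independent.
#'
#' @param params A [parameter_set()].
#' @param variant A [variant_spec()].
#' @param protocol A [switch_protocol()] profile.
#' @param n_runs Number of independent runs.
#' @param on_threshold,off_threshold LacY thresholds in molecules (the
#'   reference values are 95% and 5% of the 9500-molecule induced level).
#' @param seed Root seed (optional).
#' @param init Named counts; defaults to the rounded deterministic steady
#'   state at zero lactose.
#' @return An object of class `lac_switch`: list with `times` (tibble: run,
#'   seed, turn_on_min, turn_off_min), `summary` (tibble: statistic, mean,
#'   sd, n, n_censored), and `config`.
#' @export
switch_times <- function(params = parameter_set(),
                         variant = variant_spec("autoregulated"),
                         protocol = switch_protocol(), n_runs = 1000,
                         on_threshold = 9025, off_threshold = 475,
                         seed = NULL, init = NULL) {
  stopifnot(
    "protocol must be a switch protocol" =
      inherits(protocol, "lac_profile") &&
      !is.null(attr(protocol, "t_on_min")),
    "n_runs must be positive" = n_runs >= 1
  )
  if (is.null(init)) init <- default_count_state(params, variant)
  n0 <- check_counts(init)
  pars <- ssa_pars(params, variant)
  t_on_start <- attr(protocol, "t_on_min")
  t_off_start <- attr(protocol, "t_off_min")
  horizon <- profile_horizon(protocol)
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1, n_runs)
  times <- purrr::map_dfr(seq_len(n_runs), function(i) {
    set.seed(run_seeds[i])
    fp <- cpp_ssa_first_passage(n0, protocol$start_min, protocol$L_ext_mM,
                                horizon, pars, t_on_start, t_off_start,
                                on_threshold, off_threshold)
    tibble::tibble(run = i, seed = run_seeds[i],
                   turn_on_min = fp[["t_on"]], turn_off_min = fp[["t_off"]])
  })
  summarise_fp <- function(x, what) {
    cens <- sum(is.na(x))
    if (cens > 0) {
      warning(cens, " run(s) never crossed the ", what,
              " threshold within the phase; excluded from the mean")
    }
    tibble::tibble(statistic = what, mean = mean(x, na.rm = TRUE),
                   sd = stats::sd(x, na.rm = TRUE),
                   n = sum(!is.na(x)), n_censored = cens)
  }
  structure(
    list(
      times = times,
      summary = dplyr::bind_rows(
        summarise_fp(times$turn_on_min, "turn_on"),
        summarise_fp(times$turn_off_min, "turn_off")
      ),
      config = list(variant = variant$mode, label = params$label,
                    n_runs = n_runs, on_threshold = on_threshold,
                    off_threshold = off_threshold, seed = seed,
                    t_on_min = t_on_start, t_off_min = t_off_start,
                    horizon_min = horizon)
    ),
    class = "lac_switch"
  )
}

#' @export
print.lac_switch <- function(x, ...) {
  cat("<lac_switch> ", x$config$variant, ", ", x$config$label, ", ",
      x$config$n_runs, " runs\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Fraction of cells turned on shortly after a lactose step
#'
#' Counts, out of `n_runs` independent stochastic simulations, how many
#' reach `on_threshold` LacY molecules within `t_after_shift` minutes of a
#' 0 to `L_on` mM lactose step, after an equilibration phase at zero
#' lactose. Early turn-on is driven by cells that happen to hold few (or
#' zero) LacI tetramers when lactose appears.
#'
#' @param params A [parameter_set()].
#' @param variant A [variant_spec()].
#' @param t_after_shift Observation window after the step (min).
#' @param n_runs Number of independent runs.
#' @param equilibration Zero-lactose phase before the step (min).
#' @param L_on External lactose after the step (mM).
#' @param on_threshold LacY threshold in molecules.
#' @param seed Root seed (optional).
#' @param init Named counts; defaults to the rounded deterministic steady
#'   state at zero lactose.
#' @return A list of class `lac_fraction_on` with `n_on`, `n_runs`,
#'   `fraction`, `se` (binomial standard error) and `config`.
#' @export
fraction_on_at <- function(params = parameter_set(),
                           variant = variant_spec("autoregulated"),
                           t_after_shift = 299, n_runs = 1000,
                           equilibration = 2000, L_on = 5,
                           on_threshold = 9025, seed = NULL, init = NULL) {
  stopifnot("t_after_shift must be positive" = t_after_shift > 0,
            "n_runs must be positive" = n_runs >= 1)
  if (is.null(init)) init <- default_count_state(params, variant)
  n0 <- check_counts(init)
  pars <- ssa_pars(params, variant)
  t_end <- equilibration + t_after_shift
  profile <- environment_profile(c(0, equilibration), c(0, L_on), t_end)
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1, n_runs)
  on <- vapply(seq_len(n_runs), function(i) {
    set.seed(run_seeds[i])
    fp <- cpp_ssa_first_passage(n0, profile$start_min, profile$L_ext_mM,
                                t_end, pars, equilibration, t_end + 1,
                                on_threshold, 0)
    !is.na(fp[["t_on"]])
  }, logical(1))
  p <- mean(on)
  structure(
    list(n_on = sum(on), n_runs = n_runs, fraction = p,
         se = sqrt(p * (1 - p) / n_runs),
         config = list(variant = variant$mode, label = params$label,
                       t_after_shift = t_after_shift,
                       equilibration = equilibration, L_on = L_on,
                       on_threshold = on_threshold, seed = seed)),
    class = "lac_fraction_on"
  )
}

#' @export
print.lac_fraction_on <- function(x, ...) {
  cat("<lac_fraction_on> ", x$config$variant, ": ", x$n_on, " of ",
      x$n_runs, " runs on within ", x$config$t_after_shift,
      " min (fraction ", signif(x$fraction, 3), " +/- ",
      signif(x$se, 2), ")\n", sep = "")
  invisible(x)
}
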