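resolve_variant <- function(v) {
  v <- switch(v, wt = "autoregulated", v)
  variant_spec(v)
}

#' Run a named experiment from a config and write its outputs
#'
#' Dispatches to the package's experiment functions, writes tidy TSV
#' outputs plus a machine-readable `summary.json` embedding the fully
#' resolved config (including the seed), and returns the summary. Running
#' the same config twice produces identical outputs.
#'
#' Config fields: `experiment` (one of `"dose_response"`, `"stationary"`,
#' `"switch"`, `"fraction_on"`, `"metabolized"`), `params` (`"set_A"` or
#' `"set_B"`), `variant` (`"wt"`/`"autoregulated"`, `"fixed_low"`,
#' `"fixed_high"`), `seed`, and per-experiment settings: `L_ext_grid`
#' (dose_response), `duration`/`burn_in` (stationary), `n_runs` and phase
#' lengths `t_on`/`t_off`/`horizon` (switch), `n_runs`/`t_after_shift`/
#' `equilibration` (fraction_on), `L_ext`/`duration` (metabolized).
#'
#' @param config A named list (or path to a JSON file holding one).
#' @param out_dir Output directory; created if missing.
#' @return The summary list, invisibly.
#' @export
run_experiment <- function(config, out_dir = config$out_dir) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  required <- c("experiment", "params", "variant")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("invalid config: missing key(s) ", paste(missing, collapse = ", "))
  }
  experiments <- c("dose_response", "stationary", "switch", "fraction_on",
                   "metabolized")
  if (!config$experiment %in% experiments) {
    stop("invalid config: unknown experiment \"", config$experiment, "\"")
  }
  if (!config$params %in% c("set_A", "set_B")) {
    stop("invalid config: unknown params \"", config$params, "\"")
  }
  if (is.null(out_dir)) stop("invalid config: missing key out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ps <- parameter_set(config$params)
  variant <- resolve_variant(config$variant)
  seed <- config$seed
  `%||%` <- function(a, b) if (is.null(a)) b else a

  results <- switch(config$experiment,
    dose_response = {
      grid <- config$L_ext_grid %||% 10^seq(-3.5, 1, length.out = 19)
      curve <- dose_response(grid, ps, variant)
      readr::write_tsv(curve, file.path(out_dir, "dose_response.tsv"))
      dr <- dynamic_range(ps, variant)
      list(dynamic_range = as.numeric(dr),
           L_10pct_mM = attr(dr, "L_lo_mM"),
           L_90pct_mM = attr(dr, "L_hi_mM"),
           Y_max_nM = attr(dr, "Y_max_nM"),
           Y_repressed_nM = curve$Y_nM[1])
    },
    stationary = {
      st <- stationary_distribution(
        ps, variant,
        duration = config$duration %||% 1.1e6,
        burn_in = config$burn_in %||% 1e5,
        seed = seed
      )
      readr::write_tsv(st$summary, file.path(out_dir, "stationary_summary.tsv"))
      readr::write_tsv(st$histogram, file.path(out_dir, "histograms.tsv"))
      s <- st$summary
      list(LacI_mean = s$mean[s$species == "LacI"],
           LacI_sd = s$sd[s$species == "LacI"],
           LacI_cv2 = s$cv2[s$species == "LacI"],
           LacI_p_zero = s$p_zero[s$species == "LacI"],
           LacY_mean = s$mean[s$species == "LacY"],
           LacY_sd = s$sd[s$species == "LacY"],
           LacY_cv2 = s$cv2[s$species == "LacY"])
    },
    switch = {
      protocol <- switch_protocol(
        t_on = config$t_on %||% 10000,
        t_off = config$t_off %||% 20000,
        horizon = config$horizon %||% 30000
      )
      sw <- switch_times(ps, variant, protocol,
                         n_runs = config$n_runs %||% 1000, seed = seed)
      readr::write_tsv(sw$times, file.path(out_dir, "switch_times.tsv"))
      readr::write_tsv(sw$summary, file.path(out_dir, "switch_summary.tsv"))
      s <- sw$summary
      list(turn_on_mean = s$mean[s$statistic == "turn_on"],
           turn_on_sd = s$sd[s$statistic == "turn_on"],
           turn_off_mean = s$mean[s$statistic == "turn_off"],
           turn_off_sd = s$sd[s$statistic == "turn_off"],
           n_censored = sum(s$n_censored))
    },
    fraction_on = {
      fo <- fraction_on_at(
        ps, variant,
        t_after_shift = config$t_after_shift %||% 299,
        n_runs = config$n_runs %||% 1000,
        equilibration = config$equilibration %||% 2000,
        seed = seed
      )
      list(n_on = fo$n_on, n_runs = fo$n_runs, fraction = fo$fraction,
           fraction_se = fo$se)
    },
    metabolized = {
      mol <- cumulative_metabolized(
        L_ext = config$L_ext %||% 5,
        duration = config$duration %||% 80,
        params = ps, variant = variant
      )
      list(molecules = mol)
    }
  )

  summary <- list(
    config = c(config[setdiff(names(config), "out_dir")],
               list(variant_resolved = variant$mode)),
    results = results
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
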