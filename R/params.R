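#' Regulatory parameters of the four-state promoter model
#'
#' Bundles the operator-binding strengths of the three LacI-bound promoter
#' configurations, the allolactose-LacI inactivation constants, and the
#' combined cAMP-CRP activity factor. The three binding strengths weight the
#' O1-only bound state (`eps1`), the O1-O2 looped state (`eps2`) and the
#' O1-O3 looped state (`eps3`); only the O1-O3 loop roadblocks transcription
#' of *lacI* itself.
#'
#' @param eps1,eps2,eps3 Binding strengths of the O1-only, O1-O2 looped and
#'   O1-O3 looped states (per nM of active LacI tetramer). Defaults are the
#'   values calibrated from 1300-fold total / 18-fold O1-only repression at
#'   the 30 nM autoregulated LacI reference, see [calibrate_epsilons()].
#' @param K_A Allolactose concentration at which half the LacI pool is
#'   inactivated (uM).
#' @param h Hill coefficient of allolactose-LacI binding (dimensionless,
#'   >= 1).
#' @param crp_factor Combined cAMP-CRP activity multiplier in (0, 1]. The
#'   activator acts independently of LacI occupancy, so it enters the operon
#'   activity as a plain prefactor.
#'
#' @return An object of class `lac_regulatory_params` (a named list).
#' @seealso [calibrate_epsilons()], [operon_activity()], [laci_activity()]
#' @export
#' @examples
#' reg <- regulatory_params()
#' reg$eps1 # 0.6 per nM
regulatory_params <- function(eps1 = 18 / 30,
                              eps2 = 1300 / 90 - 18 / 30,
                              eps3 = 2600 / 90,
                              K_A = 1,
                              h = 2,
                              crp_factor = 0.9) {
  stopifnot(
    "epsilons must be non-negative" = all(c(eps1, eps2, eps3) >= 0),
    "K_A must be positive" = K_A > 0,
    "h must be >= 1" = h >= 1,
    "crp_factor must be in (0, 1]" = crp_factor > 0 && crp_factor <= 1
  )
  structure(
    list(eps1 = eps1, eps2 = eps2, eps3 = eps3,
         K_A = K_A, h = h, crp_factor = crp_factor),
    class = "lac_regulatory_params"
  )
}

#' Calibrate operator binding strengths from fold-repression data
#'
#' Solves for the three binding strengths from (i) the total fold repression
#' of the operon at a reference active-LacI concentration, (ii) the fold
#' repression measured with only the O1 operator present, and (iii) the ratio
#' of fully expressed to autoregulated LacI levels, which fixes the residual
#' *lacI* activity of the roadblocked promoter. The constraints are exact:
#' `eps1 = fold_O1 / I_ref`, `eps1 + eps2 + eps3 = fold_total / I_ref` and
#' `eps1 + eps2 = eps3 / (full_to_auto_ratio - 1)`.
#'
#' @param fold_total Total fold repression of the operon at `I_ref` (1300 for
#'   the wild-type calibration).
#' @param fold_O1 Fold repression with only O1 present (18).
#' @param I_ref Reference active LacI tetramer concentration (nM) at which
#'   the folds were measured (30 for parameter set A, 10 for set B).
#' @param full_to_auto_ratio Ratio of fully expressed to autoregulated LacI
#'   levels (3).
#'
#' @return Named numeric vector `c(eps1, eps2, eps3)` in per-nM units.
#' @export
#' @examples
#' calibrate_epsilons(1300, 18, 30, 3) # c(0.6, 13.84, 28.89)
calibrate_epsilons <- function(fold_total = 1300, fold_O1 = 18, I_ref = 30,
                               full_to_auto_ratio = 3) {
  stopifnot(
    "need fold_total > fold_O1 > 1" = fold_total > fold_O1 && fold_O1 > 1,
    "I_ref must be positive" = I_ref > 0,
    "full_to_auto_ratio must be > 1" = full_to_auto_ratio > 1
  )
  eps1 <- fold_O1 / I_ref
  eps_sum <- fold_total / I_ref
  # eps1 + eps2 = eps_sum / ratio follows from the two linear constraints
  eps12 <- eps_sum / full_to_auto_ratio
  eps2 <- eps12 - eps1
  eps3 <- eps_sum - eps12
  if (eps2 < 0) {
    stop("infeasible calibration: fold_O1 exceeds the share of the O1-only ",
         "state implied by full_to_auto_ratio (eps2 < 0)")
  }
  c(eps1 = eps1, eps2 = eps2, eps3 = eps3)
}

#' Kinetic parameters of gene expression
#'
#' Transcription, translation, dilution and mRNA decay rates. Only the
#' *lacI* mRNA is modelled explicitly (it is produced about once per cell
#' generation, so its shot noise matters); *lacY*/*lacZ* expression is
#' collapsed into single production steps with maximal throughputs `k_y` and
#' `k_z`. The *lacI* translation rate defaults to the value that yields
#' `I_full` nM LacI tetramers when the *lacI* promoter is fully active:
#' `k_l = I_full * gamma * gamma_m / k_c`.
#'
#' @param k_c Maximal *lacI* transcription rate (nM/min); 1/80 is one
#'   transcript per 80-min generation.
#' @param k_y,k_z Maximal *lacY* / *lacZ* expression throughput (nM/min).
#' @param gamma Protein dilution rate (per min); `log(2)/80` for an 80-min
#'   doubling time with no active degradation.
#' @param gamma_m *lacI* mRNA decay rate (per min); `log(2)/3.8` for a
#'   3.8-min half-life.
#' @param I_full Fully expressed LacI tetramer level (nM) used to set the
#'   default translation rate (90 for set A, 30 for set B).
#' @param k_l *lacI* translation rate per mRNA (per min).
#'
#' @return An object of class `lac_kinetic_params` (a named list).
#' @export
#' @examples
#' kin <- kinetic_params()
#' kin$k_l * kin$k_c / (kin$gamma * kin$gamma_m) # 90 nM fully expressed
kinetic_params <- function(k_c = 1 / 80,
                           k_y = 90,
                           k_z = 100,
                           gamma = log(2) / 80,
                           gamma_m = log(2) / 3.8,
                           I_full = 90,
                           k_l = I_full * gamma * gamma_m / k_c) {
  vals <- c(k_c, k_l, k_y, k_z, gamma, gamma_m)
  stopifnot("all kinetic rates must be positive" = all(vals > 0))
  structure(
    list(k_c = k_c, k_l = k_l, k_y = k_y, k_z = k_z,
         gamma = gamma, gamma_m = gamma_m),
    class = "lac_kinetic_params"
  )
}

#' Lactose transport and hydrolysis parameters
#'
#' Michaelis-Menten constants and turnover numbers for LacY-mediated import
#' and export of lactose and LacZ-mediated hydrolysis/conversion. Export
#' shares the LacY turnover `v_y` but has a `lam`-fold larger Michaelis
#' constant. Each of the two LacZ reactions on lactose (hydrolysis to
#' glucose + galactose, and conversion to allolactose) proceeds at maximal
#' rate `v_z` per enzyme, so lactose is removed at up to `2 * v_z` per LacZ.
#'
#' @param v_y LacY turnover for import and export (per min; 48/s = 2880/min).
#' @param K_ext Import half-saturation constant (mM).
#' @param lam Dimensionless multiplier of `K_ext` giving the export
#'   Michaelis constant `lam * K_ext`.
#' @param v_z Per-reaction LacZ turnover (per min); the combined lactose
#'   conversion rate is `2 * v_z = 3600`/min.
#' @param K Michaelis constant of LacZ for lactose and allolactose (mM).
#'
#' @return An object of class `lac_transport_params` (a named list).
#' @export
transport_params <- function(v_y = 2880,
                             K_ext = 0.27,
                             lam = 750,
                             v_z = 1800,
                             K = 1.4) {
  stopifnot("all transport parameters must be strictly positive" =
              all(c(v_y, K_ext, lam, v_z, K) > 0))
  structure(
    list(v_y = v_y, K_ext = K_ext, lam = lam, v_z = v_z, K = K),
    class = "lac_transport_params"
  )
}

#' Regulatory variant of the lacI gene
#'
#' Selects how *lacI* transcription is regulated: `"autoregulated"` (the
#' wild type, where the O1-O3 roadblock feeds back on *lacI*), or a
#' constitutive control with the *lacI* promoter activity clamped to a
#' constant: `"fixed_low"` clamps it at `1 / full_to_auto_ratio` (yielding
#' the autoregulated mean LacI level) and `"fixed_high"` at 1 (the fully
#' expressed level). Constitutive variants keep the mRNA stage and its
#' bursting noise; only the promoter activity is frozen.
#'
#' @param mode One of `"autoregulated"`, `"fixed_low"`, `"fixed_high"`.
#' @param fixed_activity Optional explicit clamped activity in (0, 1] for
#'   the constitutive modes, overriding the default.
#' @param full_to_auto_ratio Ratio of fully expressed to autoregulated LacI
#'   levels used to derive the `fixed_low` default activity.
#'
#' @return An object of class `lac_variant` (a named list with `mode` and
#'   `fixed_activity`, the latter `NA` for the autoregulated mode).
#' @export
#' @examples
#' variant_spec("fixed_low")$fixed_activity # 1/3
variant_spec <- function(mode = c("autoregulated", "fixed_low", "fixed_high"),
                         fixed_activity = NULL,
                         full_to_auto_ratio = 3) {
  mode <- match.arg(mode)
  if (is.null(fixed_activity)) {
    fixed_activity <- switch(mode,
      autoregulated = NA_real_,
      fixed_low = 1 / full_to_auto_ratio,
      fixed_high = 1
    )
  }
  if (mode != "autoregulated") {
    stopifnot("fixed_activity must be in (0, 1]" =
                fixed_activity > 0 && fixed_activity <= 1)
  }
  structure(list(mode = mode, fixed_activity = fixed_activity),
            class = "lac_variant")
}

#' Bundled parameter sets
#'
#' The two parameter sets used throughout the package. `"set_A"` has an
#' autoregulated LacI level of 30 nM and a fully expressed level of 90 nM.
#' `"set_B"` divides the *lacI* translation rate by three (LacI ranges
#' 10-30 nM) and recalibrates the binding strengths at the 10 nM reference
#' so both sets give identical fold repressions at their respective
#' autoregulated levels.
#'
#' @param label `"set_A"` or `"set_B"`.
#' @return An object of class `lac_parameter_set`: a list with elements
#'   `label`, `reg` ([regulatory_params()]), `kin` ([kinetic_params()]),
#'   `transport` ([transport_params()]), and the reference levels `I_auto`
#'   and `I_full` (nM).
#' @export
#' @examples
#' ps <- parameter_set("set_B")
#' ps$reg$eps1 # 1.8 per nM
parameter_set <- function(label = c("set_A", "set_B")) {
  label <- match.arg(label)
  I_auto <- switch(label, set_A = 30, set_B = 10)
  I_full <- 3 * I_auto
  eps <- calibrate_epsilons(1300, 18, I_ref = I_auto, full_to_auto_ratio = 3)
  structure(
    list(
      label = label,
      reg = regulatory_params(eps[["eps1"]], eps[["eps2"]], eps[["eps3"]]),
      kin = kinetic_params(I_full = I_full),
      transport = transport_params(),
      I_auto = I_auto,
      I_full = I_full
    ),
    class = "lac_parameter_set"
  )
}

#' @export
print.lac_parameter_set <- function(x, ...) {
  cat("<lac_parameter_set> ", x$label,
      " (autoregulated ", x$I_auto, " nM, fully expressed ", x$I_full,
      " nM LacI)\n", sep = "")
  invisible(x)
}

#' Tidy a parameter set into a long table
#'
#' @param x A `lac_parameter_set`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `value`, `unit`.
#' @importFrom generics tidy
#' @export
tidy.lac_parameter_set <- function(x, ...) {
  tibble::tibble(
    parameter = c("eps1", "eps2", "eps3", "K_A", "h", "crp_factor",
                  "k_c", "k_l", "k_y", "k_z", "gamma", "gamma_m",
                  "v_y", "K_ext", "lam", "v_z", "K", "I_auto", "I_full"),
    value = c(x$reg$eps1, x$reg$eps2, x$reg$eps3, x$reg$K_A, x$reg$h,
              x$reg$crp_factor, x$kin$k_c, x$kin$k_l, x$kin$k_y, x$kin$k_z,
              x$kin$gamma, x$kin$gamma_m, x$transport$v_y, x$transport$K_ext,
              x$transport$lam, x$transport$v_z, x$transport$K,
              x$I_auto, x$I_full),
    unit = c("1/nM", "1/nM", "1/nM", "uM", "", "",
             "nM/min", "1/min", "nM/min", "nM/min", "1/min", "1/min",
             "1/min", "mM", "", "1/min", "mM", "nM", "nM")
  )
}

#' Serialize a parameter set to a JSON config
#'
#' Writes a plain-text JSON file with unit-bearing key names; read back with
#' [read_params()]. Round-trips exactly (values are written at full double
#' precision).
#'
#' @param ps A `lac_parameter_set`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_params <- function(ps, path) {
  stopifnot(inherits(ps, "lac_parameter_set"))
  cfg <- list(
    label = ps$label,
    regulatory = list(
      eps1_per_nM = ps$reg$eps1, eps2_per_nM = ps$reg$eps2,
      eps3_per_nM = ps$reg$eps3, K_A_uM = ps$reg$K_A, hill_h = ps$reg$h,
      crp_factor = ps$reg$crp_factor
    ),
    kinetic = list(
      k_c_nM_per_min = ps$kin$k_c, k_l_per_min = ps$kin$k_l,
      k_y_nM_per_min = ps$kin$k_y, k_z_nM_per_min = ps$kin$k_z,
      gamma_per_min = ps$kin$gamma, gamma_m_per_min = ps$kin$gamma_m
    ),
    transport = list(
      v_y_per_min = ps$transport$v_y, K_ext_mM = ps$transport$K_ext,
      lambda = ps$transport$lam, v_z_per_min = ps$transport$v_z,
      K_lacZ_mM = ps$transport$K
    ),
    reference_nM = list(I_auto = ps$I_auto, I_full = ps$I_full)
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter set from a JSON config
#'
#' @param path File written by [write_params()].
#' @return A `lac_parameter_set`.
#' @export
read_params <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- cfg$regulatory; k <- cfg$kinetic; tr <- cfg$transport
  structure(
    list(
      label = cfg$label,
      reg = regulatory_params(r$eps1_per_nM, r$eps2_per_nM, r$eps3_per_nM,
                              K_A = r$K_A_uM, h = r$hill_h,
                              crp_factor = r$crp_factor),
      kin = kinetic_params(k_c = k$k_c_nM_per_min, k_y = k$k_y_nM_per_min,
                           k_z = k$k_z_nM_per_min, gamma = k$gamma_per_min,
                           gamma_m = k$gamma_m_per_min, k_l = k$k_l_per_min),
      transport = transport_params(v_y = tr$v_y_per_min, K_ext = tr$K_ext_mM,
                                   lam = tr$lambda, v_z = tr$v_z_per_min,
                                   K = tr$K_lacZ_mM),
      I_auto = cfg$reference_nM$I_auto,
      I_full = cfg$reference_nM$I_full
    ),
    class = "lac_parameter_set"
  )
}
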