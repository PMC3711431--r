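#' Active (allolactose-free) LacI concentration
#'
#' Allolactose binds and unbinds LacI fast compared with gene expression, so
#' the active repressor pool follows the total instantaneously through a
#' Hill inactivation curve: `I_star = I_total / (1 + (A / K_A)^h)`.
#'
#' @param I_total Total LacI tetramer concentration (nM), vectorized.
#' @param A Internal allolactose concentration (uM), vectorized.
#' @param params A [regulatory_params()] object.
#' @return Active LacI concentration (nM).
#' @export
#' @examples
#' active_repressor(30, 0, regulatory_params()) # 30: no inducer
#' active_repressor(90, 1, regulatory_params()) # 45: half at A = K_A, h = 2
active_repressor <- function(I_total, A, params = regulatory_params()) {
  if (any(I_total < 0) || any(A < 0)) {
    stop("I_total and A must be non-negative")
  }
  I_total / (1 + (A / params$K_A)^params$h)
}

#' Probabilities of the four promoter binding states
#'
#' The promoter region is modelled with four allowed configurations: all
#' operators free, LacI bound at O1 only, the O1-O2 loop, and the O1-O3
#' loop. Their statistical weights are `(1, eps1 * I, eps2 * I, eps3 * I)`
#' at active LacI concentration `I`, normalized to probabilities.
#'
#' @param I_star Active LacI concentration (nM), vectorized.
#' @inheritParams active_repressor
#' @return A tibble with columns `p_free`, `p_O1`, `p_loop12`, `p_loop13`,
#'   one row per element of `I_star`; rows sum to 1.
#' @export
state_probabilities <- function(I_star, params = regulatory_params()) {
  stopifnot("I_star must be non-negative" = all(I_star >= 0))
  z <- 1 + (params$eps1 + params$eps2 + params$eps3) * I_star
  tibble::tibble(
    p_free = 1 / z,
    p_O1 = params$eps1 * I_star / z,
    p_loop12 = params$eps2 * I_star / z,
    p_loop13 = params$eps3 * I_star / z
  )
}

#' Activity of the lac operon promoter
#'
#' Transcription of *lacZYA* is blocked whenever O1 is occupied (alone or in
#' either loop), so the activity is the probability that O1 is free times
#' the cAMP-CRP factor:
#' `crp_factor / (1 + (eps1 + eps2 + eps3) * I_star)`.
#'
#' @inheritParams state_probabilities
#' @return Activity fraction in (0, 1], vectorized over `I_star`.
#' @export
#' @examples
#' operon_activity(0) # 0.9, the cAMP-CRP factor
operon_activity <- function(I_star, params = regulatory_params()) {
  stopifnot("I_star must be non-negative" = all(I_star >= 0))
  eps_sum <- params$eps1 + params$eps2 + params$eps3
  params$crp_factor / (1 + eps_sum * I_star)
}

#' Activity of the lacI promoter under roadblock autoregulation
#'
#' *lacI* transcription is roadblocked only in the O1-O3 looped state, so
#' its activity is the probability of not being in that state:
#' `(1 + (eps1 + eps2) * I_star) / (1 + (eps1 + eps2 + eps3) * I_star)`.
#' As `I_star` grows this saturates at `(eps1 + eps2) / (eps1 + eps2 +
#' eps3)`, the residual activity that fixes the autoregulated-to-full LacI
#' ratio (1/3 for the default calibration).
#'
#' @inheritParams state_probabilities
#' @return Activity fraction in (0, 1], vectorized over `I_star`.
#' @export
laci_activity <- function(I_star, params = regulatory_params()) {
  stopifnot("I_star must be non-negative" = all(I_star >= 0))
  eps12 <- params$eps1 + params$eps2
  eps_sum <- eps12 + params$eps3
  (1 + eps12 * I_star) / (1 + eps_sum * I_star)
}
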