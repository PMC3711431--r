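#' Lactose import flux through LacY
#'
#' Michaelis-Menten import of external lactose:
#' `v_y * Y * L_ext / (K_ext + L_ext)`, saturating at `v_y * Y`.
#' Under the 1 nM = 1 molecule/cell convention the flux is in molecules per
#' minute when `Y` is in nM.
#'
#' @param Y LacY concentration (nM) or molecule count, vectorized.
#' @param L_ext External lactose concentration (mM); `Inf` gives the
#'   saturated flux.
#' @param params A [transport_params()] object.
#' @return Import flux (nM/min), vectorized.
#' @export
import_flux <- function(Y, L_ext, params = transport_params()) {
  stopifnot("Y and L_ext must be non-negative" = all(Y >= 0) && all(L_ext >= 0))
  frac <- ifelse(is.infinite(L_ext), 1, L_ext / (params$K_ext + L_ext))
  params$v_y * Y * frac
}

#' Quasi-steady-state internal lactose and allolactose
#'
#' Sugar fluxes equilibrate much faster than gene expression, so internal
#' lactose `L` is eliminated algebraically from the balance
#' import = export + removal by LacZ:
#' `v_y*Y*L_ext/(K_ext+L_ext) = v_y*Y*L/(lam*K_ext + L) + 2*v_z*Z*L/(K + L)`.
#' Clearing denominators gives the quadratic `a*L^2 + b*L + c = 0` with
#' `a = v_y*Y + 2*v_z*Z - J`, `b = v_y*Y*K + 2*v_z*Z*lam*K_ext -
#' J*(lam*K_ext + K)` and `c = -J*lam*K_ext*K`, `J` being the import flux.
#' Since `c <= 0 < a` for any finite `L_ext`, exactly one root is
#' non-negative; it is computed with the numerically stable quadratic
#' formula to avoid cancellation at small `J`. Setting the allolactose
#' balance to zero forces equal saturation fractions of the two LacZ
#' reactions, hence `A = L`.
#'
#' @param Y LacY level (nM), vectorized.
#' @param Z LacZ tetramer level (nM), vectorized.
#' @param L_ext External lactose (mM); `Inf` for the saturated-import limit.
#' @param params A [transport_params()] object.
#' @return A tibble with columns `L_uM` and `A_uM` (equal by construction).
#' @export
#' @examples
#' qss_sugar(9400, 10400, 5) # internal lactose in the mM range
qss_sugar <- function(Y, Z, L_ext, params = transport_params()) {
  stopifnot("inputs must be non-negative" =
              all(Y >= 0) && all(Z >= 0) && all(L_ext >= 0))
  n <- max(length(Y), length(Z), length(L_ext))
  Y <- rep_len(Y, n); Z <- rep_len(Z, n); L_ext <- rep_len(L_ext, n)
  L <- numeric(n)
  lamKe <- params$lam * params$K_ext * 1000 # uM
  K <- params$K * 1000                      # uM
  for (i in seq_len(n)) {
    if (L_ext[i] <= 0 || Y[i] <= 0) next
    J <- import_flux(Y[i], L_ext[i], params)
    a <- params$v_y * Y[i] + 2 * params$v_z * Z[i] - J
    if (a <= 0) {
      # only possible at L_ext = Inf with Z = 0: export alone must balance
      # the saturated import, which it cannot at finite L
      L[i] <- Inf
      next
    }
    b <- params$v_y * Y[i] * K + 2 * params$v_z * Z[i] * lamKe -
      J * (lamKe + K)
    cc <- -J * lamKe * K
    s <- sqrt(b * b - 4 * a * cc)
    q <- -(b + sign(b) * s) / 2
    if (b == 0) q <- -s / 2
    L[i] <- max(q / a, cc / q)
  }
  tibble::tibble(L_uM = L, A_uM = L)
}

#' Lactose consumption flux by LacZ
#'
#' Total lactose removal (hydrolysis plus conversion to allolactose):
#' `2 * v_z * Z * L / (K + L)`. At quasi-steady state the hydrolysis of
#' allolactose exactly balances its production, so this is also the total
#' lactose metabolized per minute, in molecules/min under 1 nM = 1 molecule.
#'
#' @param Z LacZ tetramer level (nM), vectorized.
#' @param L Internal lactose (uM), vectorized; may come from [qss_sugar()].
#' @param params A [transport_params()] object.
#' @return Molecules of lactose consumed per minute.
#' @export
consumption_flux <- function(Z, L, params = transport_params()) {
  stopifnot("inputs must be non-negative" = all(Z >= 0) && all(L >= 0))
  K <- params$K * 1000 # uM
  frac <- ifelse(is.infinite(L), 1, L / (K + L))
  2 * params$v_z * Z * frac
}
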