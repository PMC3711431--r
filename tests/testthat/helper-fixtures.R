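# shared fixtures: parameter sets and variants used across the suite
set_A <- parameter_set("set_A")
set_B <- parameter_set("set_B")
wt <- variant_spec("autoregulated")
fixed_low <- variant_spec("fixed_low")
fixed_high <- variant_spec("fixed_high")

# independent bisection oracle for the quasi-steady-state sugar balance:
# solves import = export + 2 * conversion on the un-expanded flux equation
qss_bisect <- function(Y, Z, L_ext, tp = transport_params(), tol = 1e-12) {
  if (L_ext <= 0 || Y <= 0) return(0)
  lamKe <- tp$lam * tp$K_ext * 1000
  K <- tp$K * 1000
  J <- tp$v_y * Y * L_ext / (tp$K_ext + L_ext)
  bal <- function(L) J - tp$v_y * Y * L / (lamKe + L) -
    2 * tp$v_z * Z * L / (K + L)
  hi <- 10 * lamKe
  while (bal(hi) > 0) hi <- hi * 10
  stats::uniroot(bal, c(0, hi), tol = tol * hi)$root
}
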