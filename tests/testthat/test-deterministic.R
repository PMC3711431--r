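test_that("derivatives at an empty cell give full lacI transcription", {
  d <- lac_derivatives(c(I_m = 0, I = 0, Y = 0), 0, set_A, wt)
  expect_equal(d[["I_m"]], set_A$kin$k_c)
  expect_equal(d[["I"]], 0)
  expect_equal(d[["Y"]], set_A$kin$k_y * 0.9)
})

test_that("hand-built fixed point zeroes the lacI branch derivatives", {
  kin <- set_A$kin
  # at zero lactose I* = I; choose I on the autoregulation fixed point
  I <- steady_state(0, set_A, wt)$I_nM
  f <- laci_activity(I, set_A$reg)
  Im <- kin$k_c * f / kin$gamma_m
  expect_equal(I, kin$k_l * Im / kin$gamma, tolerance = 1e-6)
  d <- lac_derivatives(c(I_m = Im, I = I, Y = 10), 0, set_A, wt)
  expect_equal(d[["I_m"]], 0, tolerance = 1e-12)
  expect_equal(d[["I"]], 0, tolerance = 1e-6)
})

test_that("autoregulated LacI settles on the quadratic root near 30 nM", {
  ss <- steady_state(0, set_A, wt)
  # oracle: fixed point I = I_full * laci_activity(I) is the positive root
  # of (1300/30) I^2 - 1299 I - 90 = 0
  a <- 1300 / 30; b <- -(1300 - 1) ; cc <- -90
  root <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  expect_equal(ss$I_nM, root, tolerance = 1e-6)
  expect_equal(root, 30.046, tolerance = 1e-4)
  # repressed LacY: closed form 0.9 k_y / (gamma (1 + sum(eps) I))
  eps_sum <- with(set_A$reg, eps1 + eps2 + eps3)
  expect_equal(ss$Y_nM,
               0.9 * set_A$kin$k_y / (set_A$kin$gamma * (1 + eps_sum * root)),
               tolerance = 1e-6)
})

test_that("fixed-high variant reaches the fully expressed LacI level", {
  ss <- steady_state(0, set_A, fixed_high)
  expect_equal(ss$I_nM, 90, tolerance = 1e-8)
  ssB <- steady_state(0, set_B, fixed_high)
  expect_equal(ssB$I_nM, 30, tolerance = 1e-8)
})

test_that("induced plateau approaches the closed-form maximum", {
  ss <- steady_state(Inf, set_A, wt)
  ymax <- 0.9 * set_A$kin$k_y / set_A$kin$gamma # 9348.8 at zero repression
  expect_lt(ss$Y_nM, ymax)
  expect_gt(ss$Y_nM, 0.999 * ymax) # residual active LacI barely represses
  # fixed-point residual at the steady state
  d <- lac_derivatives(c(I_m = ss$I_m_nM, I = ss$I_nM, Y = ss$Y_nM),
                       Inf, set_A, wt)
  expect_lt(sqrt(sum(d^2)), 1e-6 * sqrt(sum(ss$I_nM^2 + ss$Y_nM^2)))
})

test_that("steady states are integration fixed points across conditions", {
  for (L_ext in c(0, 0.05, 5)) {
    ss <- steady_state(L_ext, set_A, wt)
    d <- lac_derivatives(c(I_m = ss$I_m_nM, I = ss$I_nM, Y = ss$Y_nM),
                         L_ext, set_A, wt)
    norm_state <- sqrt(ss$I_m_nM^2 + ss$I_nM^2 + ss$Y_nM^2)
    expect_lt(sqrt(sum(d^2)), 1e-8 * norm_state)
  }
})

test_that("variant clamp reduces wild type to the constitutive model", {
  # with eps3 = 0 the roadblock is gone and laci activity tends to 1;
  # clamping at the same constant must give the same dynamics
  regc <- regulatory_params(eps1 = 0.6, eps2 = 13.844, eps3 = 0)
  psc <- set_A; psc$reg <- regc
  d_wt <- lac_derivatives(c(I_m = 0.02, I = 25, Y = 100), 0.2, psc, wt)
  f_eq <- laci_activity(active_repressor(
    25, qss_sugar(100, 100 / 0.9, 0.2)$A_uM, regc), regc)
  d_cl <- lac_derivatives(c(I_m = 0.02, I = 25, Y = 100), 0.2, psc,
                          variant_spec("fixed_low", fixed_activity = f_eq))
  expect_equal(d_wt, d_cl, tolerance = 1e-12)
})

test_that("integration preserves non-negativity from non-negative starts", {
  tr <- simulate_deterministic(set_A, wt, profile = 5,
                               times = seq(0, 400, 10))
  expect_true(all(as.matrix(tr[, 2:5]) >= -1e-12))
  tr0 <- simulate_deterministic(set_A, wt,
                                profile = switch_protocol(100, 200, 300),
                                times = seq(0, 300, 5))
  expect_true(all(as.matrix(tr0[, 2:5]) >= -1e-12))
  # lactose appears only during the on-phase
  expect_true(all(tr0$L_uM[tr0$time_min < 100] == 0))
  expect_true(any(tr0$L_uM[tr0$time_min > 100 & tr0$time_min < 200] > 0))
})

test_that("dose-response is monotone and brackets the WT between controls", {
  grid <- c(0.003, 0.01, 0.03, 0.1, 0.3)
  cw <- dose_response(grid, set_A, wt)
  cl <- dose_response(grid, set_A, fixed_low)
  ch <- dose_response(grid, set_A, fixed_high)
  expect_false(is.unsorted(cw$Y_nM))
  # fixed-low has least repressor, fixed-high most, WT in between
  expect_true(all(cl$Y_nM >= cw$Y_nM - 1e-6))
  expect_true(all(cw$Y_nM >= ch$Y_nM - 1e-6))
  expect_error(dose_response(c(0.1, 0.01)), "sorted")
})

test_that("cumulative metabolized lactose has the right limits", {
  expect_equal(cumulative_metabolized(0, 80, set_A, wt), 0)
  # fully induced upper bound: 2 v_z Z_max per minute
  zmax <- 0.9 * set_A$kin$k_z / set_A$kin$gamma
  bound <- 2 * set_A$transport$v_z * zmax * 80
  got <- cumulative_metabolized(5, 80, set_A, wt)
  expect_lt(got, bound)
  expect_gt(got, 0.5 * bound) # the induced cell runs near saturation
})
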