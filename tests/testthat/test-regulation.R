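test_that("active repressor follows the Hill inactivation curve", {
  reg <- regulatory_params()
  expect_equal(active_repressor(30, 0, reg), 30)
  expect_equal(active_repressor(90, 1, reg), 45) # A = K_A, h = 2 halves it
  expect_lt(active_repressor(90, 1e9, reg), 1e-12)
  # strictly decreasing in allolactose
  A <- sort(runif(50, 0, 50))
  expect_true(all(diff(active_repressor(60, A, reg)) < 0))
  expect_error(active_repressor(-1, 0, reg), "non-negative")
  expect_error(active_repressor(1, -2, reg), "non-negative")
})

test_that("binding-state probabilities normalize and keep weight ratios", {
  reg <- regulatory_params()
  expect_equal(unlist(state_probabilities(0, reg)),
               c(p_free = 1, p_O1 = 0, p_loop12 = 0, p_loop13 = 0))
  withr::with_seed(7, {
    I_star <- c(0, 10^runif(100, -3, 3))
    p <- state_probabilities(I_star, reg)
    expect_true(all(as.matrix(p) >= 0 & as.matrix(p) <= 1))
    expect_equal(rowSums(as.matrix(p)), rep(1, 101), tolerance = 1e-12)
  })
  # ratio of bound-state probabilities is the epsilon ratio at any I*
  p30 <- state_probabilities(30, reg)
  expect_equal(p30$p_loop13 / p30$p_O1, reg$eps3 / reg$eps1)
  expect_equal(reg$eps3 / reg$eps1, (2600 / 90) / 0.6, tolerance = 1e-12)
})

test_that("operon activity: CRP factor, fold repression, monotonicity", {
  reg <- regulatory_params()
  expect_equal(operon_activity(0, reg), 0.9)
  # calibrated epsilons give 1301-fold repression at the 30 nM reference
  # (printed as 1300 under the strong-binding approximation)
  expect_equal(operon_activity(0, reg) / operon_activity(30, reg),
               1301, tolerance = 1e-12)
  # O1 only: exact arithmetic gives 19 where the approximation quotes 18
  o1 <- regulatory_params(eps1 = 0.6, eps2 = 0, eps3 = 0)
  expect_equal(operon_activity(0, o1) / operon_activity(30, o1), 19)
  I_star <- seq(0, 100, by = 0.5)
  expect_true(all(diff(operon_activity(I_star, reg)) < 0))
})

test_that("lacI roadblock activity has the right limits", {
  reg <- regulatory_params()
  expect_equal(laci_activity(0, reg), 1)
  expect_equal(laci_activity(1e12, reg), 1 / 3, tolerance = 1e-9)
  expect_equal(laci_activity(30, reg),
               (1 + (1300 / 90) * 30) / (1 + (1300 / 30) * 30))
  I_star <- seq(0, 100, by = 0.5)
  expect_true(all(diff(laci_activity(I_star, reg)) < 0))
})

test_that("epsilon calibration solves the fold-repression constraints", {
  eps <- calibrate_epsilons(1300, 18, 30, 3)
  expect_equal(unname(eps), c(0.6, 415.33 / 30, 866.66 / 30),
               tolerance = 1e-4)
  # imposed structure: eps1 + eps2 = eps3 / 2 for ratio 3
  expect_equal(eps[["eps1"]] + eps[["eps2"]], eps[["eps3"]] / 2,
               tolerance = 1e-12)
  # parameter set B: same folds at the 10 nM reference scale epsilons 3x
  epsB <- calibrate_epsilons(1300, 18, 10, 3)
  expect_equal(unname(epsB), unname(eps) * 3, tolerance = 1e-12)
  expect_equal(unname(epsB), c(1.8, 41.533, 86.667), tolerance = 1e-4)
  # round-trip: operon fold repression at the reference reproduces the
  # calibration target within the strong-binding slack of 1
  for (I_ref in c(10, 30)) {
    e <- calibrate_epsilons(1300, 18, I_ref, 3)
    fold <- 1 + sum(e) * I_ref
    expect_lte(abs(fold - 1300), 1)
  }
  # residual lacI activity ratio equals 1 / full_to_auto_ratio exactly
  r <- regulatory_params(eps[["eps1"]], eps[["eps2"]], eps[["eps3"]])
  expect_equal(laci_activity(1e14, r) / laci_activity(0, r), 1 / 3,
               tolerance = 1e-9)
  # infeasible: O1-only fold too large for the imposed loop structure
  expect_error(calibrate_epsilons(100, 40, 30, 3), "infeasible")
  expect_error(calibrate_epsilons(10, 20, 30, 3), "fold_total > fold_O1")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(regulatory_params(eps1 = -1), "non-negative")
  expect_error(regulatory_params(crp_factor = 1.2), "crp_factor")
  expect_error(regulatory_params(h = 0.5), "h must be")
  expect_error(transport_params(v_y = 0), "positive")
  expect_error(variant_spec("fixed_low", fixed_activity = 2), "fixed_activity")
})
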