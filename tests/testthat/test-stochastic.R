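test_that("propensities vanish and activate where they should", {
  a0 <- lac_propensities(c(n_Im = 0, n_I = 0, n_Y = 0, n_Z = 0), 0, set_A, wt)
  expect_true(all(a0[c("Im_decay", "I_prod", "I_decay",
                       "Y_decay", "Z_decay")] == 0))
  expect_true(all(a0[c("Im_prod", "Y_prod", "Z_prod")] > 0))
  expect_equal(a0[["Im_prod"]], set_A$kin$k_c)
  # clamped promoter ignores the repressor level
  ah <- lac_propensities(c(n_Im = 0, n_I = 500, n_Y = 0, n_Z = 0), 0,
                         set_A, fixed_high)
  expect_equal(ah[["Im_prod"]], set_A$kin$k_c)
  expect_true(all(lac_propensities(c(n_Im = 2, n_I = 40, n_Y = 90,
                                     n_Z = 100), 3, set_A, wt) >= 0))
})

test_that("signed channel sums reproduce the deterministic derivatives", {
  states <- list(
    c(n_Im = 0, n_I = 30, n_Y = 7, n_Z = 8),
    c(n_Im = 2, n_I = 0, n_Y = 4000, n_Z = 5000),
    c(n_Im = 1, n_I = 90, n_Y = 100, n_Z = 111)
  )
  for (st in states) {
    for (L_ext in c(0, 0.05, 5)) {
      for (v in list(wt, fixed_low, fixed_high)) {
        a <- lac_propensities(st, L_ext, set_A, v)
        d <- lac_derivatives(
          c(I_m = st[["n_Im"]], I = st[["n_I"]], Y = st[["n_Y"]],
            Z = st[["n_Z"]]),
          L_ext, set_A, v, slave_Z = FALSE
        )
        expect_equal(unname(a[c(1, 3, 5, 7)] - a[c(2, 4, 6, 8)]),
                     unname(d), tolerance = 1e-12)
      }
    }
  }
})

test_that("trajectories are integer, non-negative, single-step events", {
  tr <- simulate_lac(set_A, wt, profile = 0.05, t_end = 300,
                     init = c(n_Im = 0, n_I = 30, n_Y = 7, n_Z = 8),
                     seed = 99)
  m <- as.matrix(tr[, c("n_Im", "n_I", "n_Y", "n_Z")])
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  steps <- abs(diff(m))
  expect_true(all(rowSums(steps) == 1)) # one species changes by 1 per event
  expect_true(all(diff(tr$t_min) >= 0))
})

test_that("identical seeds give bit-identical trajectories", {
  run <- function() simulate_lac(set_A, wt,
                                 profile = switch_protocol(100, 200, 300),
                                 seed = 123, sample_interval = 5)
  t1 <- run()
  t2 <- run()
  expect_identical(t1$n_Y, t2$n_Y)
  expect_identical(t1$n_I, t2$n_I)
  expect_identical(attr(t1, "final_state"), attr(t2, "final_state"))
  t3 <- simulate_lac(set_A, wt, profile = switch_protocol(100, 200, 300),
                     seed = 124, sample_interval = 5)
  expect_false(identical(t1$n_Y, t3$n_Y))
})

test_that("pure-death dynamics match exponential decay theory", {
  # zero all production: only first-order decay at rate gamma remains, so
  # <n_Y(t)> = n0 exp(-gamma t); check the ensemble against theory
  dead <- set_A
  dead$kin <- kinetic_params(k_c = 1e-300, k_y = 1e-300, k_z = 1e-300,
                             k_l = 1e-300)
  n0 <- 100
  t_obs <- 50
  withr::with_seed(7, {
    finals <- vapply(1:1000, function(i) {
      tr <- simulate_lac(dead, fixed_high, profile = 0, t_end = t_obs,
                         init = c(n_Im = 0, n_I = 0, n_Y = n0, n_Z = 0),
                         sample_interval = t_obs)
      attr(tr, "final_state")[["n_Y"]]
    }, numeric(1))
  })
  p_surv <- exp(-set_A$kin$gamma * t_obs)
  se <- sqrt(n0 * p_surv * (1 - p_surv)) / sqrt(1000)
  expect_lt(abs(mean(finals) - n0 * p_surv), 3 * se)
})

test_that("time-averaged counts agree with the mean field at high copy", {
  # fully induced: promoter activities are nearly constant, so the counts
  # are linear birth-death processes whose stationary mean is the ODE value
  ss <- steady_state(100, set_A, wt)
  st <- simulate_lac(
    set_A, wt, profile = 100, t_end = 15000,
    init = c(n_Im = round(ss$I_m_nM), n_I = round(ss$I_nM),
             n_Y = round(ss$Y_nM), n_Z = round(ss$Z_nM)),
    seed = 17, sample_interval = 1
  )
  tail_part <- st[st$t_min > 1500, ]
  # Poisson-scale fluctuations with autocorrelation time 1/gamma
  se <- sqrt(ss$Y_nM) / sqrt(13500 * set_A$kin$gamma / 2)
  expect_lt(abs(mean(tail_part$n_Y) - ss$Y_nM), 4 * se)
})

test_that("relative LacY fluctuations shrink as copy numbers scale up", {
  # at full induction the counts are near-linear birth-death processes, so
  # multiplying the operon throughput tenfold should cut the stationary
  # CV^2 of LacY about tenfold (intrinsic noise ~ 1/mean)
  scaled <- set_A
  scaled$kin <- kinetic_params(k_y = 900, k_z = 1000)
  run_cv2 <- function(ps, seed) {
    ss <- steady_state(100, ps, wt)
    tr <- simulate_lac(ps, wt, profile = 100, t_end = 4000,
                       init = c(n_Im = round(ss$I_m_nM),
                                n_I = round(ss$I_nM),
                                n_Y = round(ss$Y_nM),
                                n_Z = round(ss$Z_nM)),
                       seed = seed, sample_interval = 1)
    smp <- tr$n_Y[tr$t_min > 400]
    summarize_counts(smp)$cv2
  }
  base_cv2 <- run_cv2(set_A, 5)
  scaled_cv2 <- run_cv2(scaled, 5)
  expect_lt(scaled_cv2, base_cv2 / 3) # ~10x in theory; loose factor here
})

test_that("switch-time ensembles are reproducible and sanely ordered", {
  proto <- switch_protocol(300, 1200, 2000)
  sw1 <- switch_times(set_A, wt, proto, n_runs = 4, seed = 5)
  sw2 <- switch_times(set_A, wt, proto, n_runs = 4, seed = 5)
  expect_identical(sw1$times, sw2$times)
  expect_true(all(sw1$times$turn_on_min > 0, na.rm = TRUE))
  # deterministic threshold-crossing brackets the stochastic ensemble:
  # the ODE path from the same initial state crosses within the
  # ensemble's range
  tr <- simulate_deterministic(set_A, wt, profile = 5,
                               times = seq(0, 1000, 0.5),
                               init = c(I_m = 0, I = 30, Y = 7))
  t_det <- tr$time_min[which(tr$Y_nM >= 9025)[1]]
  expect_gt(t_det, min(sw1$times$turn_on_min))
  expect_lt(abs(t_det - mean(sw1$times$turn_on_min)), 200)
})

test_that("fraction-on counts are zero at zero observation time epsilon", {
  fo <- fraction_on_at(set_A, fixed_high, t_after_shift = 0.01,
                       n_runs = 5, equilibration = 10, seed = 3)
  expect_equal(fo$n_on, 0)
  expect_equal(fo$fraction, 0)
  expect_error(fraction_on_at(set_A, wt, t_after_shift = 0), "positive")
})
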