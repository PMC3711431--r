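test_that("stationary protocol is one zero-lactose segment", {
  p <- stationary_protocol(11e6, 1e6)
  expect_equal(nrow(p), 1)
  expect_equal(p$L_ext_mM, 0)
  expect_equal(profile_horizon(p), 11e6)
  expect_equal(attr(p, "burn_in_min"), 1e6)
  scaled <- stationary_protocol(1.1e5, 1e4)
  expect_equal(profile_horizon(scaled), 1.1e5)
  expect_error(stationary_protocol(100, 100), "duration > burn_in")
})

test_that("switch protocol has the 0 / 5 mM / 0 step structure", {
  p <- switch_protocol()
  expect_equal(p$start_min, c(0, 10000, 20000))
  expect_equal(p$L_ext_mM, c(0, 5, 0))
  expect_equal(profile_horizon(p), 30000)
  scaled <- switch_protocol(2000, 4000, 6000)
  expect_equal(scaled$L_ext_mM, c(0, 5, 0))
  expect_error(switch_protocol(t_on = 1000, t_off = 1000), "positive length")
  expect_equal(profile_at(p, c(0, 9999, 10000, 19999.9, 20000, 25000)),
               c(0, 0, 5, 5, 0, 0))
})

test_that("profiles and parameter sets round-trip through JSON", {
  dir <- withr::local_tempdir()
  p <- switch_protocol(2000, 4000, 6000, L_on = 2.5)
  f <- file.path(dir, "profile.json")
  write_profile(p, f)
  p2 <- read_profile(f)
  expect_equal(p2$start_min, p$start_min)
  expect_equal(p2$L_ext_mM, p$L_ext_mM)
  expect_equal(profile_horizon(p2), profile_horizon(p))
  expect_equal(attr(p2, "t_on_min"), 2000)

  g <- file.path(dir, "params.json")
  write_params(set_B, g)
  b2 <- read_params(g)
  expect_equal(b2$reg, set_B$reg)
  expect_equal(b2$kin, set_B$kin)
  expect_equal(b2$transport, set_B$transport)
  expect_equal(b2$I_auto, 10)
})

test_that("parameter sets A and B share fold repression at their scales", {
  expect_equal(set_A$reg$eps1, 0.6)
  expect_equal(set_A$I_full, 90)
  expect_equal(set_B$reg$eps1, 1.8)
  expect_equal(set_B$I_full, 30)
  # set B translates three times slower
  expect_equal(set_B$kin$k_l, set_A$kin$k_l / 3)
  foldA <- operon_activity(0, set_A$reg) / operon_activity(30, set_A$reg)
  foldB <- operon_activity(0, set_B$reg) / operon_activity(10, set_B$reg)
  expect_equal(foldA, foldB, tolerance = 1e-12)
  expect_error(parameter_set("set_C"))
})

test_that("set B deterministic steady state scales to ~10 nM LacI", {
  ss <- steady_state(0, set_B, wt)
  # the autoregulation fixed point scales as 1/3 of set A exactly
  ssA <- steady_state(0, set_A, wt)
  expect_equal(ss$I_nM, ssA$I_nM / 3, tolerance = 1e-6)
  expect_equal(ss$I_nM, 10.015, tolerance = 1e-3)
})

test_that("environment profile validation catches malformed inputs", {
  expect_error(environment_profile(c(1, 2), c(0, 1), 10), "begin at 0")
  expect_error(environment_profile(c(0, 5, 5), c(0, 1, 0), 10),
               "strictly increasing")
  expect_error(environment_profile(c(0, 5), c(0, -1), 10), "non-negative")
  expect_error(environment_profile(c(0, 5), c(0, 1), 5), "horizon")
})
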