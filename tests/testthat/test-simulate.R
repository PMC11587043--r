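test_that("3MT mean curve follows the closed-form exponential", {
  st <- simulate_3mt(canonical_3mt_profile())
  tau <- 15000 / 450
  expect_equal(st$truth$tau, tau)
  expect_equal(st$trace$power[st$trace$time == 0], 700)
  # at t = tau the excess above CP has decayed by 1/e
  p_tau <- approx(st$trace$time, st$trace$power, xout = tau)$y
  expect_equal(p_tau, 250 + 450 / exp(1), tolerance = 1e-3)
})

test_that("3MT work above CP matches high-resolution quadrature", {
  st <- simulate_3mt(canonical_3mt_profile(), fs = 1)
  tau <- st$truth$tau
  oracle <- integrate(function(t) 450 * exp(-t / tau), 0, 180,
                      rel.tol = 1e-10)$value
  expect_equal(oracle, 15000 * (1 - exp(-180 / tau)), tolerance = 1e-8)
  trapz <- integrate_above(st$trace, 250, 0, 180)
  expect_equal(trapz, oracle, tolerance = 0.01)
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_3mt(canonical_3mt_profile(noise_sd = 5, seed = 9))
  b <- simulate_3mt(canonical_3mt_profile(noise_sd = 5, seed = 9))
  d <- simulate_3mt(canonical_3mt_profile(noise_sd = 5, seed = 10))
  expect_identical(a$trace$power, b$trace$power)
  expect_false(identical(a$trace$power, d$trace$power))
})

test_that("CPT phase boundaries and truth records follow the closed forms", {
  st <- simulate_cpt(canonical_profile(), 300)
  expect_equal(st$truth$t_fail, 0.8 * 12000 / 50)   # 192 s
  expect_equal(st$truth$tau2, 0.2 * 12000 / 50)     # 48 s
  expect_equal(st$truth$constant_w_prime_true, 9600)
  # decline is cut 1 W above CP; the lost tail integrates to tau2 * 1 W
  expect_equal(st$truth$unaccounted_w_prime_true, 2400 - 48)
  expect_equal(st$truth$constant_w_prime_true +
                 st$truth$unaccounted_w_prime_true + st$truth$tau2,
               12000)
  expect_error(simulate_cpt(canonical_profile(), 250), "exceed cp")
})

test_that("f_unspent = 0 yields an empty decline straight to the plateau", {
  st <- simulate_cpt(canonical_profile(f_unspent = 0), 300)
  expect_equal(st$truth$decline_s, 0)
  expect_equal(st$truth$unaccounted_w_prime_true, 0)
  expect_equal(st$truth$t_fail, 12000 / 50)
  after <- st$trace$power[st$trace$time >= st$truth$t_fail]
  expect_true(all(after == 250))
})

test_that("noise-free CPT work above CP is conserved (quadrature oracle)", {
  st <- simulate_cpt(canonical_profile(), 300, fs = 8)
  end_decline <- st$truth$t_fail + st$truth$decline_s
  t1 <- st$trace$time[which.min(abs(st$trace$time - end_decline))]
  trapz <- integrate_above(st$trace, 250, 0, t1)
  oracle <- 12000 - st$truth$tau2  # truncated tail excluded
  expect_equal(trapz, oracle, tolerance = 1e-3)
})

test_that("increasing f_unspent shrinks constant W' and lengthens the decline", {
  fs <- c(0.05, 0.2, 0.4, 0.7)
  sims <- lapply(fs, function(f) simulate_cpt(canonical_profile(f_unspent = f), 300))
  cw <- vapply(sims, function(s) s$truth$constant_w_prime_true, numeric(1))
  dec <- vapply(sims, function(s) s$truth$decline_s, numeric(1))
  expect_true(all(diff(cw) < 0))
  expect_true(all(diff(dec) > 0))
})

test_that("simulated cohorts have the prescribed structure", {
  coh <- simulate_cohort(5, noise_sd = 5, seed = 31)
  expect_length(coh, 5L)
  for (ath in coh) {
    expect_length(ath$cpts, 4L)
    for (k in seq_along(ath$cpts)) {
      tgt <- attr(ath$cpts[[k]], "t_target")
      expect_equal(ath$cpts[[k]]$meta$prescribed_power,
                   ath$profile$cp + ath$profile$w_prime / tgt)
      expect_gt(ath$cpts[[k]]$meta$prescribed_power, ath$profile$cp)
    }
  }
  coh2 <- simulate_cohort(5, noise_sd = 5, seed = 31)
  expect_identical(coh[[3]]$cpts[[2]]$trace$power,
                   coh2[[3]]$cpts[[2]]$trace$power)
})

test_that("invalid profiles are rejected", {
  expect_error(athlete_profile(cp = -1, w_prime = 100, p_max = 10), "cp")
  expect_error(athlete_profile(cp = 250, w_prime = 100, p_max = 200), "p_max")
  expect_error(athlete_profile(cp = 250, w_prime = 100, p_max = 700,
                               f_unspent = 1), "f_unspent")
  expect_error(simulate_3mt(canonical_profile(), duration_s = 30), ">= 60")
})
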