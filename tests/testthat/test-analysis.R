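test_that("integrate_above recovers simple geometric areas", {
  ramp <- power_trace(0:100, seq(400, 300, length.out = 101))
  expect_equal(integrate_above(ramp, 300, 0, 100), 5000)  # triangle
  flat <- power_trace(0:59, rep(250, 60))
  expect_equal(integrate_above(flat, 250, 0, 59), 0)
  expect_error(integrate_above(flat, 250, 0, 120), "outside the trace")
  expect_error(integrate_above(flat, 250, 10, 10), "precede")
})

test_that("clipping suppresses only the negative contributions", {
  # 100 s at +10 W, then 100 s at -10 W relative to the reference
  tr <- power_trace(0:200, c(rep(310, 100), 300, rep(290, 100)))
  signed <- integrate_above(tr, 300, 0, 200)
  clipped <- integrate_above(tr, 300, 0, 200, clip_negative = TRUE)
  expect_equal(signed, 0)
  expect_equal(clipped, 99 * 10 + 5)  # 99 full trapezoids + one half-height
  expect_gte(clipped, signed)
})

test_that("trapezoidal integration matches quadrature on the 3MT decline", {
  tau <- 15000 / 450
  oracle <- integrate(function(t) 450 * exp(-t / tau), 0, 180,
                      rel.tol = 1e-10)$value
  for (fs in c(1, 8)) {
    st <- simulate_3mt(canonical_3mt_profile(), fs = fs)
    got <- integrate_above(st$trace, 250, 0, 180)
    tol <- if (fs == 1) 0.005 else 0.0005
    expect_equal(got, oracle, tolerance = tol)
  }
})

test_that("3MT analysis: constant trace has EP equal to power and zero W'", {
  tr <- power_trace(0:179, rep(250, 180))
  res <- analyze_3mt(tr)
  expect_equal(res$ep, 250)
  expect_equal(res$w_prime, 0)
  expect_error(analyze_3mt(power_trace(0:9, rep(250, 10))), "shorter")
})

test_that("3MT analysis recovers the analytic EP and W' of the model curve", {
  st <- simulate_3mt(canonical_3mt_profile(), fs = 1)
  res <- analyze_3mt(st$trace)
  # oracle: discrete mean of the closed-form curve over the last 30 s
  tt <- 150:180
  ep_oracle <- mean(250 + 450 * exp(-tt / st$truth$tau))
  expect_equal(res$ep, ep_oracle, tolerance = 1e-9)
  # finite horizon + EP > CP bias the estimate low, but within 5%
  expect_equal(res$w_prime, 15000, tolerance = 0.05)
  expect_lte(res$ep, max(st$trace$power))
})

test_that("3MT analysis is shift-invariant in time and equivariant in power", {
  st <- simulate_3mt(canonical_3mt_profile(noise_sd = 5, seed = 17))
  base <- analyze_3mt(st$trace)
  shifted <- power_trace(st$trace$time + 42, st$trace$power, fs = st$trace$fs)
  res_t <- analyze_3mt(shifted)
  expect_equal(res_t$ep, base$ep)
  expect_equal(res_t$w_prime, base$w_prime)
  offset <- power_trace(st$trace$time, st$trace$power + 25, fs = st$trace$fs)
  res_p <- analyze_3mt(offset)
  expect_equal(res_p$ep, base$ep + 25)
  expect_equal(res_p$w_prime, base$w_prime, tolerance = 1e-9)
})

test_that("CPT partition against the true CP recovers the simulator truth", {
  st <- simulate_cpt(canonical_profile(), 300)
  seg <- segment_cpt(st$trace, 300)
  res <- analyze_cpt(st$trace, seg, ep_reference_3mt = 250)
  expect_equal(res$constant_w_prime, st$truth$constant_w_prime_true,
               tolerance = 0.01)
  expect_equal(res$unaccounted_w_prime, st$truth$unaccounted_w_prime_true,
               tolerance = 0.02)
  expect_false(res$used_fallback)
  expect_equal(res$duration_bin, "3-6 min")
})

test_that("total W' equals its components to machine precision", {
  for (s in 1:5) {
    st <- simulate_cpt(canonical_profile(noise_sd = 5, seed = 200 + s), 300)
    seg <- segment_cpt(st$trace, 300)
    res <- analyze_cpt(st$trace, seg, ep_reference_3mt = 253)
    expect_identical(res$total_w_prime,
                     res$constant_w_prime + res$unaccounted_w_prime)
  }
})

test_that("a reference EP above the prescribed power triggers the fallback", {
  # athlete holds 265 W; a 280 W reference EP makes the constant W' negative
  pr <- athlete_profile(cp = 250, w_prime = 6000, p_max = 700, seed = 5)
  st <- simulate_cpt(pr, 265)
  seg <- segment_cpt(st$trace, 265)
  res <- analyze_cpt(st$trace, seg, ep_reference_3mt = 280)
  expect_true(res$used_fallback)
  expect_equal(res$ep_reference, res$ep_individual)
  expect_gte(res$constant_w_prime, 0)
  expect_identical(res$total_w_prime,
                   res$constant_w_prime + res$unaccounted_w_prime)
})

test_that("duration bins follow the half-open minute boundaries", {
  expect_equal(duration_bin(45), "<1 min")
  expect_equal(duration_bin(60), "1-3 min")
  expect_equal(duration_bin(192), "3-6 min")
  expect_equal(duration_bin(360), ">6 min")
  expect_equal(duration_bin(359.9), "3-6 min")
})

test_that("estimates converge to truth as the sampling rate grows", {
  res <- lapply(c(1, 8), function(fs) {
    st <- simulate_cpt(canonical_profile(), 300, fs = fs)
    seg <- segment_cpt(st$trace, 300)
    analyze_cpt(st$trace, seg, ep_reference_3mt = 250)
  })
  truth <- simulate_cpt(canonical_profile(), 300)$truth
  err <- vapply(res, function(r) abs(r$total_w_prime -
    (truth$constant_w_prime_true + truth$unaccounted_w_prime_true)), numeric(1))
  expect_lt(err[2], 0.01 * 12000)
  expect_lte(err[2], err[1] + 1)  # finer grid is at least as accurate
})
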