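test_that("noise-free failure detection recovers the true boundary exactly", {
  st <- simulate_cpt(canonical_profile(), 300)
  t_fail <- detect_failure(st$trace, 300)
  expect_lte(abs(t_fail - st$truth$t_fail), 1 / st$trace$fs)
})

test_that("a trace that never leaves the maintenance band has no failure", {
  tr <- power_trace(0:299, rep(300, 300))
  expect_error(detect_failure(tr, 300), "no failure found")
  expect_error(detect_failure(power_trace(0:4, rep(300, 5)), 300, lapse_s = 10),
               "shorter than lapse_s")
})

test_that("the lapse rule ignores sub-threshold dips (hand-built fixture)", {
  p <- rep(300, 200)
  p[101:105] <- 285   # 5 s dip: shorter than the 10 s lapse
  p[151:162] <- 285   # 12 s lapse: qualifies; run starts at t = 150
  tr <- power_trace(0:199, p)
  expect_equal(detect_failure(tr, 300, tolerance_w = 10, lapse_s = 10,
                              refine = FALSE), 150)
})

test_that("failure detection is invariant to a common power offset", {
  st <- simulate_cpt(canonical_profile(noise_sd = 5, seed = 13), 300)
  t1 <- detect_failure(st$trace, 300)
  shifted <- power_trace(st$trace$time, st$trace$power + 50, fs = st$trace$fs)
  t2 <- detect_failure(shifted, 350)
  expect_equal(t1, t2)
})

test_that("noisy failure detection stays within 3 s of truth in most runs", {
  errs <- vapply(1:25, function(s) {
    st <- simulate_cpt(canonical_profile(noise_sd = 5, seed = 100 + s), 300)
    detect_failure(st$trace, 300) - st$truth$t_fail
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 3), 0.9)
})

test_that("a trace constant from t_fail onward starts its plateau at t_fail", {
  p <- c(rep(300, 100), rep(250, 150))
  tr <- power_trace(0:249, p)
  pl <- detect_plateau(tr, t_fail = 100)
  expect_equal(pl$t_plateau_start, 100)
  expect_equal(pl$t_end, 249)
})

test_that("a pure linear decline admits no plateau", {
  tr <- power_trace(0:200, 300 - 0.5 * (0:200))
  expect_error(detect_plateau(tr, t_fail = 20), "no plateau")
})

test_that("segmentation of a noise-free CPT brackets the true phases", {
  st <- simulate_cpt(canonical_profile(), 300)
  seg <- segment_cpt(st$trace, 300)
  phase3_start <- st$truth$t_fail + st$truth$decline_s
  expect_lte(abs(seg$t_fail - st$truth$t_fail), 1)
  expect_gte(seg$t_plateau_start, seg$t_fail)
  expect_lte(seg$t_plateau_start, phase3_start)
  expect_equal(seg$t_end, max(st$trace$time))  # plateau extends to trace end
  # power at the detected plateau start is already near CP
  p_at <- st$trace$power[st$trace$time == seg$t_plateau_start]
  expect_lt(abs(p_at - 250), 10)
  # boundaries are sample-aligned and ordered
  expect_true(all(c(seg$t_fail, seg$t_plateau_start, seg$t_end) %in% st$trace$time))
  expect_true(seg$t_fail <= seg$t_plateau_start &&
                seg$t_plateau_start <= seg$t_end)
})

test_that("segmentation is reproducible on the segmented sub-trace", {
  st <- simulate_cpt(canonical_profile(noise_sd = 5, seed = 55), 300)
  seg <- segment_cpt(st$trace, 300)
  sub <- critpow:::.subset_trace(st$trace, 0, seg$t_end)
  seg2 <- segment_cpt(sub, 300)
  expect_equal(seg2$t_fail, seg$t_fail, tolerance = 2)
})

test_that("an instant drop to the plateau leaves no decline gap", {
  st <- simulate_cpt(canonical_profile(f_unspent = 0), 300)
  seg <- segment_cpt(st$trace, 300)
  expect_lte(seg$t_plateau_start - seg$t_fail, 2 / st$trace$fs)
})
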