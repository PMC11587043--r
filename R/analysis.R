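# Per-test measurements: end power (EP), the power-time integral above a
# reference power, and the constant-power / unaccounted / total W'
# partition of a CPT.

.bin_labels <- c("<1 min", "1-3 min", "3-6 min", ">6 min")

#' Assign a CPT to a duration bin
#'
#' Bins a test by the duration of its constant-power phase, with half-open
#' boundaries at `bin_edges_s` (defaults 60, 180, 360 s): `[0, 60)` is
#' `"<1 min"`, `[60, 180)` is `"1-3 min"`, `[180, 360)` is `"3-6 min"` and
#' `[360, Inf)` is `">6 min"`.
#'
#' @param constant_duration_s Constant-phase duration (s).
#' @param bin_edges_s Three increasing bin edges (s).
#' @return One of `"<1 min"`, `"1-3 min"`, `"3-6 min"`, `">6 min"`.
#' @export
duration_bin <- function(constant_duration_s, bin_edges_s = c(60, 180, 360)) {
  if (!is_scalar_number(constant_duration_s) || constant_duration_s < 0) {
    stop_critpow("constant_duration_s must be >= 0")
  }
  stopifnot(length(bin_edges_s) == 3L, !is.unsorted(bin_edges_s))
  .bin_labels[findInterval(constant_duration_s, bin_edges_s) + 1L]
}

#' Integrate power above a reference level
#'
#' Trapezoidal integral of `(power - reference)` over `[t0, t1]` on the
#' sample grid, in joules.  With `clip_negative = TRUE`, each per-interval
#' trapezoid contribution below zero is set to zero before summation, so
#' excursions below the reference cannot reduce the total.
#'
#' @param trace A [power_trace()].
#' @param reference Reference power (W).
#' @param t0,t1 Window bounds (s); must coincide with sample times and
#'   satisfy `t0 < t1`.
#' @param clip_negative Clip negative per-interval contributions.  Default
#'   `FALSE` (signed integral).
#' @return Work above the reference in joules.
#' @examples
#' tr <- power_trace(0:100, seq(400, 300, length.out = 101))
#' integrate_above(tr, 300, 0, 100)  # triangle: 5000 J
#' @export
integrate_above <- function(trace, reference, t0, t1, clip_negative = FALSE) {
  stopifnot(inherits(trace, "power_trace"))
  if (!is_scalar_number(reference)) stop_critpow("reference must be a number")
  i0 <- .time_index(trace, t0, "t0")
  i1 <- .time_index(trace, t1, "t1")
  if (i0 >= i1) stop_critpow("t0 must precede t1 within the trace")
  idx <- i0:i1
  y <- trace$power[idx] - reference
  dt <- diff(trace$time[idx])
  contrib <- dt * (y[-length(y)] + y[-1L]) / 2
  if (clip_negative) contrib <- pmax(0, contrib)
  sum(contrib)
}

#' Analyse a 3-minute all-out test
#'
#' The end power (EP) is the arithmetic mean of the samples in the final
#' `ep_window_s` seconds of the test; W' is the power-time integral above
#' the EP over the whole test.
#'
#' @param trace A [power_trace()] of a 3MT.
#' @param ep_window_s End-power window (s).  Default 30.
#' @param clip_negative Passed to [integrate_above()].  Default `FALSE`.
#' @return An object of class `threemt_result`: list with `ep` (W),
#'   `w_prime` (J), `ep_window_s` and `test_duration_s`.
#' @examples
#' st <- simulate_3mt(athlete_profile(250, 15000, 700, seed = 1))
#' analyze_3mt(st$trace)
#' @export
analyze_3mt <- function(trace, ep_window_s = 30, clip_negative = FALSE) {
  stopifnot(inherits(trace, "power_trace"))
  n <- length(trace$time)
  t_end <- trace$time[n]
  dur <- t_end - trace$time[1L]
  if (dur < ep_window_s) stop_critpow("trace shorter than ep_window_s")
  in_win <- trace$time >= t_end - ep_window_s - 1e-9
  ep <- mean(trace$power[in_win])
  wp <- integrate_above(trace, ep, trace$time[1L], t_end,
                        clip_negative = clip_negative)
  structure(list(ep = ep, w_prime = wp, ep_window_s = ep_window_s,
                 test_duration_s = dur),
            class = "threemt_result")
}

#' @export
print.threemt_result <- function(x, ...) {
  cat(sprintf("<threemt_result> EP %.1f W, W' %.0f J (%.0f s test)\n",
              x$ep, x$w_prime, x$test_duration_s))
  invisible(x)
}

#' Analyse a constant-power plus all-out test
#'
#' Partitions the work above a reference end power into its constant-power
#' and unaccounted components.  The constant-power W' is the integral of
#' `(power - EP)` over the constant phase `[0, t_fail]`; the unaccounted W'
#' is the same integral over the all-out decline `[t_fail, t_end]`; the
#' total W' is their sum, exactly.
#'
#' By default (`ep_reference = "3mt"`) the reference EP is the athlete's
#' 3MT end power, as in the protocol; should the constant-power W' come out
#' negative (possible for long tests whose mean power drifts below the 3MT
#' EP), both components are recomputed against the test's own end power
#' (`ep_individual`, the mean power over the final 30 s of the plateau) and
#' `used_fallback` is set.  `ep_reference = "individual"` uses the test's
#' own end power throughout; because the plateau directly estimates the
#' athlete's sustainable power, this variant is free of any bias carried by
#' a finite-duration 3MT EP.
#'
#' @param trace A [power_trace()] of a CPT.
#' @param seg A [segment_cpt()] result for this trace.
#' @param ep_reference_3mt The athlete's 3MT end power (W), > 0.
#' @param ep_reference `"3mt"` (protocol, with negative-W' fallback) or
#'   `"individual"`.
#' @param ep_window_s Window for the individual end power (s).  Default 30.
#' @param clip_negative Passed to [integrate_above()].  Default `FALSE`.
#' @param bin_edges_s Passed to [duration_bin()].
#' @return An object of class `cpt_result`: list with `ep_individual`,
#'   `ep_reference` (the EP actually used, W), `constant_w_prime`,
#'   `unaccounted_w_prime`, `total_w_prime` (J), `used_fallback`,
#'   `duration_bin` and `constant_duration_s`.
#' @examples
#' pr <- athlete_profile(250, 12000, 700, seed = 4)
#' st <- simulate_cpt(pr, 300)
#' seg <- segment_cpt(st$trace, 300)
#' analyze_cpt(st$trace, seg, ep_reference_3mt = 253)
#' @export
analyze_cpt <- function(trace, seg, ep_reference_3mt,
                        ep_reference = c("3mt", "individual"),
                        ep_window_s = 30, clip_negative = FALSE,
                        bin_edges_s = c(60, 180, 360)) {
  stopifnot(inherits(trace, "power_trace"), inherits(seg, "cpt_segmentation"))
  ep_reference <- match.arg(ep_reference)
  if (!is_scalar_number(ep_reference_3mt) || ep_reference_3mt <= 0) {
    stop_critpow("ep_reference_3mt must be > 0")
  }
  t0 <- trace$time[1L]
  if (seg$t_end - seg$t_plateau_start < ep_window_s) {
    stop_critpow("plateau shorter than ", ep_window_s, " s")
  }
  in_win <- trace$time >= seg$t_end - ep_window_s - 1e-9 &
    trace$time <= seg$t_end + 1e-9
  ep_individual <- mean(trace$power[in_win])
  partition <- function(ref) {
    cwp <- integrate_above(trace, ref, t0, seg$t_fail,
                           clip_negative = clip_negative)
    uwp <- integrate_above(trace, ref, seg$t_fail, seg$t_end,
                           clip_negative = clip_negative)
    list(constant = cwp, unaccounted = uwp)
  }
  used_fallback <- FALSE
  if (ep_reference == "individual") {
    ref_used <- ep_individual
    parts <- partition(ref_used)
  } else {
    ref_used <- ep_reference_3mt
    parts <- partition(ref_used)
    if (parts$constant < 0) {
      ref_used <- ep_individual
      parts <- partition(ref_used)
      used_fallback <- TRUE
    }
  }
  const_dur <- seg$t_fail - t0
  structure(list(ep_individual = ep_individual,
                 ep_reference = ref_used,
                 constant_w_prime = parts$constant,
                 unaccounted_w_prime = parts$unaccounted,
                 total_w_prime = parts$constant + parts$unaccounted,
                 used_fallback = used_fallback,
                 duration_bin = duration_bin(const_dur, bin_edges_s),
                 constant_duration_s = const_dur),
            class = "cpt_result")
}

#' @export
print.cpt_result <- function(x, ...) {
  cat(sprintf("<cpt_result> bin %s (%.0f s constant)%s\n", x$duration_bin,
              x$constant_duration_s,
              if (x$used_fallback) " [fallback EP]" else ""))
  cat(sprintf("  EP used %.1f W; W': constant %.0f + unaccounted %.0f = %.0f J\n",
              x$ep_reference, x$constant_w_prime, x$unaccounted_w_prime,
              x$total_w_prime))
  invisible(x)
}
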