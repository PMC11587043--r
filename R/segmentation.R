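# Segmentation of constant-power plus all-out (CPT) traces: locate the
# point where the prescribed power could no longer be held (task failure)
# and the terminal plateau where power has levelled off at its asymptote.

# Rolling least-squares slope over windows of n_w consecutive samples
# (uniform grid).  Returns one slope per window start, O(n) via cumsums.
.rolling_slope <- function(power, dt, n_w) {
  n <- length(power)
  if (n < n_w) return(numeric(0))
  j <- seq_len(n)
  cs_p <- cumsum(power)
  cs_pj <- cumsum(power * j)
  win_sum <- function(cs, i) cs[i + n_w - 1L] - c(0, cs)[i]
  starts <- seq_len(n - n_w + 1L)
  Sp <- win_sum(cs_p, starts)
  Spj <- win_sum(cs_pj, starts)
  jbar <- starts + (n_w - 1) / 2
  sxx <- n_w * (n_w^2 - 1) / 12  # sum (j - jbar)^2 on the index grid
  ((Spj - jbar * Sp) / sxx) / dt
}

# Robust per-sample noise SD from first differences (median absolute
# difference); exactly 0 on noise-free traces with piecewise-smooth means.
.noise_sd_hat <- function(power) {
  d <- diff(power)
  stats::median(abs(d)) / (0.6744898 * sqrt(2))
}

#' Detect the constant-power failure point of a CPT
#'
#' The protocol declares task failure once the prescribed power can no
#' longer be maintained for more than `lapse_s` seconds.  This detector
#' first applies that rule literally: it finds the first contiguous run of
#' at least `lapse_s` seconds with power below
#' `prescribed_power - tolerance_w` (the maintenance band is one-sided:
#' over-performance never signals failure).  With `refine = FALSE` the start
#' of that run is returned.
#'
#' Because a gradual all-out decline crosses the band only some time after
#' the effort actually gave way, the default `refine = TRUE` additionally
#' estimates the onset of the decline by least squares: a changepoint `c` is
#' chosen (on the sample grid, searching backwards from the lapse) to
#' minimise the residual sum of squares of a
#' constant-then-exponential-decline mean model (power = prescribed before
#' `c`; `a + (prescribed - a) exp(-(t - c)/tau)` after, with the asymptote
#' `a` taken from the trace tail and `tau` profiled out numerically).
#'
#' @param trace A [power_trace()] of a CPT.
#' @param prescribed_power Prescribed power (W), > 0.
#' @param tolerance_w One-sided maintenance band (W).  Default 10.
#' @param lapse_s Minimum lapse duration declaring failure (s).  Default 10.
#' @param refine Refine the lapse time to the decline onset (default TRUE).
#' @return `t_fail` in seconds (a sample time).
#' @export
detect_failure <- function(trace, prescribed_power, tolerance_w = 10,
                           lapse_s = 10, refine = TRUE) {
  stopifnot(inherits(trace, "power_trace"))
  if (!is_scalar_number(prescribed_power) || prescribed_power <= 0) {
    stop_critpow("prescribed_power must be > 0")
  }
  n <- length(trace$time)
  dt <- 1 / trace$fs
  n_lapse <- max(1L, ceiling(lapse_s * trace$fs))
  if (n < n_lapse) stop_critpow("trace shorter than lapse_s")
  below <- trace$power < prescribed_power - tolerance_w
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= n_lapse)
  if (length(hit) == 0L) {
    stop_critpow("no failure found: power never leaves the maintenance band for ",
                 lapse_s, " s")
  }
  i_lapse <- starts[hit[1L]]
  if (!refine) return(trace$time[i_lapse])
  .refine_failure(trace, prescribed_power, i_lapse)
}

# Changepoint refinement: search c on the sample grid in a window before the
# lapse start.  For each candidate the decline model
#   mu(t) = a + (prescribed - a) exp(-(t - c)/tau),  t >= c
# is fitted to the remainder of the trace with the asymptote a profiled out
# in closed form (the model is linear in a at fixed tau) and tau profiled
# numerically; the candidate minimising the total residual sum of squares
# (constant segment + decline segment) wins.
.refine_failure <- function(trace, prescribed_power, i_lapse,
                            back_s = 150, ahead_min = 30) {
  t <- trace$time
  p <- trace$power
  n <- length(t)
  fs <- trace$fs
  i_lo <- max(2L, i_lapse - as.integer(round(back_s * fs)))
  i_hi <- min(n - as.integer(round(ahead_min * fs)), i_lapse)
  if (i_hi < i_lo) i_hi <- i_lo
  sse_at <- function(i) {
    c_t <- t[i]
    res1 <- p[seq_len(i - 1L)] - prescribed_power
    t2 <- t[i:n] - c_t
    p2 <- p[i:n]
    seg2 <- function(tau) {
      g <- exp(-t2 / tau)
      x <- 1 - g                       # mu = a x + prescribed g
      y <- p2 - prescribed_power * g
      sxx <- sum(x * x)
      a_hat <- if (sxx > 0) sum(x * y) / sxx else 0
      sum((y - a_hat * x)^2)
    }
    opt <- stats::optimize(seg2, interval = c(0.05, 1000))
    sum(res1^2) + opt$objective
  }
  # coarse pass, then full-resolution neighbourhood
  stride <- max(1L, as.integer(round(fs * 4)))
  coarse <- unique(c(seq(i_lo, i_hi, by = stride), i_hi))
  sse_c <- vapply(coarse, sse_at, numeric(1))
  i_best <- coarse[which.min(sse_c)]
  fine <- seq(max(i_lo, i_best - stride), min(i_hi, i_best + stride))
  sse_f <- vapply(fine, sse_at, numeric(1))
  t[fine[which.min(sse_f)]]
}

#' Detect the terminal power plateau of a CPT
#'
#' The test is terminated once power has fallen to an asymptote and stayed
#' there for `hold_s` seconds — so the final `hold_s` seconds of the trace
#' are plateau by protocol, and their mean anchors the asymptote level.  A
#' candidate plateau start `s` (>= `t_fail`) qualifies when
#' \itemize{
#'   \item the least-squares slope of power over every sliding window of
#'     `window_s` seconds inside `[s, s + hold_s]`, and over the full hold
#'     window, is bounded: `|slope| <= slope_w_per_s + z * SE(slope)`, where
#'     `SE(slope)` is the sampling error of the window slope under the
#'     trace's estimated noise SD and `z = 2.58`; and
#'   \item the mean power over `[s, s + hold_s]` lies within
#'     `slope_w_per_s * window_s + z * SE` of the terminal plateau level
#'     (slow declines satisfy local slope bounds long before they reach the
#'     asymptote; the level anchor rejects such starts).
#' }
#' The noise allowances vanish on noise-free traces.  The earliest
#' qualifying start wins.  `t_end` is the trace end when the final hold
#' window qualifies as flat (the plateau extends), otherwise
#' `t_plateau_start + hold_s`.
#'
#' @param trace A [power_trace()].
#' @param t_fail Failure time from [detect_failure()] (s, a sample time).
#' @param window_s Slope window length (s).  Default 30.
#' @param slope_w_per_s Maximum absolute slope (W/s).  Default 0.1.
#' @param hold_s Required plateau duration (s).  Default 60.
#' @return List with `t_plateau_start` and `t_end` (s, sample times).
#' @export
detect_plateau <- function(trace, t_fail, window_s = 30, slope_w_per_s = 0.1,
                           hold_s = 60) {
  stopifnot(inherits(trace, "power_trace"))
  t <- trace$time
  p <- trace$power
  n <- length(t)
  fs <- trace$fs
  dt <- 1 / fs
  i_fail <- .time_index(trace, t_fail, "t_fail")
  n_w <- as.integer(round(window_s * fs)) + 1L
  n_hold <- as.integer(round(hold_s * fs)) + 1L
  if (n_w < 3L) stop_critpow("window_s too short for the sampling rate")
  if (n - i_fail + 1L < n_hold) stop_critpow("fewer than hold_s seconds of data after t_fail")
  post <- p[i_fail:n]
  sd_hat <- .noise_sd_hat(post)
  z <- 2.58
  se_w <- sd_hat / sqrt(n_w * (n_w^2 - 1) / 12) / dt
  se_h <- sd_hat / sqrt(n_hold * (n_hold^2 - 1) / 12) / dt
  slopes_w <- .rolling_slope(p, dt, n_w)      # window start indices 1..n-n_w+1
  slopes_h <- .rolling_slope(p, dt, n_hold)
  ok_w <- abs(slopes_w) <= slope_w_per_s + z * se_w
  ok_h <- abs(slopes_h) <= slope_w_per_s + z * se_h
  # level anchor: mean over the hold window must match the terminal level
  level_tail <- mean(p[(n - n_hold + 1L):n])
  cs <- c(0, cumsum(p))
  mean_hold <- (cs[seq_len(n - n_hold + 1L) + n_hold] -
                  cs[seq_len(n - n_hold + 1L)]) / n_hold
  level_tol <- slope_w_per_s * window_s +
    z * sd_hat * sqrt(2 / n_hold)
  ok_l <- abs(mean_hold - level_tail) <= level_tol
  last_start <- n - n_hold + 1L
  s_found <- NA_integer_
  for (s in i_fail:last_start) {
    w_range <- s:(s + n_hold - n_w)
    if (ok_h[s] && ok_l[s] && all(ok_w[w_range])) { s_found <- s; break }
  }
  if (is.na(s_found)) {
    stop_critpow("no plateau satisfying the slope rule before trace end")
  }
  i_end <- if (ok_h[last_start]) n else s_found + n_hold - 1L
  list(t_plateau_start = t[s_found], t_end = t[i_end])
}

#' Segment a CPT trace
#'
#' Composes [detect_failure()] and [detect_plateau()] and records every
#' parameter used.
#'
#' @inheritParams detect_failure
#' @inheritParams detect_plateau
#' @return An object of class `cpt_segmentation`: list with `t_fail`,
#'   `t_plateau_start`, `t_end`, `tolerance_w`, `lapse_s` and `plateau_rule`
#'   (list with `window_s`, `slope_w_per_s`, `hold_s`).
#' @examples
#' pr <- athlete_profile(250, 12000, 700, seed = 3)
#' st <- simulate_cpt(pr, 300)
#' segment_cpt(st$trace, 300)
#' @export
segment_cpt <- function(trace, prescribed_power, tolerance_w = 10,
                        lapse_s = 10, window_s = 30, slope_w_per_s = 0.1,
                        hold_s = 60, refine = TRUE) {
  t_fail <- detect_failure(trace, prescribed_power, tolerance_w = tolerance_w,
                           lapse_s = lapse_s, refine = refine)
  pl <- detect_plateau(trace, t_fail, window_s = window_s,
                       slope_w_per_s = slope_w_per_s, hold_s = hold_s)
  structure(list(t_fail = t_fail,
                 t_plateau_start = pl$t_plateau_start,
                 t_end = pl$t_end,
                 tolerance_w = tolerance_w, lapse_s = lapse_s,
                 plateau_rule = list(window_s = window_s,
                                     slope_w_per_s = slope_w_per_s,
                                     hold_s = hold_s)),
            class = "cpt_segmentation")
}

#' @export
print.cpt_segmentation <- function(x, ...) {
  cat(sprintf("<cpt_segmentation> t_fail %.1f s, plateau %.1f-%.1f s\n",
              x$t_fail, x$t_plateau_start, x$t_end))
  invisible(x)
}
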