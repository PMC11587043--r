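#' Define a synthetic athlete
#'
#' An `athlete_profile` carries the ground-truth parameters from which
#' synthetic test traces are generated: true critical power `cp` (W), true
#' anaerobic work capacity `w_prime` (J), instantaneous peak power `p_max`
#' (W, must exceed `cp`), the fraction `f_unspent` of W' still unspent when
#' the constant-power task fails, additive Gaussian power noise `noise_sd`
#' (W), a nominal cadence (rpm) and an RNG seed.
#'
#' @param cp True critical power (W), > 0.
#' @param w_prime True W' (J), > 0.
#' @param p_max Instantaneous peak power (W), > `cp`.
#' @param f_unspent Fraction of W' unspent at constant-power task failure,
#'   in `[0, 1)`.  Default 0.2: roughly the share of anaerobic capacity that
#'   a constant-power test leaves untapped at the point the target power can
#'   no longer be held.
#' @param noise_sd SD of additive Gaussian power noise (W), >= 0.
#' @param cadence Nominal cadence (rpm).
#' @param seed RNG seed (integer) or `NULL` to use the current RNG stream.
#' @return An object of class `athlete_profile`.
#' @examples
#' athlete_profile(cp = 250, w_prime = 15000, p_max = 700)
#' @export
athlete_profile <- function(cp, w_prime, p_max, f_unspent = 0.2,
                            noise_sd = 0, cadence = 90, seed = NULL) {
  if (!is_scalar_number(cp) || cp <= 0) stop_critpow("cp must be > 0")
  if (!is_scalar_number(w_prime) || w_prime <= 0) stop_critpow("w_prime must be > 0")
  if (!is_scalar_number(p_max) || p_max <= cp) stop_critpow("p_max must exceed cp")
  if (!is_scalar_number(f_unspent) || f_unspent < 0 || f_unspent >= 1) {
    stop_critpow("f_unspent must lie in [0, 1)")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) stop_critpow("noise_sd must be >= 0")
  if (!is_scalar_number(cadence) || cadence <= 0) stop_critpow("cadence must be > 0")
  structure(list(cp = cp, w_prime = w_prime, p_max = p_max,
                 f_unspent = f_unspent, noise_sd = noise_sd,
                 cadence = cadence, seed = seed),
            class = "athlete_profile")
}

#' @export
print.athlete_profile <- function(x, ...) {
  cat(sprintf("<athlete_profile> CP %.0f W, W' %.0f J, Pmax %.0f W, f_unspent %.2f, noise %.1f W\n",
              x$cp, x$w_prime, x$p_max, x$f_unspent, x$noise_sd))
  invisible(x)
}

# sample grid 0, 1/fs, ..., covering [0, duration]
.time_grid <- function(duration, fs) seq(0L, ceiling(duration * fs)) / fs

.apply_noise <- function(mean_power, profile) {
  if (profile$noise_sd > 0) {
    pmax(0, mean_power + stats::rnorm(length(mean_power), 0, profile$noise_sd))
  } else {
    mean_power
  }
}

.sim_cadence <- function(n, profile) {
  jitter <- if (profile$noise_sd > 0) stats::rnorm(n, 0, 1) else rep(0, n)
  profile$cadence + jitter
}

#' Simulate a 3-minute all-out test
#'
#' Generates a 3MT trace whose noise-free mean curve is
#' `P(t) = cp + (p_max - cp) * exp(-t / tau)` with
#' `tau = w_prime / (p_max - cp)`, so that the integral of the curve above
#' CP over an infinite horizon equals W' exactly.  Gaussian noise of SD
#' `noise_sd` is added per sample and clipped at 0 W.  Deterministic given
#' the profile seed.
#'
#' @param profile An [athlete_profile()].
#' @param duration_s Test duration (s), >= 60.  Default 180.
#' @param fs Sampling rate (Hz).  Default 1.
#' @return An object of class `simulated_test`: list with `trace`
#'   ([power_trace()]), `meta` ([test_meta()]) and `truth` (list with `cp`,
#'   `w_prime`, `tau`).
#' @examples
#' st <- simulate_3mt(athlete_profile(250, 15000, 700, seed = 1))
#' st$trace
#' @export
simulate_3mt <- function(profile, duration_s = 180, fs = 1) {
  stopifnot(inherits(profile, "athlete_profile"))
  if (!is_scalar_number(duration_s) || duration_s < 60) {
    stop_critpow("duration_s must be >= 60")
  }
  tau <- profile$w_prime / (profile$p_max - profile$cp)
  t <- .time_grid(duration_s, fs)
  mean_power <- profile$cp + (profile$p_max - profile$cp) * exp(-t / tau)
  with_seed(profile$seed, {
    power <- .apply_noise(mean_power, profile)
    cad <- .sim_cadence(length(t), profile)
  })
  trace <- power_trace(t, power, cadence = cad, fs = fs)
  meta <- test_meta("sim", "3MT", preferred_cadence = profile$cadence)
  structure(list(trace = trace, meta = meta,
                 truth = list(cp = profile$cp, w_prime = profile$w_prime,
                              tau = tau)),
            class = "simulated_test")
}

#' Simulate a constant-power plus all-out test
#'
#' Generates a CPT trace in three phases.  Phase 1 (constant): mean power
#' equals `prescribed_power` until task failure at
#' `t_fail = (1 - f_unspent) * w_prime / (prescribed_power - cp)` seconds,
#' when only the unspent fraction of W' remains.  Phase 2 (all-out decline):
#' mean power `cp + (prescribed_power - cp) * exp(-(t - t_fail)/tau2)` with
#' `tau2 = f_unspent * w_prime / (prescribed_power - cp)` (so the remaining
#' W' equals the integral of the decline above CP), truncated once the mean
#' is within 1 W of CP.  Phase 3 (plateau): mean power CP for
#' `plateau_hold_s` seconds.  Gaussian noise throughout, clipped at 0 W.
#'
#' The `truth` record reports `t_fail`, `constant_w_prime_true =
#' (1 - f_unspent) * w_prime`, and `unaccounted_w_prime_true` as the decline
#' integral actually laid down in the mean trace, i.e. `f_unspent * w_prime -
#' tau2` (the analytically known tail below the 1 W cut is excluded).
#'
#' @param profile An [athlete_profile()].
#' @param prescribed_power Prescribed power (W); must exceed `cp`, otherwise
#'   the model predicts no exhaustion.
#' @param fs Sampling rate (Hz).  Default 1.
#' @param plateau_hold_s Plateau duration appended after the decline (s).
#'   Default 120.
#' @return A `simulated_test`; `truth` additionally carries `t_fail`,
#'   `decline_s`, `constant_w_prime_true`, `unaccounted_w_prime_true` and
#'   `tau2`.
#' @examples
#' pr <- athlete_profile(250, 12000, 700, f_unspent = 0.2, seed = 2)
#' st <- simulate_cpt(pr, prescribed_power = 300)
#' st$truth$t_fail  # 0.8 * 12000 / 50 = 192 s
#' @export
simulate_cpt <- function(profile, prescribed_power, fs = 1,
                         plateau_hold_s = 120) {
  stopifnot(inherits(profile, "athlete_profile"))
  if (!is_scalar_number(prescribed_power)) {
    stop_critpow("prescribed_power must be a number")
  }
  dp <- prescribed_power - profile$cp
  if (dp <= 0) {
    stop_critpow("prescribed_power must exceed cp (time to exhaustion is infinite below CP)")
  }
  f <- profile$f_unspent
  t_fail <- (1 - f) * profile$w_prime / dp
  tau2 <- f * profile$w_prime / dp
  # decline runs until the mean curve is within 1 W of CP
  decline_s <- if (f > 0 && dp > 1) tau2 * log(dp) else 0
  # tail of the decline below the 1 W cut integrates to tau2 * 1 W exactly;
  # if dp <= 1 the whole decline falls inside the cut and nothing is laid down
  unacc_true <- if (f > 0 && dp > 1) f * profile$w_prime - tau2 else 0
  total_s <- t_fail + decline_s + plateau_hold_s
  t <- .time_grid(total_s, fs)
  mean_power <- ifelse(
    t < t_fail, prescribed_power,
    ifelse(t < t_fail + decline_s,
           profile$cp + dp * exp(-(t - t_fail) / tau2),
           profile$cp))
  with_seed(profile$seed, {
    power <- .apply_noise(mean_power, profile)
    cad <- .sim_cadence(length(t), profile)
  })
  trace <- power_trace(t, power, cadence = cad, fs = fs)
  meta <- test_meta("sim", "CPT", prescribed_power = prescribed_power,
                    preferred_cadence = profile$cadence)
  structure(list(trace = trace, meta = meta,
                 truth = list(cp = profile$cp, w_prime = profile$w_prime,
                              t_fail = t_fail, decline_s = decline_s,
                              tau2 = tau2,
                              constant_w_prime_true = (1 - f) * profile$w_prime,
                              unaccounted_w_prime_true = unacc_true)),
            class = "simulated_test")
}

#' @export
print.simulated_test <- function(x, ...) {
  cat(sprintf("<simulated_test> %s, true CP %.0f W, true W' %.0f J\n",
              x$meta$test_kind, x$truth$cp, x$truth$w_prime))
  print(x$trace)
  invisible(x)
}

#' Simulate a cohort of athletes
#'
#' Draws `n_athletes` profiles and generates, for each, one 3MT plus four
#' CPTs at prescribed powers `cp + w_prime / t_target` for target times to
#' exhaustion `t_targets` (defaults 45, 120, 270 and 480 s, one per duration
#' bin of the protocol: <1, 1-3, 3-6 and >6 min).  CP is drawn uniformly
#' over `cp_range`, W' over `w_prime_range`; peak power is set as
#' `cp + w_prime / tau` with the sprint decay constant `tau` drawn uniformly
#' over `tau_range`, so that essentially all of W' is spent within the first
#' two minutes of an all-out effort.
#'
#' @param n_athletes Number of athletes, >= 1.
#' @param cp_range Range (W) for true CP.  Default `c(230, 330)`.
#' @param w_prime_range Range (J) for true W'.  Default `c(8000, 20000)`.
#' @param tau_range Range (s) for the all-out decay constant.  Default
#'   `c(20, 30)`.
#' @param f_unspent Unspent W' fraction at task failure.  Default 0.2.
#' @param noise_sd Power noise SD (W).  Default 5.
#' @param t_targets Target times to exhaustion (s) for the four CPTs.
#' @param fs Sampling rate (Hz).  Default 1.
#' @param seed Cohort seed; per-test seeds are derived deterministically.
#' @return A list of class `simulated_cohort`; each element is a list with
#'   `athlete_id`, `profile`, `three_mt` and `cpts` (list of
#'   `simulated_test`s with attribute `t_target`).
#' @examples
#' coh <- simulate_cohort(2, seed = 1)
#' length(coh)
#' @export
simulate_cohort <- function(n_athletes,
                            cp_range = c(230, 330),
                            w_prime_range = c(8000, 20000),
                            tau_range = c(20, 30),
                            f_unspent = 0.2,
                            noise_sd = 5,
                            t_targets = c(45, 120, 270, 480),
                            fs = 1,
                            seed = NULL) {
  if (!is_scalar_number(n_athletes) || n_athletes < 1) {
    stop_critpow("n_athletes must be >= 1")
  }
  ok_range <- function(r) is.numeric(r) && length(r) == 2L &&
    all(is.finite(r)) && r[1L] > 0 && r[2L] >= r[1L]
  if (!ok_range(cp_range) || !ok_range(w_prime_range) || !ok_range(tau_range)) {
    stop_critpow("parameter ranges must be positive, ordered pairs")
  }
  n_athletes <- as.integer(n_athletes)
  draws <- with_seed(seed, {
    list(cp = stats::runif(n_athletes, cp_range[1L], cp_range[2L]),
         wp = stats::runif(n_athletes, w_prime_range[1L], w_prime_range[2L]),
         tau = stats::runif(n_athletes, tau_range[1L], tau_range[2L]),
         cad = round(stats::runif(n_athletes, 85, 105)))
  })
  cohort <- vector("list", n_athletes)
  for (i in seq_len(n_athletes)) {
    prof <- athlete_profile(
      cp = draws$cp[i], w_prime = draws$wp[i],
      p_max = draws$cp[i] + draws$wp[i] / draws$tau[i],
      f_unspent = f_unspent, noise_sd = noise_sd, cadence = draws$cad[i],
      seed = child_seed(seed, i * 10L))
    id <- sprintf("A%03d", i)
    tm <- simulate_3mt(prof, fs = fs)
    tm$meta$athlete_id <- id
    cpts <- vector("list", length(t_targets))
    for (k in seq_along(t_targets)) {
      pk <- prof
      pk$seed <- child_seed(seed, i * 10L + k)
      pw <- prof$cp + prof$w_prime / t_targets[k]
      stk <- simulate_cpt(pk, prescribed_power = pw, fs = fs)
      stk$meta$athlete_id <- id
      attr(stk, "t_target") <- t_targets[k]
      cpts[[k]] <- stk
    }
    cohort[[i]] <- list(athlete_id = id, profile = prof,
                        three_mt = tm, cpts = cpts)
  }
  structure(cohort, class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %d athletes, %d tests each\n",
              length(x), 1L + length(x[[1L]]$cpts)))
  invisible(x)
}

#' Write a simulated cohort to a directory of trace CSVs
#'
#' One CSV per test, named `<athlete>_3mt.csv` / `<athlete>_cpt<k>.csv`,
#' readable by [read_trace()] and [run_pipeline()].
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ath in cohort) {
    write_trace(ath$three_mt$trace, ath$three_mt$meta,
                file.path(dir, paste0(ath$athlete_id, "_3mt.csv")))
    for (k in seq_along(ath$cpts)) {
      write_trace(ath$cpts[[k]]$trace, ath$cpts[[k]]$meta,
                  file.path(dir, sprintf("%s_cpt%d.csv", ath$athlete_id, k)))
    }
  }
  invisible(dir)
}
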