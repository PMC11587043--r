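# Canonical simulation profiles used across test files.

canonical_profile <- function(noise_sd = 0, seed = NULL, f_unspent = 0.2) {
  athlete_profile(cp = 250, w_prime = 12000, p_max = 700,
                  f_unspent = f_unspent, noise_sd = noise_sd, seed = seed)
}

canonical_3mt_profile <- function(noise_sd = 0, seed = NULL) {
  athlete_profile(cp = 250, w_prime = 15000, p_max = 700,
                  noise_sd = noise_sd, seed = seed)
}

# Minimal athlete_result-shaped list for group-stats tests.
mock_athlete_result <- function(id, cp_trad, wp_trad, ep_3mt, wp_3mt, cpt_rows) {
  list(athlete_id = id,
       traditional_fit = list(cp = cp_trad, w_prime = wp_trad),
       three_mt = list(ep = ep_3mt, w_prime = wp_3mt),
       cpt_results = cpt_rows)
}

mock_cpt_row <- function(bin, ep_ind, cwp, uwp) {
  list(ep_individual = ep_ind, constant_w_prime = cwp,
       unaccounted_w_prime = uwp, total_w_prime = cwp + uwp,
       duration_bin = bin)
}

# Complete balanced long table of iid normal values (null simulation).
null_long_table <- function(n_athletes, variable = "total_w_prime",
                            mean = 15000, sd = 3000, subject_sd = 0) {
  conds <- c("Traditional", "3MT", "CPT<1", "CPT1-3", "CPT3-6", "CPT>6")
  tab <- expand.grid(athlete_id = sprintf("A%03d", seq_len(n_athletes)),
                     condition = conds, stringsAsFactors = FALSE)
  tab$variable <- variable
  tab$value <- stats::rnorm(nrow(tab), mean, sd) +
    rep(stats::rnorm(n_athletes, 0, subject_sd), times = length(conds))
  tab
}
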