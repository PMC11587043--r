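# End-to-end cohort pipeline: per-athlete analysis of one 3MT plus a set
# of CPTs, a Table-1-style cohort summary, and the group comparisons.

#' Pipeline configuration
#'
#' Collects every protocol constant and analysis threshold in one
#' validated, serialisable object: sampling rate, the 30 s end-power
#' window, the failure rule (10 W one-sided band, 10 s lapse), the plateau
#' rule (30 s slope windows, 0.1 W/s, 60 s hold), integral clipping, the
#' duration-bin edges, the reference-EP policy, the post hoc procedure and
#' alpha, and the seed.
#'
#' @param fs_hz Sampling rate (Hz).
#' @param ep_window_s End-power window (s).
#' @param tolerance_w Failure maintenance band (W).
#' @param lapse_s Failure lapse (s).
#' @param window_s Plateau slope window (s).
#' @param slope_w_per_s Plateau slope bound (W/s).
#' @param hold_s Plateau hold (s).
#' @param refine_failure Refine t_fail to the decline onset (see
#'   [detect_failure()]).
#' @param clip_negative Clip negative integral contributions.
#' @param bin_edges_s Duration-bin edges (s).
#' @param ep_reference `"3mt"` or `"individual"` (see [analyze_cpt()]).
#' @param procedure `"dunnett"` or `"bonferroni"`.
#' @param alpha Significance level, in (0, 1).
#' @param seed Optional integer seed recorded with the run.
#' @return An object of class `cp_config` (a validated named list).
#' @export
pipeline_config <- function(fs_hz = 1, ep_window_s = 30, tolerance_w = 10,
                            lapse_s = 10, window_s = 30, slope_w_per_s = 0.1,
                            hold_s = 60, refine_failure = TRUE,
                            clip_negative = FALSE,
                            bin_edges_s = c(60, 180, 360),
                            ep_reference = c("3mt", "individual"),
                            procedure = c("dunnett", "bonferroni"),
                            alpha = 0.05, seed = NULL) {
  ep_reference <- match.arg(ep_reference)
  procedure <- match.arg(procedure)
  for (nm in c("fs_hz", "ep_window_s", "tolerance_w", "lapse_s", "window_s",
               "slope_w_per_s", "hold_s")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0) stop_critpow(nm, " must be > 0")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_critpow("alpha must lie in (0, 1)")
  }
  stopifnot(is.numeric(bin_edges_s), length(bin_edges_s) == 3L,
            !is.unsorted(bin_edges_s), all(bin_edges_s > 0))
  structure(list(fs_hz = fs_hz, ep_window_s = ep_window_s,
                 tolerance_w = tolerance_w, lapse_s = lapse_s,
                 window_s = window_s, slope_w_per_s = slope_w_per_s,
                 hold_s = hold_s, refine_failure = isTRUE(refine_failure),
                 clip_negative = isTRUE(clip_negative),
                 bin_edges_s = as.double(bin_edges_s),
                 ep_reference = ep_reference, procedure = procedure,
                 alpha = alpha, seed = seed),
            class = "cp_config")
}

#' @export
print.cp_config <- function(x, ...) {
  cat("<cp_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated `cp_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cp_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Analyse one athlete's test set
#'
#' Runs the full per-athlete chain: 3MT analysis, segmentation and W'
#' partitioning of each CPT against the 3MT reference EP, and the
#' traditional power-1/time fit from the prescribed powers and maintained
#' (constant-phase) durations of the CPTs.
#'
#' @param three_mt List with `trace` (and optionally `meta`) for the 3MT.
#' @param cpts List of CPT tests, each a list with `trace` and `meta`
#'   (carrying `prescribed_power`).
#' @param athlete_id Athlete identifier.
#' @param config A [pipeline_config()].
#' @return An `athlete_result`: list with `athlete_id`, `traditional_fit`
#'   ([critical_power()] fit), `three_mt` ([analyze_3mt()] result) and
#'   `cpt_results` (list of [analyze_cpt()] results named by duration bin,
#'   each with attributes `prescribed_power` and `segmentation`).
#' @export
analyze_athlete <- function(three_mt, cpts, athlete_id, config = pipeline_config()) {
  stopifnot(inherits(config, "cp_config"))
  tm <- analyze_3mt(three_mt$trace, ep_window_s = config$ep_window_s,
                    clip_negative = config$clip_negative)
  cpt_results <- list()
  powers <- durations <- numeric(0)
  for (tst in cpts) {
    pw <- tst$meta$prescribed_power
    if (is.null(pw)) stop_critpow("CPT without prescribed_power for athlete ", athlete_id)
    seg <- segment_cpt(tst$trace, pw,
                       tolerance_w = config$tolerance_w,
                       lapse_s = config$lapse_s,
                       window_s = config$window_s,
                       slope_w_per_s = config$slope_w_per_s,
                       hold_s = config$hold_s,
                       refine = config$refine_failure)
    res <- analyze_cpt(tst$trace, seg, ep_reference_3mt = tm$ep,
                       ep_reference = config$ep_reference,
                       ep_window_s = config$ep_window_s,
                       clip_negative = config$clip_negative,
                       bin_edges_s = config$bin_edges_s)
    attr(res, "prescribed_power") <- pw
    attr(res, "segmentation") <- seg
    cpt_results[[res$duration_bin]] <- res
    powers <- c(powers, pw)
    durations <- c(durations, res$constant_duration_s)
  }
  fit <- if (length(powers) >= 2L) critical_power(powers, durations) else NULL
  structure(list(athlete_id = athlete_id, traditional_fit = fit,
                 three_mt = tm, cpt_results = cpt_results),
            class = "athlete_result")
}

#' Run the cohort pipeline
#'
#' Accepts either a directory of trace CSVs (as written by [write_trace()]
#' / [write_cohort()]; files are grouped by the `athlete_id` metadata and
#' each athlete must have exactly one 3MT) or a [simulate_cohort()] object.
#' Produces per-athlete results, the long table, a Table-1-style summary
#' (mean +/- SD per condition and variable) and the group comparisons
#' (EP of every test against the traditional CP, and total W' of every
#' test against the 3MT).
#'
#' @param x Directory path or `simulated_cohort`.
#' @param config A [pipeline_config()].
#' @return An object of class `cp_cohort_report`: list with `athletes`,
#'   `long_table`, `summary` (rendered character matrix, see
#'   [render_summary()]), `stats` (list of [rm_anova_cs()] results) and
#'   `config`.
#' @export
run_pipeline <- function(x, config = pipeline_config()) {
  stopifnot(inherits(config, "cp_config"))
  groups <- if (inherits(x, "simulated_cohort")) {
    lapply(x, function(ath) list(athlete_id = ath$athlete_id,
                                 three_mt = ath$three_mt, cpts = ath$cpts))
  } else if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    .read_cohort_dir(x)
  } else {
    stop_critpow("x must be a directory path or a simulated_cohort")
  }
  athletes <- lapply(groups, function(g) {
    analyze_athlete(g$three_mt, g$cpts, g$athlete_id, config)
  })
  tab <- build_long_table(athletes)
  stats_out <- list()
  if ("Traditional" %in% tab$condition && length(unique(tab$athlete_id)) >= 3L) {
    stats_out$EP <- rm_anova_cs(tab, "EP", control = "Traditional",
                                procedure = config$procedure,
                                alpha = config$alpha)
    stats_out$total_w_prime <- rm_anova_cs(tab, "total_w_prime",
                                           control = "3MT",
                                           procedure = config$procedure,
                                           alpha = config$alpha)
  }
  structure(list(athletes = athletes, long_table = tab,
                 summary = render_summary(tab), stats = stats_out,
                 config = config),
            class = "cp_cohort_report")
}

.read_cohort_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0L) stop_critpow("no trace CSVs in ", dir)
  tests <- lapply(sort(files), read_trace)
  ids <- vapply(tests, function(x) x$meta$athlete_id, character(1))
  lapply(split(tests, ids), function(ts) {
    kinds <- vapply(ts, function(x) x$meta$test_kind, character(1))
    if (sum(kinds == "3MT") != 1L) {
      stop_critpow("athlete ", ts[[1L]]$meta$athlete_id,
                   " must have exactly one 3MT (reference EP)")
    }
    list(athlete_id = ts[[1L]]$meta$athlete_id,
         three_mt = ts[[which(kinds == "3MT")]],
         cpts = ts[kinds == "CPT"])
  })
}

#' Render a cohort summary table
#'
#' Mean +/- SD per condition (columns) and variable (rows), formatted with
#' `digits` decimal places (default 0, i.e. integer watts and joules).  All
#' internal statistics are computed at full precision; rounding happens
#' only at render time.  A single observation renders its SD as 0.
#'
#' @param x A long table from [build_long_table()] (or a list of athlete
#'   results, which is flattened first).
#' @param digits Decimal places.  Default 0.
#' @return A character matrix of `"mean +/- sd"` cells with numeric
#'   matrices attached as attributes `mean`, `sd` and `n`.
#' @export
render_summary <- function(x, digits = 0) {
  tab <- if (is.data.frame(x)) x else build_long_table(x)
  if (nrow(tab) == 0L) stop_critpow("empty results")
  conds <- levels(tab$condition)
  vars <- intersect(.variables, unique(tab$variable))
  m <- s <- nmat <- matrix(NA_real_, nrow = length(vars), ncol = length(conds),
                           dimnames = list(vars, conds))
  for (v in vars) for (cc in conds) {
    vals <- tab$value[tab$variable == v & tab$condition == cc]
    if (length(vals) == 0L) next
    m[v, cc] <- mean(vals)
    s[v, cc] <- if (length(vals) > 1L) stats::sd(vals) else 0
    nmat[v, cc] <- length(vals)
  }
  cells <- matrix("", nrow = length(vars), ncol = length(conds),
                  dimnames = list(vars, conds))
  fmt <- function(x) formatC(round(x, digits), format = "f", digits = digits)
  for (i in seq_along(vars)) for (j in seq_along(conds)) {
    if (!is.na(m[i, j])) {
      cells[i, j] <- paste0(fmt(m[i, j]), " ± ", fmt(s[i, j]))
    }
  }
  structure(cells, mean = m, sd = s, n = nmat)
}

#' @export
print.cp_cohort_report <- function(x, ...) {
  cat(sprintf("Cohort of %d athletes\n\n", length(x$athletes)))
  cells <- x$summary
  attributes(cells)[c("mean", "sd", "n")] <- NULL
  print(cells, quote = FALSE)
  if (length(x$stats)) {
    cat("\n")
    for (st in x$stats) print(st)
  }
  invisible(x)
}

#' @export
summary.cp_cohort_report <- function(object, ...) object$summary
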