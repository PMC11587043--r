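# Group-level comparisons: long-format result table, repeated-measures
# ANOVA under compound symmetry, Dunnett many-to-one and Bonferroni
# adjustment.

.conditions <- c("Traditional", "3MT", "CPT<1", "CPT1-3", "CPT3-6", "CPT>6")
.variables <- c("EP", "constant_w_prime", "unaccounted_w_prime", "total_w_prime")

.bin_to_condition <- c("<1 min" = "CPT<1", "1-3 min" = "CPT1-3",
                       "3-6 min" = "CPT3-6", ">6 min" = "CPT>6")

#' Flatten per-athlete results to a long table
#'
#' Builds the analysis-ready long format with one row per (athlete,
#' condition, variable): `Traditional` contributes CP (as the `EP`
#' variable) and the traditional W' (as `total_w_prime`); `3MT` contributes
#' its EP and W'; each CPT duration bin contributes its EP (individual end
#' power) and all three W' components.  Missing tests simply contribute no
#' rows; duplicates are an error.
#'
#' @param results List of per-athlete results as produced by
#'   [run_pipeline()] (each with `athlete_id`, `traditional_fit`,
#'   `three_mt`, `cpt_results`).
#' @return A `data.frame` with columns `athlete_id`, `condition` (factor
#'   over the six test conditions), `variable` and `value`, ordered by
#'   athlete, condition, variable.
#' @export
build_long_table <- function(results) {
  if (length(results) == 0L) stop_critpow("no results")
  rows <- list()
  add <- function(id, cond, var, val) {
    if (is.null(val) || is.na(val)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      athlete_id = id, condition = cond, variable = var, value = val,
      stringsAsFactors = FALSE)
  }
  for (res in results) {
    id <- res$athlete_id
    if (!is.null(res$traditional_fit)) {
      add(id, "Traditional", "EP", res$traditional_fit$cp)
      add(id, "Traditional", "total_w_prime", res$traditional_fit$w_prime)
    }
    if (!is.null(res$three_mt)) {
      add(id, "3MT", "EP", res$three_mt$ep)
      add(id, "3MT", "total_w_prime", res$three_mt$w_prime)
    }
    for (cr in res$cpt_results) {
      cond <- unname(.bin_to_condition[cr$duration_bin])
      add(id, cond, "EP", cr$ep_individual)
      add(id, cond, "constant_w_prime", cr$constant_w_prime)
      add(id, cond, "unaccounted_w_prime", cr$unaccounted_w_prime)
      add(id, cond, "total_w_prime", cr$total_w_prime)
    }
  }
  tab <- do.call(rbind, rows)
  key <- paste(tab$athlete_id, tab$condition, tab$variable, sep = "\r")
  if (anyDuplicated(key)) {
    stop_critpow("duplicate (athlete, condition, variable) rows — ",
                 "two tests fell in the same duration bin?")
  }
  tab$condition <- factor(tab$condition, levels = .conditions)
  tab <- tab[order(tab$athlete_id, tab$condition, tab$variable), ]
  rownames(tab) <- NULL
  tab
}

.check_long_table <- function(table, variable) {
  stopifnot(is.data.frame(table),
            all(c("athlete_id", "condition", "variable", "value") %in% names(table)))
  if (!variable %in% table$variable) {
    stop_critpow("variable '", variable, "' absent from the table")
  }
  d <- table[table$variable == variable, , drop = FALSE]
  d$condition <- factor(as.character(d$condition))
  d$athlete_id <- as.character(d$athlete_id)
  key <- paste(d$athlete_id, d$condition, sep = "\r")
  if (anyDuplicated(key)) stop_critpow("duplicate (athlete, condition) values")
  d
}

#' Repeated-measures ANOVA with many-to-one comparisons
#'
#' Omnibus test and per-condition comparisons against a control condition
#' for one variable of a long table, under the compound-symmetry model
#' (equal variances, equal pairwise correlations across conditions —
#' equivalent to a subject random intercept).
#'
#' For complete balanced data the classical within-subject ANOVA is
#' computed in closed form, and the many-to-one comparisons use the pooled
#' error term with single-step Dunnett adjustment via [dunnett_pvalue()]
#' (or Bonferroni when `procedure = "bonferroni"`).  Unbalanced data are
#' handled by the equivalent linear mixed model
#' (`lmer(value ~ condition + (1 | athlete))`) with the same adjustments
#' through \pkg{multcomp}.
#'
#' @param table Long table from [build_long_table()].
#' @param variable Which variable to analyse (e.g. `"total_w_prime"`).
#' @param control Control condition name (e.g. `"3MT"` or `"Traditional"`).
#' @param procedure `"dunnett"` (default) or `"bonferroni"`.
#' @param alpha Significance level recorded in the result.  Default 0.05.
#' @return An object of class `cp_comparison`: list with `F`, `df_num`,
#'   `df_den`, `p_omnibus`, `comparisons` (data.frame with `condition`,
#'   `estimate`, `se`, `t`, `p_raw`, `p_adj`), `procedure`, `control`,
#'   `variable`, `engine` (`"closed_form_cs"` or `"lmm"`).
#' @export
rm_anova_cs <- function(table, variable, control,
                        procedure = c("dunnett", "bonferroni"),
                        alpha = 0.05) {
  procedure <- match.arg(procedure)
  d <- .check_long_table(table, variable)
  levs <- levels(d$condition)
  if (!control %in% levs) stop_critpow("control condition '", control, "' absent")
  if (length(levs) < 2L) stop_critpow("need at least 2 conditions")
  n_per <- table(d$athlete_id)
  if (sum(n_per >= 2L) < 3L) {
    stop_critpow("need at least 3 athletes with data in 2 or more conditions")
  }
  wide <- stats::xtabs(value ~ athlete_id + condition, data = d)
  has <- stats::xtabs(~ athlete_id + condition, data = d)
  balanced <- all(has == 1L)
  if (balanced) {
    out <- .rm_anova_balanced(as.matrix(wide), control, procedure)
  } else {
    out <- .rm_anova_lmm(d, control, procedure)
  }
  out$procedure <- procedure
  out$control <- control
  out$variable <- variable
  out$alpha <- alpha
  class(out) <- "cp_comparison"
  out
}

# Closed-form within-subject ANOVA on a complete n x k matrix.
.rm_anova_balanced <- function(Y, control, procedure) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  m_cond <- colMeans(Y)
  m_subj <- rowMeans(Y)
  ss_cond <- n * sum((m_cond - grand)^2)
  resid <- Y - outer(m_subj, rep(1, k)) - outer(rep(1, n), m_cond) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1L
  df2 <- (n - 1L) * (k - 1L)
  mse <- ss_err / df2
  if (mse == 0) {
    Fv <- if (ss_cond == 0) 0 else Inf
  } else {
    Fv <- (ss_cond / df1) / mse
  }
  p_omni <- if (mse == 0 && ss_cond == 0) 1 else stats::pf(Fv, df1, df2, lower.tail = FALSE)
  others <- setdiff(colnames(Y), control)
  est <- m_cond[others] - m_cond[control]
  se <- sqrt(2 * mse / n)
  tstat <- if (se == 0) ifelse(est == 0, 0, sign(est) * Inf) else est / se
  p_raw <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
  p_adj <- switch(procedure,
    dunnett = dunnett_pvalue(tstat, k = length(others), df = df2),
    bonferroni = pmin(1, length(others) * p_raw))
  list(F = Fv, df_num = df1, df_den = df2, p_omnibus = p_omni,
       comparisons = data.frame(condition = others, estimate = unname(est),
                                se = se, t = unname(tstat),
                                p_raw = unname(p_raw), p_adj = unname(p_adj),
                                stringsAsFactors = FALSE),
       engine = "closed_form_cs")
}

# Mixed-model route for unbalanced data (subject random intercept = CS).
.rm_anova_lmm <- function(d, control, procedure) {
  d$condition <- stats::relevel(d$condition, ref = control)
  m <- lmerTest::lmer(value ~ condition + (1 | athlete_id), data = d)
  an <- stats::anova(m)
  glht_proc <- if (procedure == "dunnett") multcomp::adjusted("single-step")
               else multcomp::adjusted("bonferroni")
  gl <- multcomp::glht(m, linfct = multcomp::mcp(condition = "Dunnett"))
  sm <- summary(gl, test = glht_proc)
  sm_raw <- summary(gl, test = multcomp::adjusted("none"))
  others <- sub(" - .*$", "", names(sm$test$coefficients))
  list(F = unname(an$`F value`[1L]),
       df_num = unname(an$NumDF[1L]), df_den = unname(an$DenDF[1L]),
       p_omnibus = unname(an$`Pr(>F)`[1L]),
       comparisons = data.frame(condition = others,
                                estimate = unname(sm$test$coefficients),
                                se = unname(sm$test$sigma),
                                t = unname(sm$test$tstat),
                                p_raw = unname(sm_raw$test$pvalues),
                                p_adj = unname(as.vector(sm$test$pvalues)),
                                stringsAsFactors = FALSE),
       engine = "lmm")
}

#' @export
print.cp_comparison <- function(x, ...) {
  cat(sprintf("Repeated-measures comparison of %s (control: %s, %s)\n",
              x$variable, x$control, x$procedure))
  cat(sprintf("  Omnibus F(%g, %g) = %.3f, p = %.4g  [%s]\n",
              x$df_num, x$df_den, x$F, x$p_omnibus, x$engine))
  cmp <- x$comparisons
  cmp$estimate <- round(cmp$estimate, 2)
  cmp$t <- round(cmp$t, 3)
  cmp$p_raw <- signif(cmp$p_raw, 3)
  cmp$p_adj <- signif(cmp$p_adj, 3)
  print(cmp, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-adjusted paired comparisons
#'
#' Paired t-tests for an explicit list of condition pairs on one variable,
#' with each p-value multiplied by the number of pairs (capped at 1).
#'
#' @param table Long table from [build_long_table()].
#' @param variable Which variable to analyse.
#' @param pairs List of length-2 character vectors (condition pairs), or a
#'   2-column matrix.
#' @return A `cp_comparison` with one row per pair (`condition` gives
#'   `"A vs B"`); `F`, `df_num`, `df_den`, `p_omnibus` are `NA` (no omnibus
#'   model is fitted).
#' @export
bonferroni_compare <- function(table, variable, pairs) {
  d <- .check_long_table(table, variable)
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1L)
  if (length(pairs) == 0L) stop_critpow("empty pair list")
  k <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    if (!all(pr %in% levels(d$condition))) {
      stop_critpow("pair references missing condition: ",
                   paste(pr, collapse = " vs "))
    }
    a <- d[d$condition == pr[1L], c("athlete_id", "value")]
    b <- d[d$condition == pr[2L], c("athlete_id", "value")]
    common <- intersect(a$athlete_id, b$athlete_id)
    if (length(common) < 2L) stop_critpow("fewer than 2 paired observations for ",
                                          paste(pr, collapse = " vs "))
    diffs <- a$value[match(common, a$athlete_id)] -
      b$value[match(common, b$athlete_id)]
    tt <- stats::t.test(diffs)
    data.frame(condition = paste(pr[1L], "vs", pr[2L]),
               estimate = mean(diffs),
               se = unname(tt$stderr),
               t = unname(tt$statistic),
               p_raw = tt$p.value,
               p_adj = min(1, k * tt$p.value),
               stringsAsFactors = FALSE)
  })
  structure(list(F = NA_real_, df_num = NA_real_, df_den = NA_real_,
                 p_omnibus = NA_real_,
                 comparisons = do.call(rbind, rows),
                 procedure = "bonferroni", control = NA_character_,
                 variable = variable, alpha = 0.05, engine = "paired_t"),
            class = "cp_comparison")
}
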