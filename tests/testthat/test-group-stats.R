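test_that("per-athlete results flatten to the expected long format", {
  res <- list(
    mock_athlete_result("A1", 289, 9400, 274, 15300, list(
      mock_cpt_row("<1 min", 279, 8800, 5900),
      mock_cpt_row(">6 min", 249, 25800, 1200))),
    mock_athlete_result("A2", 300, 10000, 280, 16000, list(
      mock_cpt_row("<1 min", 285, 9000, 6000)))
  )
  tab <- build_long_table(res)
  # 2 athletes x (Traditional 2 + 3MT 2 rows) + 3 CPTs x 4 rows
  expect_equal(nrow(tab), 2 * 4 + 3 * 4)
  expect_true(all(levels(tab$condition) ==
                    c("Traditional", "3MT", "CPT<1", "CPT1-3", "CPT3-6", "CPT>6")))
  # missing bins contribute no rows, with no imputation
  expect_equal(sum(tab$condition == "CPT>6"), 4)
  expect_equal(sum(tab$athlete_id == "A2" & tab$condition == "CPT>6"), 0)
  # aggregation oracle: condition means equal means of the inputs
  m <- attr(render_summary(tab), "mean")
  expect_equal(m["EP", "Traditional"], mean(c(289, 300)))
  expect_equal(m["total_w_prime", "CPT<1"], mean(c(8800 + 5900, 9000 + 6000)))
  # duplicated bins are an error
  res_dup <- res
  res_dup[[2]]$cpt_results <- c(res_dup[[2]]$cpt_results,
                                list(mock_cpt_row("<1 min", 280, 9100, 6100)))
  expect_error(build_long_table(res_dup), "duplicate")
})

test_that("identical values across conditions give a null comparison", {
  tab <- expand.grid(athlete_id = sprintf("A%d", 1:6),
                     condition = c("Traditional", "3MT", "CPT<1"),
                     stringsAsFactors = FALSE)
  tab$variable <- "EP"
  tab$value <- rep(c(250, 260, 270, 280, 290, 300), times = 3)
  out <- rm_anova_cs(tab, "EP", control = "3MT")
  expect_equal(out$F, 0)
  expect_equal(out$p_omnibus, 1)
  expect_true(all(out$comparisons$p_adj == 1))
})

test_that("the closed-form Dunnett probability matches mvtnorm::pmvt", {
  skip_if_not_installed("mvtnorm")
  set.seed(41)
  for (df in c(30, 135)) {
    for (k in c(2, 5)) {
      corr <- matrix(0.5, k, k); diag(corr) <- 1
      for (cv in c(1.5, 2.5, 3.2)) {
        ref <- mvtnorm::pmvt(lower = rep(-cv, k), upper = rep(cv, k),
                             corr = corr, df = df,
                             algorithm = mvtnorm::GenzBretz(abseps = 1e-5,
                                                            maxpts = 100000))
        expect_equal(dunnett_prob(cv, k, df), as.numeric(ref),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("balanced closed form agrees with the mixed-model route", {
  set.seed(43)
  tab <- null_long_table(12, subject_sd = 2000)
  a <- rm_anova_cs(tab, "total_w_prime", control = "3MT")
  expect_equal(a$engine, "closed_form_cs")
  # run the mixed-model engine on the same balanced data
  d <- critpow:::.check_long_table(tab, "total_w_prime")
  b <- critpow:::.rm_anova_lmm(d, "3MT", "dunnett")
  expect_equal(a$F, b$F, tolerance = 0.02)
  expect_equal(a$df_den, b$df_den, tolerance = 0.05)
  cmp <- merge(a$comparisons, b$comparisons, by = "condition")
  expect_equal(cmp$t.x, cmp$t.y, tolerance = 0.02)
  expect_equal(cmp$p_adj.x, cmp$p_adj.y, tolerance = 0.02)
  # unbalanced data routes to the mixed model automatically
  u <- rm_anova_cs(tab[-5, ], "total_w_prime", control = "3MT")
  expect_equal(u$engine, "lmm")
  expect_s3_class(u, "cp_comparison")
})

test_that("Dunnett adjusted p never exceeds Bonferroni on the same family", {
  set.seed(47)
  for (r in 1:25) {
    tab <- null_long_table(10, subject_sd = 1500)
    d <- rm_anova_cs(tab, "total_w_prime", control = "3MT",
                     procedure = "dunnett")
    b <- rm_anova_cs(tab, "total_w_prime", control = "3MT",
                     procedure = "bonferroni")
    expect_true(all(d$comparisons$p_adj <= b$comparisons$p_adj + 1e-10))
  }
})

test_that("Bonferroni paired comparisons multiply and cap the p-value", {
  set.seed(53)
  tab <- null_long_table(10)
  one <- bonferroni_compare(tab, "total_w_prime",
                            list(c("3MT", "Traditional")))
  expect_equal(one$comparisons$p_adj, one$comparisons$p_raw)
  pairs6 <- list(c("3MT", "Traditional"), c("3MT", "CPT<1"),
                 c("3MT", "CPT1-3"), c("3MT", "CPT3-6"),
                 c("3MT", "CPT>6"), c("Traditional", "CPT<1"))
  six <- bonferroni_compare(tab, "total_w_prime", pairs6)
  expect_true(all(six$comparisons$p_adj <= 1))
  raw <- six$comparisons$p_raw
  expect_equal(six$comparisons$p_adj, pmin(1, 6 * raw))
  expect_error(bonferroni_compare(tab, "total_w_prime", list(c("3MT", "nope"))),
               "missing condition")
})

test_that("the omnibus test is invariant under condition relabeling", {
  set.seed(59)
  tab <- null_long_table(8, subject_sd = 1000)
  a <- rm_anova_cs(tab, "total_w_prime", control = "3MT")
  relab <- tab
  relab$condition <- factor(as.character(relab$condition),
                            levels = rev(sort(unique(as.character(relab$condition)))))
  b <- rm_anova_cs(relab, "total_w_prime", control = "3MT")
  expect_equal(a$F, b$F, tolerance = 1e-10)
  expect_equal(a$p_omnibus, b$p_omnibus, tolerance = 1e-10)
})

test_that("a shifted condition is flagged while nulls are spared", {
  set.seed(61)
  n <- 28
  tab <- null_long_table(n, mean = 15000, sd = 2000, subject_sd = 3000)
  shift <- tab$condition == "CPT>6"
  tab$value[shift] <- tab$value[shift] + 6000
  out <- rm_anova_cs(tab, "total_w_prime", control = "3MT")
  flagged <- out$comparisons$condition[out$comparisons$p_adj < 0.05]
  expect_true("CPT>6" %in% flagged)
  expect_gt(out$F, 10)
})
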