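# minimal analysis table for fitting against closed-form expectations
fit_table <- function(x, y) {
  tibble::tibble(participant_id = as.character(seq_along(x)),
                 bad_performances = x, tug_decline = y)
}

fit1 <- function(x, y) {
  d <- covariate_design(fit_table(x, y), 1, "bad_performances",
                        "tug_decline", baseline_impaired = "keep")
  fit_logistic(d)
}

test_that("a 2x2 table reproduces the closed-form cross-ratio", {
  # exposed: 20 events / 80 non-events; unexposed: 10 / 90
  x <- rep(c(1L, 0L), c(100, 100))
  y <- c(rep(1L, 20), rep(0L, 80), rep(1L, 10), rep(0L, 90))
  f <- fit1(x, y)
  t <- f$terms[f$terms$term == "bad_performances", ]
  expect_equal(t$or, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("Wald intervals are exp(estimate +/- z * SE) exactly", {
  set.seed(8)
  x <- rpois(400, 1)
  y <- rbinom(400, 1, plogis(-1 + 0.3 * x))
  f <- fit1(x, y)
  z <- qnorm(0.975)
  expect_equal(f$terms$ci_low, exp(f$terms$estimate - z * f$terms$se),
               tolerance = 1e-6)
  expect_equal(f$terms$ci_high, exp(f$terms$estimate + z * f$terms$se),
               tolerance = 1e-6)
  expect_equal(f$terms$or, exp(f$terms$estimate), tolerance = 1e-12)
  expect_true(all(f$terms$ci_low <= f$terms$or &
                    f$terms$or <= f$terms$ci_high))
})

test_that("rank deficiency and separation fail loudly", {
  tab <- analysis_table()
  tab$mean_rt_ms <- tab$bad_performances  # duplicated information
  expect_error(
    fit_logistic(covariate_design(tab, 2, "bad_performances",
                                  "tug_decline")),
    "rank-deficient")

  x <- c(rep(0L, 30), rep(5L, 30))
  y <- as.integer(x > 2)
  suppressWarnings(expect_error(fit1(x, y), "separation"))
})

test_that("log-likelihood never decreases along the nested suite", {
  tab <- analysis_table()
  tab <- tab[stats::complete.cases(tab), ]  # identical rows across models
  suite <- run_model_suite(tab, "bad_performances", "tug_decline")
  ll <- vapply(suite, function(f) f$loglik, 0)
  expect_identical(unname(vapply(suite, function(f) f$n_used, 0L)),
                   rep(suite[["1"]]$n_used, 5L))
  expect_true(all(diff(ll) >= -1e-8))
  # 4a extends 4 by the baseline gait-speed term
  expect_true("ugs_w1" %in% suite[["4a"]]$terms$term)
  expect_false("ugs_w1" %in% suite[["4"]]$terms$term)
})

test_that("the Spearman screen reports the pairwise structure", {
  set.seed(21)
  x <- matrix(rnorm(3000), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  chk <- collinearity_check(x)
  expect_equal(unname(diag(chk$rho)), rep(1, 3))
  expect_lt(chk$max_abs_rho, 0.15)
  expect_true(chk$pass)

  tab <- analysis_table()
  d4 <- covariate_design(tab, 4, "bad_performances", "tug_decline")
  chk4 <- collinearity_check(d4)
  expect_true(chk4$pass)
  f4 <- fit_logistic(d4)
  expect_equal(f4$max_abs_rho, chk4$max_abs_rho)

  expect_error(collinearity_check(x[, 1, drop = FALSE]), "at least 2")
})

test_that("normality tests flag the SART features as non-normal", {
  co <- simulate_cohort(sart_config(n_participants = 2500, seed = 13))
  fx <- extract_sart_features(co$streams,
                              threshold = fixed_sart_threshold(4))
  for (v in c("bad_performances", "total_mistakes",
              "mistakes_in_good_performances")) {
    ns <- normality_screen(fx$features[[v]])
    expect_lt(ns$ks_p, 0.001)
    expect_lt(ns$shapiro_p, 0.001)
    expect_false(ns$normal)
  }
  expect_error(normality_screen(c(1, 2)), "at least 3")
  expect_error(normality_screen(rep(1, 50)), "constant")
})

test_that("normality tests accept genuinely normal draws", {
  ok <- vapply(1:100, function(s) {
    set.seed(s)
    normality_screen(rnorm(5000))$normal
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("the paired Wilcoxon test detects a uniform shift", {
  set.seed(3)
  w1 <- rnorm(50, 10, 2)
  res <- paired_wilcoxon(w1, w1 + 1)
  expect_lt(res$p_value, 0.001)
  expect_error(paired_wilcoxon(w1, w1), "zero")
})

test_that("the Mann-Whitney U statistic behaves at the extremes", {
  res <- mannwhitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_identical(unname(res$statistic), 0)
  expect_lt(res$p_value, 0.2)  # n too small for more
  same <- mannwhitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_error(mannwhitney_u(numeric(0), 1), "non-empty")
})

test_that("wave comparisons on synthetic data show the built-in trends", {
  co <- simulate_cohort(sart_config(n_participants = 1500, seed = 23))
  fx <- extract_sart_features(co$streams,
                              threshold = fixed_sart_threshold(4))
  tab <- suppressMessages(merge_waves(co$cohort, fx$features))
  # TUG rises between waves by construction
  expect_lt(paired_wilcoxon(tab$tug_w1, tab$tug_w3)$p_value, 0.05)
  # and rises faster for participants with bad performances
  d <- tab$tug_w3 - tab$tug_w1
  grp <- tab$bad_performances > 0
  expect_lt(mannwhitney_u(d[grp], d[!grp])$p_value, 0.05)
})

test_that("predictor comparison flags CIs consistently with its table", {
  tab <- analysis_table()
  cmp <- compare_predictors(tab, "tug_decline", models = c("1", "4"))
  expect_identical(nrow(cmp$table), 6L)
  for (i in seq_len(nrow(cmp$overlap))) {
    r <- cmp$table[cmp$table$model_id == cmp$overlap$model_id[i], ]
    iv <- function(p) r[r$predictor == p, c("ci_low", "ci_high")]
    a <- iv("bad_performances"); b <- iv("total_mistakes")
    expect_identical(cmp$overlap$bad_vs_total[i],
                     a$ci_low <= b$ci_high && b$ci_low <= a$ci_high)
  }
  # identical predictors must overlap everywhere
  tab2 <- tab
  tab2$total_mistakes <- tab2$bad_performances
  tab2$mistakes_in_good_performances <- tab2$bad_performances
  cmp2 <- compare_predictors(tab2, "tug_decline", models = "1")
  expect_true(all(unlist(cmp2$overlap[c("bad_vs_total", "bad_vs_good",
                                        "total_vs_good")])))
  # the TUG increment is steeper in the bad-performance group
  expect_gt(cmp$group_slopes["bad"], cmp$group_slopes["good"])
})
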