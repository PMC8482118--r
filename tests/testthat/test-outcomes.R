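rec <- function(...) {
  base <- tibble::tibble(
    participant_id = "x", tug_w1 = 9, tug_w3 = 10, ugs_w1 = 130,
    ugs_w3 = 125, falls_w1 = 0L, falls_w3 = 0L, mmse_w1 = 29L,
    mmse_w3 = 29L)
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}

test_that("outcome flags honour the clinical cut-offs at the boundary", {
  expect_identical(derive_outcomes(rec(tug_w1 = 11.9,
                                       tug_w3 = 12))$tug_decline, 1L)
  expect_identical(derive_outcomes(rec(tug_w1 = 12,
                                       tug_w3 = 15))$tug_decline, 0L)
  expect_identical(derive_outcomes(rec(ugs_w1 = 100,
                                       ugs_w3 = 99.9))$ugs_decline, 1L)
  expect_identical(derive_outcomes(rec(ugs_w1 = 99.9,
                                       ugs_w3 = 90))$ugs_decline, 0L)
  expect_identical(derive_outcomes(rec(falls_w1 = 0L,
                                       falls_w3 = 2L))$new_faller, 1L)
  expect_identical(derive_outcomes(rec(falls_w1 = 1L,
                                       falls_w3 = 2L))$new_faller, 0L)
  expect_identical(derive_outcomes(rec(mmse_w1 = 28L,
                                       mmse_w3 = 26L))$mmse_decline, 1L)
  expect_identical(derive_outcomes(rec(mmse_w1 = 28L,
                                       mmse_w3 = 27L))$mmse_decline, 0L)
  # a missing input yields a missing flag, nothing else
  out <- derive_outcomes(rec(tug_w3 = NA))
  expect_true(is.na(out$tug_decline))
  expect_identical(out$mmse_decline, 0L)
})

test_that("raising wave-3 TUG can never rescue a declined participant", {
  for (w1 in c(8, 10, 11.9)) {
    flags <- vapply(seq(12, 30, by = 2), function(w3)
      derive_outcomes(rec(tug_w1 = w1, tug_w3 = w3))$tug_decline, 1L)
    expect_true(all(flags == 1L))
  }
})

test_that("outcome derivation commutes with row permutation", {
  co <- small_cohort()$cohort
  out <- derive_outcomes(co)
  perm <- sample(nrow(co))
  out_perm <- derive_outcomes(co[perm, ])
  expect_equal(as.data.frame(out_perm), as.data.frame(out[perm, ]))
})

test_that("merging keeps only participants observed at both waves", {
  co <- small_cohort()
  fx <- extract_sart_features(co$streams,
                              threshold = fixed_sart_threshold(4))
  expect_message(tab <- merge_waves(co$cohort, fx$features), "merged")
  w3 <- tab[c("tug_w3", "ugs_w3", "falls_w3", "mmse_w3")]
  expect_true(all(rowSums(!is.na(w3)) > 0))
  # attrition leaves roughly the configured fraction behind
  expect_lt(nrow(tab), nrow(co$cohort))
  expect_gt(nrow(tab), 0.6 * nrow(co$cohort))

  disjoint <- fx$features
  disjoint$participant_id <- paste0("zz", disjoint$participant_id)
  expect_warning(empty <- merge_waves(co$cohort, disjoint), "no participants")
  expect_identical(nrow(empty), 0L)

  dup <- co$cohort[c(1, 1, 2), ]
  expect_error(merge_waves(dup, fx$features), "duplicate")
})

test_that("each model of the suite has its documented column set", {
  tab <- analysis_table()
  d1 <- covariate_design(tab, 1, "bad_performances", "tug_decline")
  expect_identical(colnames(d1$x), c("(Intercept)", "bad_performances"))

  d4 <- covariate_design(tab, "4", "bad_performances", "tug_decline")
  d4a <- covariate_design(tab, "4a", "bad_performances", "tug_decline")
  expect_setequal(setdiff(colnames(d4a$x), colnames(d4$x)), "ugs_w1")

  # 3-level factors produce two dummies against the reference level
  expect_setequal(grep("^smoking", colnames(d4$x), value = TRUE),
                  c("smokingpast", "smokingcurrent"))
  expect_setequal(grep("^drinking", colnames(d4$x), value = TRUE),
                  c("drinking_problemyes", "drinking_problemdont_know"))
  expect_setequal(grep("^education", colnames(d4$x), value = TRUE),
                  c("educationsecondary", "educationthird/higher"))

  expect_error(covariate_design(tab, "5", "bad_performances",
                                "tug_decline"), "unknown model_id")
  expect_error(covariate_design(tab, 1, "age", "tug_decline"),
               "predictor")
})

test_that("every model's design has full column rank on synthetic data", {
  tab <- analysis_table()
  for (m in c("1", "2", "3", "4", "4a")) {
    d <- covariate_design(tab, m, "total_mistakes", "tug_decline")
    expect_identical(qr(d$x)$rank, ncol(d$x))
  }
})

test_that("baseline-impaired participants are excluded unless kept", {
  tab <- analysis_table()
  d_drop <- covariate_design(tab, 1, "bad_performances", "tug_decline")
  d_keep <- covariate_design(tab, 1, "bad_performances", "tug_decline",
                             baseline_impaired = "keep")
  expect_true(all(d_drop$data$tug_decline %in% 0:1))
  n_impaired <- sum(tab$tug_w1 >= 12 &
                      stats::complete.cases(tab[c("tug_w1", "tug_w3",
                                                  "bad_performances")]))
  expect_identical(d_keep$n_used - d_drop$n_used, n_impaired)

  # analogous rule for prior fallers: dropping them shrinks the sample by
  # exactly the number of complete-case wave-1 fallers
  f_drop <- covariate_design(tab, 1, "bad_performances", "new_faller")
  f_keep <- covariate_design(tab, 1, "bad_performances", "new_faller",
                             baseline_impaired = "keep")
  n_fallers <- sum(tab$falls_w1 > 0 &
                     stats::complete.cases(tab[c("falls_w1", "falls_w3",
                                                 "bad_performances")]))
  expect_identical(f_keep$n_used - f_drop$n_used, n_fallers)
})

test_that("degenerate outcomes are refused", {
  tab <- analysis_table()
  tab$mmse_decline <- 0L
  expect_error(covariate_design(tab, 1, "bad_performances",
                                "mmse_decline"), "degenerate")
})
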