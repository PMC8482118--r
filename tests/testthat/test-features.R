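test_that("cycle metrics decompose mistakes and RTs as defined", {
  s <- build_stream(list(
    perfect(),                                    # cycle 1: flawless
    list(omit = 8),                               # cycle 2: no presses
    list(omit = 7, commission = TRUE, rt = 400),  # cycle 3: 8 mistakes, 1 RT
    list(omit = 2, commission = TRUE, rt = 500),  # cycle 4: mixed
    list(omit = 0, lost_rt = 1)                   # cycle 5: lost RT
  ))
  cm <- cycle_metrics(s)
  expect_identical(nrow(cm), 23L)

  expect_identical(cm$n_mistakes[1], 0L)
  expect_identical(cm$error_fraction[1], 0)
  expect_true(cm$plottable[1])
  expect_equal(cm$mean_rt_correct_ms[1], 400)

  # withholding on the NO-GO is correct even when everything else fails
  expect_identical(cm$n_omissions[2], 8L)
  expect_identical(cm$n_commissions[2], 0L)
  expect_identical(cm$n_mistakes[2], 8L)
  expect_true(is.na(cm$mean_rt_correct_ms[2]))
  expect_false(cm$plottable[2])

  # the single correct press anchors the spot at its own RT
  expect_identical(cm$n_mistakes[3], 8L)
  expect_identical(cm$n_correct_actions[3], 1L)
  expect_equal(cm$mean_rt_correct_ms[3], 400)
  expect_true(cm$plottable[3])

  # commission RTs are excluded from the cycle mean
  expect_identical(cm$n_mistakes[4], 3L)
  expect_equal(cm$mean_rt_correct_ms[4], 500)

  # one lost RT on a press voids the whole cycle's average
  expect_identical(cm$n_mistakes[5], 0L)
  expect_true(is.na(cm$mean_rt_correct_ms[5]))
  expect_false(cm$plottable[5])

  expect_identical(cm$n_mistakes, cm$n_omissions + cm$n_commissions)
  expect_identical(cm$plottable, !is.na(cm$mean_rt_correct_ms))
})

test_that("the 2-SD rule matches a brute-force recomputation", {
  # 100 hand-built cycles with a long-tailed mistake mix
  set.seed(42)
  counts <- sample(0:8, 100, TRUE,
                   prob = c(0.55, 0.2, 0.1, 0.05, 0.04, 0.02, 0.02,
                            0.01, 0.01))
  metrics <- tibble::tibble(
    participant_id = sprintf("p%03d", 1:100),
    cycle_index = 1L,
    n_mistakes = as.integer(counts),
    error_fraction = counts / 9,
    plottable = TRUE
  )
  for (pw in c(1, 2)) {
    thr <- sart_threshold(metrics, size_power = pw)
    # independent oracle: explicit loops, no shared code path
    sizes <- (counts / 9)^pw
    m <- sum(sizes) / length(sizes)
    sdev <- sqrt(sum((sizes - m)^2) / (length(sizes) - 1))
    cut <- m + 2 * sdev
    k_oracle <- 10L
    for (k in 9:1) if ((k / 9)^pw > cut) k_oracle <- k
    expect_equal(thr$cutoff, cut, tolerance = 1e-12)
    expect_identical(thr$mistake_threshold, k_oracle)
  }
})

test_that("identical spot sizes produce a zero-SD cutoff and no big spots", {
  metrics <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:20), cycle_index = 1L,
    n_mistakes = 2L, error_fraction = 2 / 9, plottable = TRUE)
  thr <- sart_threshold(metrics)
  expect_equal(thr$size_sd, 0)
  expect_equal(thr$cutoff, (2 / 9)^2)
  # strict inequality: nothing exceeds its own mean
  expect_identical(thr$n_big_spots, 0L)
  expect_gt(thr$mistake_threshold, 2L)
})

test_that("fewer than two plottable cycles is an error", {
  metrics <- tibble::tibble(
    participant_id = "p1", cycle_index = 1:3,
    n_mistakes = c(1L, 2L, 3L), error_fraction = 1:3 / 9,
    plottable = c(TRUE, FALSE, FALSE))
  expect_error(sart_threshold(metrics), "insufficient")
})

test_that("inflating all error fractions never lowers the cutoff", {
  co <- small_cohort()
  cm <- cycle_metrics(co$streams)
  base <- sart_threshold(cm)$cutoff
  for (c_scale in c(1.5, 2, 3)) {
    scaled <- cm
    scaled$error_fraction <- pmin(1, cm$error_fraction * c_scale)
    expect_gte(sart_threshold(scaled)$cutoff, base)
  }
})

test_that("participant features decompose mistakes around the threshold", {
  plan <- rep(list(perfect()), 23)
  plan[[22]] <- list(omit = 5)             # a bad cycle (5 >= 4)
  plan[[23]] <- list(omit = 2, commission = TRUE)  # 3 mistakes: good
  s <- build_stream(plan)
  f <- participant_features(s, fixed_sart_threshold(4))
  expect_identical(f$total_mistakes, 8L)
  expect_identical(f$bad_performances, 1L)
  expect_identical(f$mistakes_in_good_performances, 3L)

  # with the ceiling threshold nothing is ever bad
  f10 <- participant_features(s, fixed_sart_threshold(10))
  expect_identical(f10$bad_performances, 0L)
  expect_identical(f10$mistakes_in_good_performances, 8L)
})

test_that("unplottable bad cycles count by default but not when excluded", {
  plan <- rep(list(perfect()), 23)
  plan[[10]] <- list(omit = 8)   # 8 mistakes, no presses: unplottable
  s <- build_stream(plan)
  thr <- fixed_sart_threshold(4)
  expect_identical(participant_features(s, thr)$bad_performances, 1L)
  expect_identical(
    participant_features(s, thr,
                         bad_perf_plottable_only = TRUE)$bad_performances,
    0L)
  # the conservation identity holds under either convention
  for (po in c(FALSE, TRUE)) {
    f <- participant_features(s, thr, bad_perf_plottable_only = po)
    cm <- cycle_metrics(s)
    bad <- cm$n_mistakes >= 4 & (cm$plottable | !po)
    expect_identical(f$total_mistakes,
                     f$mistakes_in_good_performances +
                       sum(cm$n_mistakes[bad]))
  }
})

test_that("vectorised mistake counting matches a per-presentation loop", {
  co <- small_cohort()
  cm <- cycle_metrics(co$streams)
  s <- co$streams
  for (pid in sample(unique(s$participant_id), 25)) {
    one <- s[s$participant_id == pid, ]
    for (k in sample(1:23, 6)) {
      rows <- one[one$cycle_index == k, ]
      om <- 0L; com <- 0L
      for (i in seq_len(nrow(rows))) {
        if (rows$digit[i] != 3 && !rows$pressed[i]) om <- om + 1L
        if (rows$digit[i] == 3 && rows$pressed[i]) com <- com + 1L
      }
      ref <- cm[cm$participant_id == pid & cm$cycle_index == k, ]
      expect_identical(ref$n_omissions, om)
      expect_identical(ref$n_commissions, com)
      expect_identical(ref$n_mistakes, om + com)
    }
  }
})

test_that("the mean/SD RT features use correct GO presses only", {
  plan <- rep(list(list(omit = 0, rt = 420, commission = TRUE)), 23)
  s <- build_stream(plan)
  f <- participant_features(s, fixed_sart_threshold(4))
  expect_equal(f$mean_rt_ms, 420)  # the 350 ms commission RTs are ignored
  expect_equal(f$sd_rt_ms, 0)
})
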