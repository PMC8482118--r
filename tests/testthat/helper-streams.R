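# Hand-construct a raw SART stream from a per-cycle plan.
#
# plan: a list with one element per cycle (recycled to 23), each a list
# with fields
#   omit      - number of GO digits left unpressed (0-8, taken in digit order)
#   commission- press the NO-GO digit (default FALSE)
#   rt        - RT assigned to each correct GO press (default 400)
#   lost_rt   - number of GO presses whose RT is recorded as missing
build_stream <- function(plan, participant_id = "T1") {
  plan <- rep(plan, length.out = 23)
  digits <- rep(1:9, 23)
  pressed <- logical(207)
  rt <- rep(NA_real_, 207)
  go_pos <- c(1, 2, 4, 5, 6, 7, 8, 9)
  for (k in 1:23) {
    p <- plan[[k]]
    omit <- p$omit %||% 0
    comm <- isTRUE(p$commission)
    rtv <- p$rt %||% 400
    lost <- p$lost_rt %||% 0
    base <- (k - 1) * 9
    press_go <- go_pos[seq_len(8 - omit) + omit]  # omit the first `omit`
    pressed[base + press_go] <- TRUE
    rt[base + press_go] <- rtv
    if (lost > 0) rt[base + press_go[seq_len(lost)]] <- NA_real_
    if (comm) {
      pressed[base + 3] <- TRUE
      rt[base + 3] <- 350  # commission RT; must never be used downstream
    }
  }
  tibble::tibble(
    participant_id = participant_id,
    presentation_index = 1:207,
    cycle_index = rep(1:23, each = 9),
    digit = digits,
    pressed = pressed,
    rt_ms = rt
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a cycle plan with no mistakes
perfect <- function() list(omit = 0)

# config for an error-free administration
errorfree_config <- function(n = 1L) {
  sart_config(
    n_participants = n,
    baseline_go_error_rate = 0, baseline_nogo_error_rate = 0,
    age_error_slope = 0, deficit_error_slope = 0,
    lapse_cycle_rate = 0, deep_lapse_cycle_rate = 0,
    missing_stream_rate = 0, seed = 1
  )
}

# a small cohort shared across tests (generated once per test run)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sart_config(n_participants = 120, seed = 99))
    cache
  }
})

# a mid-sized merged analysis table shared across tests
analysis_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(sart_config(n_participants = 900, seed = 55))
      fx <- extract_sart_features(co$streams,
                                  threshold = fixed_sart_threshold(4))
      cache <<- suppressMessages(merge_waves(co$cohort, fx$features))
    }
    cache
  }
})
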