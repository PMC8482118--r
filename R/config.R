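#' Configuration for the synthetic SART cohort generator
#'
#' Builds the full parameter set that drives [simulate_cohort()]. The
#' defaults are calibrated so that a cohort of a few thousand synthetic
#' participants reproduces the descriptive moments of a large
#' community-dwelling ageing cohort: mean total SART mistakes near 11
#' (SD near 12), mean reaction time near 385 ms (between-participant SD
#' near 95 ms), within-task RT SD near 72 ms, TUG near 8.6 s, usual gait
#' speed near 136 cm/s, MMSE near 28.7 — and, crucially, a spot-size
#' distribution whose mean-plus-2-SD rule implies a bad-performance
#' threshold of 4 mistakes per cycle (see [sart_threshold()]).
#'
#' @details
#' The error model has three components, all acting on the log-odds scale
#' through age (per year above 60) and a standard-normal latent attention
#' deficit:
#'
#' * **Baseline errors** — independent GO omissions
#'   (`baseline_go_error_rate`) and NO-GO commissions
#'   (`baseline_nogo_error_rate`).
#' * **Attention bursts** — with per-cycle probability `lapse_cycle_rate`,
#'   a run of 2-3 consecutive GO digits (lengths drawn from
#'   `burst_length_probs`) goes unanswered: the short "zoning out" episodes
#'   that produce 2-3-mistake cycles.
#' * **Deep lapses** — with per-cycle probability `deep_lapse_cycle_rate`,
#'   task engagement breaks down for the whole cycle: each GO digit is
#'   omitted with probability `lapse_error_rate` and the NO-GO digit is
#'   pressed with probability `deep_lapse_commission_rate`. These rare,
#'   severe cycles carry most of the upper tail of the per-cycle mistake
#'   distribution and hence dominate the 2-SD spot-size cutoff.
#'
#' Reaction times of presses are lognormal with a participant-level
#' location (`rt_log_mean` plus a normal deviate scaled by `rt_log_sd`),
#' within-task log-SD `rt_within_log_sd`, and an additive age trend of
#' `rt_age_slope` ms per year above 60.
#'
#' `outcome_coefficients` is a named list (one element per binary outcome:
#' `tug_decline`, `ugs_decline`, `new_faller`, `mmse_decline`), each a
#' named vector of log-odds terms `intercept`, `bad_performances` (per bad
#' cycle, where a bad cycle holds at least `bad_threshold` mistakes) and
#' `age` (per year above 60). The defaults use the odds ratios reported for
#' fully adjusted models on real cohort data (e.g. 1.29 per bad performance
#' for TUG decline), so end-to-end synthetic runs resemble the published
#' effect magnitudes.
#'
#' `wave_interval_effects` gives the mean wave-1-to-wave-3 TUG increment in
#' seconds for participants with only good performances (`good`, default
#' 0.871) and with at least one bad performance (`bad`, default 1.512).
#'
#' @param n_participants Number of participants (>= 1).
#' @param age_range Two-element numeric, youngest and oldest age in years.
#' @param age_shape,age_scale Shape and scale of the gamma distribution of
#'   `age - age_range[1]`; the defaults put most of the cohort between 50
#'   and 65 with a tail to the low 90s (mean near 61.8, SD near 8.3).
#' @param baseline_go_error_rate Per-GO-presentation omission probability
#'   at age 60 and zero deficit.
#' @param baseline_nogo_error_rate Per-NO-GO commission probability at age
#'   60 and zero deficit.
#' @param age_error_slope Per-year log-odds increment on the baseline error
#'   rates.
#' @param deficit_error_slope Log-odds loading of the latent attention
#'   deficit on the baseline error rates.
#' @param lapse_cycle_rate Per-cycle probability of an attention burst at
#'   age 60 and zero deficit.
#' @param burst_length_probs Named numeric vector of burst-length
#'   probabilities; names are run lengths in consecutive GO digits.
#' @param deep_lapse_cycle_rate Per-cycle probability of a deep lapse at
#'   age 60 and zero deficit.
#' @param lapse_error_rate Per-GO omission probability inside a deep-lapse
#'   cycle; must exceed both baseline rates.
#' @param deep_lapse_commission_rate NO-GO press probability inside a
#'   deep-lapse cycle.
#' @param lapse_age_slope,lapse_deficit_slope Per-year and per-deficit-SD
#'   log-odds increments on both lapse rates; the large deficit loading
#'   concentrates bad performances in a small subgroup, reproducing the
#'   heavy-tailed, strongly non-normal feature distributions seen in real
#'   cohorts.
#' @param rt_log_mean Log of the median correct-press RT (log-ms) at age 60.
#' @param rt_log_sd Between-participant SD of the lognormal RT location.
#' @param rt_within_log_sd Median within-participant log-scale RT SD.
#' @param rt_within_dispersion Log-scale spread of the per-participant
#'   within-task RT SD around `rt_within_log_sd`; keeps the mean-RT and
#'   SD-RT features only moderately correlated, as observed in real
#'   cohorts.
#' @param rt_age_slope Additive RT trend, ms per year above 60.
#' @param missing_stream_rate Probability that a participant's stream is
#'   additionally degraded (1-2 cycles with either no presses at all or a
#'   press whose RT was lost), emulating the small unplottable-data
#'   fraction of real recordings.
#' @param attrition_rate Probability that a participant misses wave 3
#'   (all wave-3 fields missing), at age 60; rises mildly with age.
#' @param wave_interval_effects Named numeric (`good`, `bad`): mean TUG
#'   increment in seconds between waves by bad-performance group.
#' @param outcome_coefficients Named list of log-odds coefficient vectors,
#'   see Details.
#' @param size_power Exponent linking a spot's drawn area to its cycle
#'   error fraction; 2 (the default) makes the marker *radius* linear in
#'   the percentage of errors. See [sart_threshold()].
#' @param bad_threshold Mistake count (per cycle) at or above which the
#'   generator's outcome links treat a cycle as a bad performance.
#' @param seed Optional integer; when set, [simulate_cohort()] seeds the
#'   RNG with it so cohorts are exactly reproducible.
#'
#' @return A validated list of class `"sart_config"`.
#' @seealso [simulate_cohort()], [sart_threshold()]
#' @export
#' @examples
#' cfg <- sart_config(n_participants = 200, seed = 1)
#' cfg$protocol$n_presentations
sart_config <- function(n_participants = 5000L,
                        age_range = c(50, 93),
                        age_shape = 2.0,
                        age_scale = 5.9,
                        baseline_go_error_rate = 0.024,
                        baseline_nogo_error_rate = 0.13,
                        age_error_slope = 0.02,
                        deficit_error_slope = 0.35,
                        lapse_cycle_rate = 0.003,
                        burst_length_probs = c(`2` = 0.35, `3` = 0.65),
                        deep_lapse_cycle_rate = 0.00062,
                        lapse_error_rate = 0.78,
                        deep_lapse_commission_rate = 0.5,
                        lapse_age_slope = 0.095,
                        lapse_deficit_slope = 2.3,
                        rt_log_mean = log(368),
                        rt_log_sd = 0.225,
                        rt_within_log_sd = 0.185,
                        rt_within_dispersion = 0.4,
                        rt_age_slope = 1.0,
                        missing_stream_rate = 0.008,
                        attrition_rate = 0.2,
                        wave_interval_effects = c(good = 0.871, bad = 1.512),
                        outcome_coefficients = default_outcome_coefficients(),
                        size_power = 2,
                        bad_threshold = 4L,
                        seed = NULL) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    age_range = as.numeric(age_range),
    age_shape = age_shape,
    age_scale = age_scale,
    baseline_go_error_rate = baseline_go_error_rate,
    baseline_nogo_error_rate = baseline_nogo_error_rate,
    age_error_slope = age_error_slope,
    deficit_error_slope = deficit_error_slope,
    lapse_cycle_rate = lapse_cycle_rate,
    burst_length_probs = burst_length_probs,
    deep_lapse_cycle_rate = deep_lapse_cycle_rate,
    lapse_error_rate = lapse_error_rate,
    deep_lapse_commission_rate = deep_lapse_commission_rate,
    lapse_age_slope = lapse_age_slope,
    lapse_deficit_slope = lapse_deficit_slope,
    rt_log_mean = rt_log_mean,
    rt_log_sd = rt_log_sd,
    rt_within_log_sd = rt_within_log_sd,
    rt_within_dispersion = rt_within_dispersion,
    rt_age_slope = rt_age_slope,
    missing_stream_rate = missing_stream_rate,
    attrition_rate = attrition_rate,
    wave_interval_effects = wave_interval_effects,
    outcome_coefficients = outcome_coefficients,
    size_power = size_power,
    bad_threshold = as.integer(bad_threshold),
    seed = if (!is.null(seed)) as.integer(seed),
    protocol = sart_protocol()
  )
  class(cfg) <- "sart_config"
  validate_sart_config(cfg)
  cfg
}

#' Default outcome log-odds coefficients
#'
#' One vector per binary outcome; `intercept` sets the marginal event rate,
#' `bad_performances` the per-bad-cycle effect, `age` the per-year effect
#' (age centred at 60). Effects default to the odds ratios reported in
#' fully adjusted models on real cohort data.
#'
#' @return Named list of named numeric vectors.
#' @export
default_outcome_coefficients <- function() {
  list(
    tug_decline  = c(intercept = -3.0,  bad_performances = log(1.29),
                     age = 0.055),
    ugs_decline  = c(intercept = -3.3,  bad_performances = log(1.15),
                     age = 0.075),
    new_faller   = c(intercept = -1.8,  bad_performances = log(1.114),
                     age = log(1.02)),
    mmse_decline = c(intercept = -2.35, bad_performances = log(1.067),
                     age = log(1.044))
  )
}

#' Validate a generator configuration
#'
#' Checks the structural invariants of a [sart_config()] object: all rates
#' are probabilities in \[0, 1\], at least one participant, a non-degenerate
#' age range, burst-length probabilities that sum to one, deep-lapse
#' severity above the baseline rates, and complete outcome coefficient sets.
#'
#' @param config A `"sart_config"` object.
#' @return `config`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_sart_config <- function(config) {
  stopifnot(inherits(config, "sart_config"))
  bad <- function(field, msg) {
    stop("invalid configuration: `", field, "` ", msg, call. = FALSE)
  }
  if (is.na(config$n_participants) || config$n_participants < 1L)
    bad("n_participants", "must be at least 1")
  if (length(config$age_range) != 2L ||
      config$age_range[1] >= config$age_range[2])
    bad("age_range", "must satisfy low < high")
  probs <- c("baseline_go_error_rate", "baseline_nogo_error_rate",
             "lapse_cycle_rate", "deep_lapse_cycle_rate",
             "lapse_error_rate", "deep_lapse_commission_rate",
             "missing_stream_rate", "attrition_rate")
  for (f in probs) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      bad(f, "must be a probability in [0, 1]")
  }
  if (config$lapse_error_rate <= config$baseline_go_error_rate ||
      config$lapse_error_rate <= config$baseline_nogo_error_rate)
    bad("lapse_error_rate", "must exceed both baseline error rates")
  blp <- config$burst_length_probs
  if (is.null(names(blp)) || any(is.na(suppressWarnings(as.integer(names(blp))))) ||
      any(blp < 0) || abs(sum(blp) - 1) > 1e-8)
    bad("burst_length_probs", "must be named by run length and sum to 1")
  if (max(as.integer(names(blp))) > config$protocol$n_go_per_cycle)
    bad("burst_length_probs", "runs cannot exceed the GO digits in a cycle")
  if (!is.numeric(config$size_power) || config$size_power <= 0)
    bad("size_power", "must be positive")
  need <- c("tug_decline", "ugs_decline", "new_faller", "mmse_decline")
  oc <- config$outcome_coefficients
  if (!all(need %in% names(oc)))
    bad("outcome_coefficients", paste(
      "must contain", paste(setdiff(need, names(oc)), collapse = ", ")))
  for (nm in need) {
    if (!all(c("intercept", "bad_performances") %in% names(oc[[nm]])))
      bad("outcome_coefficients",
          paste0("[['", nm, "']] needs `intercept` and `bad_performances`"))
  }
  if (!all(c("good", "bad") %in% names(config$wave_interval_effects)))
    bad("wave_interval_effects", "must have elements `good` and `bad`")
  invisible(config)
}

#' @export
print.sart_config <- function(x, ...) {
  cat("<sart_config>\n")
  cat("  participants:", x$n_participants,
      " ages", x$age_range[1], "-", x$age_range[2], "\n")
  cat("  baseline error rates: GO", x$baseline_go_error_rate,
      "/ NO-GO", x$baseline_nogo_error_rate, "\n")
  cat("  lapse rates: burst", x$lapse_cycle_rate,
      "/ deep", x$deep_lapse_cycle_rate,
      "(severity", x$lapse_error_rate, ")\n")
  cat("  RT: exp(", round(x$rt_log_mean, 3), ") ms, age slope",
      x$rt_age_slope, "ms/yr\n")
  cat("  outcome ORs per bad performance:",
      paste(sprintf("%s=%.3f", names(x$outcome_coefficients),
                    vapply(x$outcome_coefficients,
                           function(b) exp(b[["bad_performances"]]), 0)),
            collapse = ", "), "\n")
  invisible(x)
}
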