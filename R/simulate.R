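#' Draw participant profiles for a synthetic cohort
#'
#' Samples demographic and covariate profiles: age (gamma-shaped, most of
#' the cohort between 50 and 65), sex, education, a standard-normal latent
#' attention deficit that drives both SART errors and outcome risk, and the
#' wave-1 covariates used by the adjusted regression models (HADS-A
#' anxiety, CES-D depression, antihypertensive use, diabetes, smoking,
#' self-reported drinking problem, IPAQ physical activity).
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param config A [sart_config()] object.
#' @param n Number of profiles; defaults to `config$n_participants`.
#' @return A tibble, one row per participant.
#' @export
simulate_profiles <- function(config, n = config$n_participants) {
  validate_sart_config(config)
  age <- config$age_range[1] +
    stats::rgamma(n, shape = config$age_shape, scale = config$age_scale)
  age <- pmin(age, config$age_range[2])
  z <- stats::rnorm(n)
  ac <- age - 62

  p_primary <- stats::plogis(stats::qlogis(0.212) + 0.040 * ac)
  p_third <- stats::plogis(stats::qlogis(0.369) - 0.030 * ac)
  u <- stats::runif(n)
  education <- ifelse(u < p_primary, "primary/none",
               ifelse(u < p_primary + pmax(0, 1 - p_primary - p_third),
                      "secondary", "third/higher"))

  p_low_ipaq <- stats::plogis(stats::qlogis(0.275) + 0.035 * ac)
  u2 <- stats::runif(n)
  ipaq <- ifelse(u2 < p_low_ipaq, "low",
          ifelse(u2 < p_low_ipaq + 0.52 * (1 - p_low_ipaq), "medium", "high"))

  tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    age_w1 = age,
    sex = sample(c("female", "male"), n, TRUE, c(0.546, 0.454)),
    education = factor(education,
                       c("primary/none", "secondary", "third/higher")),
    latent_attention_deficit = z,
    anxiety = pmin(21, stats::rnbinom(n, mu = 5.4 * exp(0.10 * z),
                                      size = 3.2)),
    depression = pmin(60, stats::rnbinom(n, mu = 5.6 * exp(0.12 * z),
                                         size = 0.9)),
    antihypertensives = stats::runif(n) <
      stats::plogis(stats::qlogis(0.13) + 0.07 * ac),
    diabetes = stats::runif(n) <
      stats::plogis(stats::qlogis(0.06) + 0.03 * ac),
    smoking = factor(sample(c("never", "past", "current"), n, TRUE,
                            c(0.459, 0.393, 0.148)),
                     c("never", "past", "current")),
    drinking_problem = factor(sample(c("no", "yes", "dont_know"), n, TRUE,
                                     c(0.781, 0.128, 0.091)),
                              c("no", "yes", "dont_know")),
    ipaq = factor(ipaq, c("low", "medium", "high"))
  )
}

# Vectorised press/RT generation for all profiles at once.
# Returns pressed (n x 207 logical), rt (n x 207, NA where no press or RT
# lost) plus the per-participant rates actually used.
simulate_press_matrices <- function(profiles, config) {
  n <- nrow(profiles)
  age <- profiles$age_w1
  z <- profiles$latent_attention_deficit
  ac <- age - 60
  pr <- config$protocol

  c_i <- stats::plogis(stats::qlogis(config$baseline_nogo_error_rate) +
                         config$age_error_slope * ac +
                         config$deficit_error_slope * z)
  o_i <- stats::plogis(stats::qlogis(config$baseline_go_error_rate) +
                         config$age_error_slope * ac +
                         config$deficit_error_slope * z)
  pb_i <- stats::plogis(stats::qlogis(config$lapse_cycle_rate) +
                          config$lapse_age_slope * ac +
                          config$lapse_deficit_slope * z)
  pd_i <- stats::plogis(stats::qlogis(config$deep_lapse_cycle_rate) +
                          config$lapse_age_slope * ac +
                          config$lapse_deficit_slope * z)

  digit <- protocol_digits()
  go_cols <- protocol_go_idx()
  nogo_cols <- protocol_nogo_idx()
  cyc_of_col <- protocol_cycles()
  n_go <- pr$n_go

  # cycle types: deep lapse beats burst when both are drawn
  u <- matrix(stats::runif(n * pr$n_cycles), n, pr$n_cycles)
  deep <- u < pd_i
  burst <- !deep & (u < pd_i + pb_i)

  pressed <- matrix(FALSE, n, pr$n_presentations)
  omit_p <- matrix(o_i, n, n_go)
  omit_p[deep[, cyc_of_col[go_cols]]] <- config$lapse_error_rate
  pressed[, go_cols] <- matrix(stats::runif(n * n_go), n, n_go) >= omit_p
  comm_p <- matrix(c_i, n, pr$n_cycles)
  comm_p[deep] <- config$deep_lapse_commission_rate
  pressed[, nogo_cols] <-
    matrix(stats::runif(n * pr$n_cycles), n, pr$n_cycles) < comm_p

  # attention bursts: a run of consecutive GO digits goes unanswered
  bi <- which(burst, arr.ind = TRUE)
  if (nrow(bi) > 0) {
    lens <- as.integer(names(config$burst_length_probs))
    L <- sample(lens, nrow(bi), TRUE, config$burst_length_probs)
    s <- 1L + floor(stats::runif(nrow(bi)) * (pr$n_go_per_cycle - L + 1L))
    go_in_cycle <- protocol_go_in_cycle()
    reps <- rep(seq_len(nrow(bi)), L)
    pos <- sequence(L) - 1L + s[reps]
    col <- (bi[reps, 2L] - 1L) * pr$n_digits + go_in_cycle[pos]
    pressed[cbind(bi[reps, 1L], col)] <- FALSE
  }

  # reaction times for every press (commission RTs are generated but never
  # used downstream: only correct GO actions feed the cycle metrics)
  lmu <- config$rt_log_mean + config$rt_log_sd * stats::rnorm(n)
  disp <- config$rt_within_dispersion
  sig_i <- config$rt_within_log_sd *
    exp(disp * stats::rnorm(n) - disp^2 / 2)
  rt <- matrix(NA_real_, n, pr$n_presentations)
  idx <- which(pressed)
  row_i <- ((idx - 1L) %% n) + 1L
  rt[idx] <- exp(lmu[row_i] + sig_i[row_i] * stats::rnorm(length(idx))) +
    config$rt_age_slope * (age[row_i] - 60)

  # recording degradation: a few participants lose presses or RTs
  n_miss <- stats::rbinom(1L, n, config$missing_stream_rate)
  if (n_miss > 0) {
    who <- sample.int(n, n_miss)
    for (i in who) {
      k <- sample.int(pr$n_cycles, sample(1:2, 1L))
      in_k <- cyc_of_col %in% k
      if (stats::runif(1) < 0.25) {     # no presses at all in those cycles
        pressed[i, in_k] <- FALSE
        rt[i, in_k] <- NA_real_
      } else {                          # pressed, but the RT was lost
        cand <- which(in_k & digit != 3L & pressed[i, ])
        if (length(cand) > 0) rt[i, sample(cand, 1L)] <- NA_real_
      }
    }
  }

  list(pressed = pressed, rt = rt)
}

# matrices -> long tibble in the raw-stream dialect
streams_long <- function(profiles, mats) {
  n <- nrow(profiles)
  pr <- sart_protocol()
  tibble::tibble(
    participant_id = rep(profiles$participant_id, each = pr$n_presentations),
    presentation_index = rep.int(seq_len(pr$n_presentations), n),
    cycle_index = rep.int(protocol_cycles(), n),
    digit = rep.int(protocol_digits(), n),
    pressed = as.vector(t(mats$pressed)),
    rt_ms = as.vector(t(mats$rt))
  )
}

#' Simulate one participant's raw SART stream
#'
#' Generates a single 207-presentation stream for the given profile under
#' the configured error and reaction-time model. Uses the current RNG
#' state: call `set.seed()` first for a reproducible stream.
#'
#' @param profile A one-row tibble (or named list) with at least `age_w1`
#'   and `latent_attention_deficit`; typically a row of
#'   [simulate_profiles()]. A missing `participant_id` defaults to `"P1"`.
#' @param config A [sart_config()] object.
#' @return A tibble with 207 rows and columns `participant_id`,
#'   `presentation_index`, `cycle_index`, `digit`, `pressed`, `rt_ms`.
#' @export
#' @examples
#' cfg <- sart_config(n_participants = 1)
#' set.seed(42)
#' stream <- simulate_sart_stream(
#'   list(participant_id = "P1", age_w1 = 60, latent_attention_deficit = 0),
#'   cfg)
#' nrow(stream) # 207
simulate_sart_stream <- function(profile, config) {
  validate_sart_config(config)
  profile <- tibble::as_tibble(as.list(profile)[
    intersect(names(profile),
              c("participant_id", "age_w1", "latent_attention_deficit"))])
  if (!"participant_id" %in% names(profile))
    profile$participant_id <- "P1"
  stopifnot(nrow(profile) == 1L,
            !is.null(profile$age_w1),
            !is.null(profile$latent_attention_deficit))
  mats <- simulate_press_matrices(profile, config)
  streams_long(profile, mats)
}

#' Simulate a full synthetic cohort: SART streams plus two-wave records
#'
#' Generates participant profiles, one raw SART stream each, and a
#' two-wave clinical table (TUG, usual gait speed, falls, MMSE at waves 1
#' and 3, plus all wave-1 covariates). The four binary decline outcomes
#' are drawn from logistic links on the participant's bad-performance
#' count (cycles with at least `config$bad_threshold` mistakes) and age,
#' with the coefficients in `config$outcome_coefficients`; wave-3
#' continuous values are then generated consistently with the drawn flags,
#' using the configured per-group TUG wave increments. A configurable
#' fraction of participants miss wave 3 entirely (attrition).
#'
#' @param config A [sart_config()] object. When `config$seed` is set the
#'   RNG is seeded first, making the cohort exactly reproducible.
#' @return An object of class `"sart_cohort"`: a list with `streams` (long
#'   raw-stream tibble), `cohort` (one row per participant) and `profiles`
#'   (including the latent deficit and the generator's own
#'   `bad_performances` count, for parameter-recovery studies).
#' @export
#' @examples
#' cohort <- simulate_cohort(sart_config(n_participants = 50, seed = 7))
#' nrow(cohort$cohort)
simulate_cohort <- function(config) {
  validate_sart_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_participants
  profiles <- simulate_profiles(config)
  mats <- simulate_press_matrices(profiles, config)
  streams <- streams_long(profiles, mats)

  # the generator's own bad-performance count, for the outcome links
  mist <- cycle_mistake_matrix(mats)
  bad <- as.integer(rowSums(mist >= config$bad_threshold))
  profiles$bad_performances <- bad

  age <- profiles$age_w1
  ac <- age - 60
  oc <- config$outcome_coefficients
  draw <- function(nm) {
    b <- oc[[nm]]
    eta <- b[["intercept"]] + b[["bad_performances"]] * bad +
      (if ("age" %in% names(b)) b[["age"]] * ac else 0)
    stats::runif(n) < stats::plogis(eta)
  }

  tug_w1 <- exp(stats::rnorm(n, log(8.2), 0.20)) + 0.05 * (age - 62)
  ugs_w1 <- 165 - 0.45 * age + stats::rnorm(n, 0, 19)
  faller1 <- stats::runif(n) < 0.2
  falls_w1 <- ifelse(faller1,
                     1L + stats::rnbinom(n, mu = 0.8, size = 0.4), 0L)
  mmse_w1 <- 30L - pmin(30L, stats::rnbinom(
    n, mu = pmax(0.2, 1.1 + 0.02 * ac), size = 1.5))

  slope <- unname(config$wave_interval_effects[
    ifelse(bad > 0, "bad", "good")])

  # TUG: decline flag drawn only where baseline is unimpaired; wave-3
  # values regenerated consistently with the flag and the group increment
  tug_flag <- draw("tug_decline") & tug_w1 < 12
  tug_w3 <- tug_w1 + slope + stats::rnorm(n, 0, 0.9)
  low <- tug_w1 < 12
  tug_w3[low & !tug_flag] <- pmin(tug_w3[low & !tug_flag], 11.9)
  tug_w3[tug_flag] <- 12 + stats::rexp(sum(tug_flag), 1 / 0.8)
  tug_w3 <- pmax(tug_w3, 4)

  ugs_flag <- draw("ugs_decline") & ugs_w1 >= 100
  ugs_w3 <- ugs_w1 - 2 + stats::rnorm(n, 0, 8)
  hi <- ugs_w1 >= 100
  ugs_w3[hi & !ugs_flag] <- pmax(ugs_w3[hi & !ugs_flag], 100.1)
  ugs_w3[ugs_flag] <- 100 - stats::rexp(sum(ugs_flag), 1 / 6)
  ugs_w3 <- pmax(ugs_w3, 30)

  fall_flag <- draw("new_faller") & falls_w1 == 0L
  falls_w3 <- integer(n)
  falls_w3[fall_flag] <- 1L +
    stats::rnbinom(sum(fall_flag), mu = 0.6, size = 0.5)
  rep_faller <- falls_w1 > 0L & stats::runif(n) < 0.35
  falls_w3[rep_faller] <- 1L +
    stats::rnbinom(sum(rep_faller), mu = 0.8, size = 0.4)

  mmse_flag <- draw("mmse_decline")
  mmse_w3 <- pmin(30L, pmax(0L, mmse_w1 +
    sample(c(-1L, 0L, 1L), n, TRUE, c(0.25, 0.5, 0.25))))
  mmse_w3[mmse_flag] <- pmax(0L, mmse_w1[mmse_flag] - 2L -
    stats::rpois(sum(mmse_flag), 0.8))

  attrited <- stats::runif(n) <
    stats::plogis(stats::qlogis(max(config$attrition_rate, 1e-12)) +
                    0.03 * ac)
  if (config$attrition_rate == 0) attrited <- rep(FALSE, n)
  for (v in c("tug_w3", "ugs_w3", "mmse_w3")) {
    x <- get(v); x[attrited] <- NA; assign(v, x)
  }
  falls_w3[attrited] <- NA_integer_

  cohort <- tibble::tibble(
    participant_id = profiles$participant_id,
    tug_w1 = tug_w1, tug_w3 = tug_w3,
    ugs_w1 = ugs_w1, ugs_w3 = ugs_w3,
    falls_w1 = falls_w1, falls_w3 = falls_w3,
    mmse_w1 = mmse_w1, mmse_w3 = mmse_w3,
    age = age,
    sex = profiles$sex,
    education = profiles$education,
    anxiety = profiles$anxiety,
    depression = profiles$depression,
    antihypertensives = profiles$antihypertensives,
    diabetes = profiles$diabetes,
    smoking = profiles$smoking,
    drinking_problem = profiles$drinking_problem,
    ipaq = profiles$ipaq
  )

  structure(list(streams = streams, cohort = cohort, profiles = profiles),
            class = "sart_cohort")
}

# per-cycle mistake counts straight from the press matrices (generator
# internal; the analysis path recomputes them from the long table)
cycle_mistake_matrix <- function(mats) {
  pr <- sart_protocol()
  go_cols <- protocol_go_idx()
  nogo_cols <- protocol_nogo_idx()
  agg <- matrix(0, pr$n_presentations, pr$n_cycles)
  agg[cbind(seq_len(pr$n_presentations), protocol_cycles())] <- 1
  omit <- (!mats$pressed)[, go_cols, drop = FALSE] %*%
    agg[go_cols, , drop = FALSE]
  comm <- mats$pressed[, nogo_cols, drop = FALSE]
  omit + comm
}

#' @export
print.sart_cohort <- function(x, ...) {
  cat("<sart_cohort> ", nrow(x$cohort), " participants, ",
      nrow(x$streams), " presentations\n", sep = "")
  cat("  wave-3 follow-up available for ",
      sum(!is.na(x$cohort$tug_w3) | !is.na(x$cohort$mmse_w3)),
      " participants\n", sep = "")
  invisible(x)
}
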