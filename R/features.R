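#' Per-cycle SART metrics
#'
#' Decomposes each 9-digit cycle into its mistake counts and the mean
#' reaction time of the correct actions in that cycle. A *mistake* is
#' either an omission (a GO digit with no press, up to 8 per cycle) or a
#' commission (the NO-GO digit pressed, at most 1 per cycle). The mean RT
#' averages correct GO presses only; commission RTs never enter any
#' downstream quantity. A cycle is *plottable* when it has at least one
#' correct action and none of its presses lost their RT — otherwise no
#' average RT exists and the cycle cannot receive a spot in the
#' visualisation.
#'
#' The maximum mistake count of a plottable cycle is 8: nine mistakes
#' would require omitting every GO digit and pressing the NO-GO, leaving
#' no correct action to anchor the spot.
#'
#' @param streams Long raw-stream tibble (one or more participants), as
#'   returned by [read_sart_csv()] or [simulate_cohort()].
#' @param validate Re-check the protocol invariants first (default TRUE;
#'   skipped internally when the table is already validated).
#' @return A tibble with 23 rows per participant: `participant_id`,
#'   `cycle_index`, `n_omissions`, `n_commissions`, `n_mistakes`,
#'   `n_correct_actions`, `error_fraction` (`n_mistakes / 9`),
#'   `mean_rt_correct_ms` (NA when not plottable) and `plottable`.
#' @export
#' @examples
#' cfg <- sart_config(n_participants = 2, seed = 3)
#' cm <- cycle_metrics(simulate_cohort(cfg)$streams)
#' table(cm$n_mistakes)
cycle_metrics <- function(streams, validate = TRUE) {
  if (validate) validate_sart_streams(streams)
  pr <- sart_protocol()
  np <- pr$n_presentations
  n <- nrow(streams) %/% np
  if (n == 0) stop("no streams supplied", call. = FALSE)
  pid <- streams$participant_id[seq(1L, nrow(streams), by = np)]

  pressed <- matrix(streams$pressed, nrow = np)
  rt <- matrix(streams$rt_ms, nrow = np)
  go <- protocol_digits() != 3L
  cyc <- protocol_cycles()

  omit <- rowsum((!pressed) * go, cyc)                      # 23 x n
  comm <- pressed[!go, , drop = FALSE] * 1L                 # 23 x n
  correct <- rowsum((pressed & !is.na(rt)) * go, cyc)
  lost <- rowsum((pressed & is.na(rt)) * go, cyc)
  rt0 <- rt
  rt0[!pressed | is.na(rt) | !go] <- 0
  rtsum <- rowsum(rt0, cyc)
  mistakes <- omit + comm
  mean_rt <- ifelse(correct >= 1 & lost == 0, rtsum / correct, NA_real_)

  tibble::tibble(
    participant_id = rep(pid, each = pr$n_cycles),
    cycle_index = rep.int(seq_len(pr$n_cycles), n),
    n_omissions = as.integer(omit),
    n_commissions = as.integer(comm),
    n_mistakes = as.integer(mistakes),
    n_correct_actions = as.integer(correct),
    error_fraction = as.vector(mistakes) / pr$n_digits,
    mean_rt_correct_ms = as.vector(mean_rt),
    plottable = as.vector(correct >= 1 & lost == 0)
  )
}

#' The 2-SD spot-size rule for bad performances
#'
#' Computes the bad-performance cutoff from the spot sizes of all
#' plottable cycles pooled across participants. A cycle's drawn spot has
#' area proportional to `error_fraction ^ size_power`; with the default
#' `size_power = 2` the marker *radius* grows linearly with the
#' percentage of errors, which is how scatter-marker sizes are specified
#' in most plotting systems. The cutoff is `mean(size) + n_sd * sd(size)`
#' and the integer `mistake_threshold` is the smallest mistake count k
#' (1-9) whose spot size strictly exceeds the cutoff; 10 encodes "no
#' cycle can exceed the cutoff". Cycles with no computable mean RT are
#' excluded from the cutoff computation, exactly as they are absent from
#' the graph.
#'
#' @param metrics Cycle-metrics tibble from [cycle_metrics()], pooled over
#'   all participants of the analysed dataset.
#' @param n_sd Number of SDs above the mean (default 2).
#' @param size_power Exponent of the size mapping (default 2; 1 applies
#'   the rule directly on the error-fraction scale).
#' @return An object of class `"sart_threshold"`: a list with
#'   `size_mean`, `size_sd`, `cutoff`, `mistake_threshold`, `size_power`,
#'   `n_big_spots` (plottable cycles at or above the threshold) and
#'   `n_participants_with_big_spots`.
#' @seealso [fixed_sart_threshold()] to pin a known threshold for
#'   cross-dataset comparability.
#' @export
sart_threshold <- function(metrics, n_sd = 2, size_power = 2) {
  pl <- metrics[metrics$plottable, , drop = FALSE]
  if (nrow(pl) < 2)
    stop("insufficient data: need at least 2 plottable cycles",
         call. = FALSE)
  size <- pl$error_fraction^size_power
  size_mean <- mean(size)
  size_sd <- stats::sd(size)
  cutoff <- size_mean + n_sd * size_sd
  pr <- sart_protocol()
  k <- ((1:pr$n_digits) / pr$n_digits)^size_power
  exceeds <- which(k > cutoff)
  mistake_threshold <- if (length(exceeds) > 0) min(exceeds) else
    pr$n_digits + 1L
  big <- pl$n_mistakes >= mistake_threshold
  structure(
    list(size_mean = size_mean, size_sd = size_sd, cutoff = cutoff,
         n_sd = n_sd, size_power = size_power,
         mistake_threshold = as.integer(mistake_threshold),
         n_big_spots = sum(big),
         n_participants_with_big_spots =
           length(unique(pl$participant_id[big]))),
    class = "sart_threshold")
}

#' Pin a known bad-performance threshold
#'
#' Builds a `"sart_threshold"` object with a fixed integer mistake
#' threshold instead of recomputing the 2-SD rule, e.g. to apply the
#' reference value of 4 mistakes per cycle to a new dataset.
#'
#' @param mistake_threshold Integer in 1-10 (10 = nothing is bad).
#' @param size_power Size-mapping exponent carried along for plotting.
#' @return A `"sart_threshold"` object with NA summary statistics.
#' @export
fixed_sart_threshold <- function(mistake_threshold, size_power = 2) {
  stopifnot(mistake_threshold >= 1, mistake_threshold <= 10)
  structure(
    list(size_mean = NA_real_, size_sd = NA_real_, cutoff = NA_real_,
         n_sd = NA_real_, size_power = size_power,
         mistake_threshold = as.integer(mistake_threshold),
         n_big_spots = NA_integer_,
         n_participants_with_big_spots = NA_integer_),
    class = "sart_threshold")
}

#' @export
print.sart_threshold <- function(x, ...) {
  cat("<sart_threshold> bad performance = >=", x$mistake_threshold,
      "mistakes per cycle\n")
  if (!is.na(x$cutoff))
    cat(sprintf("  spot size mean %.4f, sd %.4f, cutoff %.4f (power %g)\n",
                x$size_mean, x$size_sd, x$cutoff, x$size_power))
  if (!is.na(x$n_big_spots))
    cat("  ", x$n_big_spots, " big spots across ",
        x$n_participants_with_big_spots, " participants\n", sep = "")
  invisible(x)
}

#' Participant-level SART features
#'
#' Reduces each participant's stream to the five features used by the
#' regression suite: the traditional mean and SD of the reaction time over
#' all correct actions of the whole task, the total mistake count, the
#' number of *bad performances* (cycles at or above the mistake
#' threshold), and the number of mistakes accrued in the remaining "good"
#' cycles. By default an unplottable cycle (one that receives no spot)
#' still counts as a bad performance when its mistakes reach the
#' threshold — a cycle with no presses at all is plainly a bad
#' performance even though it cannot be drawn; set
#' `bad_perf_plottable_only = TRUE` for the stricter visualisation-bound
#' reading.
#'
#' The identity `total_mistakes = mistakes_in_good_performances + sum of
#' mistakes over bad cycles` holds exactly under either convention.
#'
#' @param streams Long raw-stream tibble.
#' @param threshold A `"sart_threshold"` object.
#' @param metrics Optional precomputed [cycle_metrics()] for `streams`.
#' @param bad_perf_plottable_only Count only plottable cycles as bad
#'   performances (default FALSE).
#' @return A tibble, one row per participant: `participant_id`,
#'   `mean_rt_ms`, `sd_rt_ms`, `total_mistakes`, `bad_performances`,
#'   `mistakes_in_good_performances`, `n_unplottable_cycles`.
#' @export
participant_features <- function(streams, threshold,
                                 metrics = NULL,
                                 bad_perf_plottable_only = FALSE) {
  stopifnot(inherits(threshold, "sart_threshold"))
  if (is.null(metrics)) metrics <- cycle_metrics(streams)
  thr <- threshold$mistake_threshold

  is_bad <- metrics$n_mistakes >= thr
  if (bad_perf_plottable_only) is_bad <- is_bad & metrics$plottable
  g <- factor(metrics$participant_id, unique(metrics$participant_id))
  total <- rowsum(metrics$n_mistakes, g)
  bad_n <- rowsum(as.integer(is_bad), g)
  bad_m <- rowsum(metrics$n_mistakes * is_bad, g)
  unpl <- rowsum(as.integer(!metrics$plottable), g)

  pr <- sart_protocol()
  np <- pr$n_presentations
  pid <- streams$participant_id[seq(1L, nrow(streams), by = np)]
  pressed <- matrix(streams$pressed, nrow = np)
  rt <- matrix(streams$rt_ms, nrow = np)
  ok <- pressed & !is.na(rt) & (protocol_digits() != 3L)
  rt0 <- ifelse(ok, rt, 0)
  cnt <- colSums(ok)
  s1 <- colSums(rt0)
  s2 <- colSums(rt0^2)
  mean_rt <- ifelse(cnt >= 1, s1 / cnt, NA_real_)
  var_rt <- ifelse(cnt >= 2, (s2 - cnt * mean_rt^2) / (cnt - 1), NA_real_)

  tibble::tibble(
    participant_id = levels(g),
    mean_rt_ms = unname(mean_rt[match(levels(g), pid)]),
    sd_rt_ms = unname(sqrt(pmax(var_rt, 0))[match(levels(g), pid)]),
    total_mistakes = as.integer(total),
    bad_performances = as.integer(bad_n),
    mistakes_in_good_performances = as.integer(total - bad_m),
    n_unplottable_cycles = as.integer(unpl)
  )
}

#' One-call feature extraction for a whole dataset
#'
#' Convenience wrapper running [cycle_metrics()], [sart_threshold()] (or a
#' supplied pinned threshold) and [participant_features()] on a raw-stream
#' table.
#'
#' @param streams Long raw-stream tibble.
#' @param threshold Optional `"sart_threshold"`; recomputed from the data
#'   when NULL.
#' @param ... Passed to [sart_threshold()] / [participant_features()].
#' @inheritParams participant_features
#' @return A list with `metrics`, `threshold` and `features`.
#' @export
extract_sart_features <- function(streams, threshold = NULL,
                                  bad_perf_plottable_only = FALSE, ...) {
  metrics <- cycle_metrics(streams)
  if (is.null(threshold)) threshold <- sart_threshold(metrics, ...)
  features <- participant_features(
    streams, threshold, metrics = metrics,
    bad_perf_plottable_only = bad_perf_plottable_only)
  list(metrics = metrics, threshold = threshold, features = features)
}

#' Write participant features and the threshold record
#'
#' @param features Participant-features tibble.
#' @param path CSV path for the features.
#' @param threshold Optional `"sart_threshold"`; when given, a JSON record
#'   (`size_mean`, `size_sd`, `cutoff`, `mistake_threshold`) is written
#'   next to `path` with extension `.threshold.json`.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path, threshold = NULL) {
  readr::write_csv(features, path, na = "")
  if (!is.null(threshold)) {
    jpath <- sub("\\.csv$", "", path)
    jsonlite::write_json(
      threshold[c("size_mean", "size_sd", "cutoff", "mistake_threshold")],
      paste0(jpath, ".threshold.json"), auto_unbox = TRUE, digits = NA,
      null = "null", na = "null")
  }
  invisible(path)
}
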