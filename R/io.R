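#' Write raw SART streams to CSV
#'
#' Writes the long-format raw dialect: one row per presentation, columns
#' `participant_id`, `presentation_index` (1-207), `cycle_index` (1-23),
#' `digit` (1-9), `pressed` (0/1) and `rt_ms` (empty when there was no
#' press, or the press's RT was not recorded).
#'
#' @param streams Long tibble of raw streams, e.g. from
#'   [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sart_csv <- function(streams, path) {
  out <- streams
  out$pressed <- as.integer(out$pressed)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read and validate raw SART streams
#'
#' Parses a raw-stream CSV (the dialect written by [write_sart_csv()]) and
#' validates the protocol invariants for every participant: exactly 207
#' presentations indexed 1-207, digits following the repeating 1-9 cycle,
#' and a reaction time only where a press occurred. A recorded press with
#' a missing `rt_ms` is legal (a lost RT) and is handled downstream by the
#' plottability rules.
#'
#' @param path CSV file path.
#' @return A validated long tibble sorted by participant and presentation
#'   index; zero rows (with a warning) for an empty file.
#' @export
read_sart_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  need <- c("participant_id", "presentation_index", "cycle_index",
            "digit", "pressed", "rt_ms")
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               col_types = readr::cols(
                                 .default = readr::col_character())))
  missing_cols <- setdiff(need, hdr)
  if (length(missing_cols) > 0)
    stop("raw SART file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  streams <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      presentation_index = readr::col_integer(),
      cycle_index = readr::col_integer(),
      digit = readr::col_integer(),
      pressed = readr::col_integer(),
      rt_ms = readr::col_double()
    ),
    na = c("", "NA"), progress = FALSE
  )
  if (nrow(streams) == 0) {
    warning("empty raw SART file: ", path, call. = FALSE)
    streams$pressed <- logical(0)
    return(streams)
  }
  streams$pressed <- streams$pressed != 0L
  streams <- dplyr::arrange(streams, .data$participant_id,
                            .data$presentation_index)
  validate_sart_streams(streams)
}

#' Validate a long table of SART streams
#'
#' @param streams Long tibble with the raw-stream columns, sorted by
#'   participant and presentation index.
#' @return `streams`, invisibly returned visibly for chaining; errors name
#'   the offending participant and presentation.
#' @export
validate_sart_streams <- function(streams) {
  pr <- sart_protocol()
  counts <- table(streams$participant_id)
  off <- counts != pr$n_presentations
  if (any(off))
    stop("participant ", names(counts)[off][1], " has ",
         counts[off][1], " presentations; expected ",
         pr$n_presentations, call. = FALSE)
  n <- length(counts)
  idx <- matrix(streams$presentation_index, nrow = pr$n_presentations)
  if (!all(idx == seq_len(pr$n_presentations)))
    stop("presentation_index must run 1..", pr$n_presentations,
         " for every participant", call. = FALSE)
  dg <- matrix(streams$digit, nrow = pr$n_presentations)
  bad_dig <- which(dg != protocol_digits())
  if (length(bad_dig) > 0) {
    i <- bad_dig[1]
    stop("digit sequence violates the repeating 1-9 cycle for participant ",
         streams$participant_id[i], " at presentation ",
         streams$presentation_index[i], call. = FALSE)
  }
  cy <- matrix(streams$cycle_index, nrow = pr$n_presentations)
  if (!all(cy == protocol_cycles()))
    stop("cycle_index inconsistent with presentation order", call. = FALSE)
  if (any(!streams$pressed & !is.na(streams$rt_ms)))
    stop("rt_ms recorded without a press for participant ",
         streams$participant_id[which(!streams$pressed &
                                        !is.na(streams$rt_ms))[1]],
         call. = FALSE)
  if (any(streams$rt_ms <= 0, na.rm = TRUE))
    stop("rt_ms must be positive", call. = FALSE)
  streams
}

#' Write a two-wave cohort table to CSV
#'
#' @param cohort Cohort tibble (one row per participant), e.g. from
#'   [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Read a two-wave cohort table
#'
#' Restores the factor codings the regression models rely on (education,
#' smoking, drinking problem and IPAQ reference levels).
#'
#' @param path CSV file path.
#' @return A cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cohort <- readr::read_csv(path, na = c("", "NA"), progress = FALSE,
                            show_col_types = FALSE)
  relevel_map <- list(
    education = c("primary/none", "secondary", "third/higher"),
    smoking = c("never", "past", "current"),
    drinking_problem = c("no", "yes", "dont_know"),
    ipaq = c("low", "medium", "high")
  )
  for (nm in names(relevel_map)) {
    if (nm %in% names(cohort))
      cohort[[nm]] <- factor(cohort[[nm]], relevel_map[[nm]])
  }
  for (nm in c("antihypertensives", "diabetes")) {
    if (nm %in% names(cohort)) cohort[[nm]] <- as.logical(cohort[[nm]])
  }
  cohort
}
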