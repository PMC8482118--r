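#' Derive the four binary decline outcomes
#'
#' Adds the dichotomous clinical outcomes to a two-wave cohort table:
#'
#' * `tug_decline` — 1 if TUG was under 12 s at wave 1 and at least 12 s
#'   at wave 3 (transition into clinically significant mobility
#'   impairment), 0 otherwise.
#' * `ugs_decline` — 1 if usual gait speed was at least 100 cm/s at wave 1
#'   and below 100 cm/s at wave 3.
#' * `new_faller` — 1 if the participant reported no falls in the year
#'   before wave 1 and at least one fall in the year before wave 3.
#' * `mmse_decline` — 1 if the MMSE score dropped by at least 2 points
#'   between waves.
#'
#' A flag is NA exactly when one of its required inputs is missing.
#' Whether participants already impaired at baseline (e.g. TUG >= 12 s at
#' wave 1) are kept as 0 or excluded from the regressions is decided later,
#' in [covariate_design()].
#'
#' @param cohort Cohort tibble with the two-wave columns.
#' @return `cohort` with the four outcome columns appended (integer 0/1/NA).
#' @export
#' @examples
#' derive_outcomes(tibble::tibble(
#'   participant_id = "x", tug_w1 = 11.9, tug_w3 = 12,
#'   ugs_w1 = 120, ugs_w3 = 95, falls_w1 = 0L, falls_w3 = 2L,
#'   mmse_w1 = 28L, mmse_w3 = 26L))
derive_outcomes <- function(cohort) {
  flag <- function(x) as.integer(x)
  dplyr::mutate(
    cohort,
    tug_decline = flag(.data$tug_w1 < 12 & .data$tug_w3 >= 12),
    ugs_decline = flag(.data$ugs_w1 >= 100 & .data$ugs_w3 < 100),
    new_faller = flag(.data$falls_w1 == 0 & .data$falls_w3 > 0),
    mmse_decline = flag((.data$mmse_w1 - .data$mmse_w3) >= 2)
  )
}

#' Merge SART features with the two-wave cohort
#'
#' Inner-joins participant features onto the cohort table and restricts to
#' participants examined at both waves (at least one wave-3 measurement
#' present), mirroring the construction of a merged longitudinal sample
#' from a larger baseline cohort. Row counts before and after are
#' reported via `message()`.
#'
#' @param cohort Cohort tibble (one row per participant).
#' @param features Participant-features tibble from
#'   [participant_features()].
#' @return The merged analysis tibble with derived outcome columns
#'   appended.
#' @export
merge_waves <- function(cohort, features) {
  if (anyDuplicated(cohort$participant_id))
    stop("duplicate participant_id in cohort table", call. = FALSE)
  if (anyDuplicated(features$participant_id))
    stop("duplicate participant_id in features table", call. = FALSE)
  merged <- dplyr::inner_join(cohort, features, by = "participant_id")
  if (nrow(merged) == 0) {
    warning("no participants shared between cohort and features",
            call. = FALSE)
    return(derive_outcomes(merged))
  }
  w3 <- c("tug_w3", "ugs_w3", "falls_w3", "mmse_w3")
  w3 <- intersect(w3, names(merged))
  has_w3 <- rowSums(!is.na(merged[w3])) > 0
  message("merged longitudinal sample: ", sum(has_w3), " of ",
          nrow(cohort), " baseline participants")
  derive_outcomes(merged[has_w3, , drop = FALSE])
}

model_terms <- function(model_id, predictor) {
  base <- c("1" = "", "2" = "mean_rt_ms + sd_rt_ms",
            "3" = "mean_rt_ms + sd_rt_ms + age + sex + education",
            "4" = paste("mean_rt_ms + sd_rt_ms + age + sex + education",
                        "+ anxiety + depression + antihypertensives",
                        "+ diabetes + smoking + drinking_problem + ipaq"),
            "4a" = paste("mean_rt_ms + sd_rt_ms + age + sex + education",
                         "+ anxiety + depression + antihypertensives",
                         "+ diabetes + smoking + drinking_problem + ipaq",
                         "+ ugs_w1"))
  if (!model_id %in% names(base))
    stop("unknown model_id: ", model_id, "; use 1, 2, 3, 4 or 4a",
         call. = FALSE)
  rhs <- if (base[[model_id]] == "") predictor else
    paste(predictor, "+", base[[model_id]])
  rhs
}

#' Build the design for one logistic model of the suite
#'
#' Assembles the outcome vector and model matrix for one of the five
#' incrementally adjusted logistic models: model 1 holds just the chosen
#' SART predictor; model 2 adds mean and SD of RT; model 3 adds age, sex
#' and education; model 4 adds the psychological and physical covariates
#' (anxiety, depression, antihypertensives, diabetes, smoking, drinking
#' problem, IPAQ); model 4a additionally adjusts for baseline gait speed.
#' Exactly one of the three candidate predictors enters any model.
#'
#' Categorical covariates are dummy-coded against their clinical reference
#' levels (education: primary/none; smoking: never; IPAQ: low; drinking
#' problem: no, with a separate indicator for "don't know"). Rows with any
#' missing required value are dropped (complete-case analysis).
#'
#' By default the analysis population for each outcome excludes
#' participants already past the cut-off at baseline (TUG >= 12 s for TUG
#' decline, gait speed < 100 cm/s for UGS decline, fallers at wave 1 for
#' new falls), because each outcome is defined as a transition from a
#' normal baseline; `baseline_impaired = "keep"` retains them coded 0.
#'
#' @param table Analysis tibble from [merge_waves()].
#' @param model_id One of `"1"`, `"2"`, `"3"`, `"4"`, `"4a"` (numeric
#'   accepted).
#' @param predictor One of `"bad_performances"`, `"total_mistakes"`,
#'   `"mistakes_in_good_performances"`.
#' @param outcome One of `"tug_decline"`, `"ugs_decline"`, `"new_faller"`,
#'   `"mmse_decline"`.
#' @param baseline_impaired `"drop"` (default) or `"keep"`.
#' @return An object of class `"sart_design"`: a list with the model
#'   matrix `x` (intercept included), outcome vector `y`, the fitted
#'   `formula`, the complete-case `data`, and the identifiers.
#' @export
covariate_design <- function(table, model_id, predictor, outcome,
                             baseline_impaired = c("drop", "keep")) {
  model_id <- as.character(model_id)
  baseline_impaired <- match.arg(baseline_impaired)
  predictors <- c("bad_performances", "total_mistakes",
                  "mistakes_in_good_performances")
  if (!predictor %in% predictors)
    stop("predictor must be one of: ",
         paste(predictors, collapse = ", "), call. = FALSE)
  outcomes <- c("tug_decline", "ugs_decline", "new_faller", "mmse_decline")
  if (!outcome %in% outcomes)
    stop("outcome must be one of: ",
         paste(outcomes, collapse = ", "), call. = FALSE)

  if (baseline_impaired == "drop") {
    keep <- switch(outcome,
      tug_decline = table$tug_w1 < 12,
      ugs_decline = table$ugs_w1 >= 100,
      new_faller = table$falls_w1 == 0,
      mmse_decline = rep(TRUE, nrow(table)))
    table <- table[!is.na(keep) & keep, , drop = FALSE]
  }

  rhs <- model_terms(model_id, predictor)
  form <- stats::as.formula(paste(outcome, "~", rhs))
  vars <- all.vars(form)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols) > 0)
    stop("analysis table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- table[stats::complete.cases(table[vars]), vars, drop = FALSE]
  y <- data[[outcome]]
  if (length(unique(y)) < 2)
    stop("degenerate outcome: `", outcome,
         "` takes a single value in the analysis rows", call. = FALSE)
  x <- stats::model.matrix(form, data = data)
  structure(
    list(x = x, y = y, formula = form, data = data,
         model_id = model_id, predictor = predictor, outcome = outcome,
         n_used = nrow(data)),
    class = "sart_design")
}

#' @export
print.sart_design <- function(x, ...) {
  cat("<sart_design> model ", x$model_id, ": ",
      deparse(x$formula), "\n  n = ", x$n_used, ", ",
      ncol(x$x), " columns\n", sep = "")
  invisible(x)
}
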