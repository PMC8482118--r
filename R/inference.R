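#' Normality screen for candidate predictors
#'
#' Applies the two normality tests used to justify nonparametric methods
#' for the SART features: a Kolmogorov-Smirnov test in its
#' Lilliefors form (parameters estimated from the data, the convention of
#' standard statistical GUIs) and the Shapiro-Wilk test. The Shapiro-Wilk
#' implementation is limited to 5000 observations; longer vectors are
#' deterministically thinned to an evenly spaced subsample of 5000.
#'
#' @param values Numeric vector, length at least 3.
#' @param alpha Significance level for the combined flag (default 0.05).
#' @return A list with `ks_p`, `shapiro_p` and `normal` (TRUE only when
#'   both tests fail to reject).
#' @export
normality_screen <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3)
    stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate input: constant vector", call. = FALSE)
  ks_p <- nortest::lillie.test(values)$p.value
  sw_values <- if (length(values) > 5000)
    values[round(seq(1, length(values), length.out = 5000))] else values
  shapiro_p <- stats::shapiro.test(sw_values)$p.value
  list(ks_p = ks_p, shapiro_p = shapiro_p,
       normal = ks_p >= alpha && shapiro_p >= alpha)
}

#' Wilcoxon signed-rank test between waves
#'
#' Compares paired measurements of the same participants at two waves.
#' Zero differences are discarded (the signed-rank convention) and the
#' asymptotic normal approximation with continuity correction is used
#' when more than 25 non-zero pairs remain, the exact distribution
#' otherwise.
#'
#' @param w1,w3 Numeric vectors of equal length; pairs with a missing
#'   value in either wave are dropped.
#' @return A list with `statistic` (V), `p_value`, `n_pairs` (non-missing)
#'   and `method`.
#' @export
paired_wilcoxon <- function(w1, w3) {
  stopifnot(length(w1) == length(w3))
  ok <- !is.na(w1) & !is.na(w3)
  w1 <- w1[ok]; w3 <- w3[ok]
  d <- w3 - w1
  nz <- sum(d != 0)
  if (nz == 0)
    stop("degenerate comparison: all paired differences are zero",
         call. = FALSE)
  exact <- nz <= 25 && !any(duplicated(abs(d[d != 0])))
  res <- suppressWarnings(
    stats::wilcox.test(w3, w1, paired = TRUE, exact = exact,
                       correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n_pairs = length(d), method = res$method)
}

#' Mann-Whitney U test between independent groups
#'
#' Two-sided rank-sum comparison of two independent samples, exact for
#' small tie-free samples and asymptotic with continuity correction
#' otherwise. The returned statistic is the U count for `group_a`.
#'
#' @param group_a,group_b Non-empty numeric vectors; missing values are
#'   dropped.
#' @return A list with `statistic` (U for `group_a`), `p_value`, the two
#'   group sizes and `method`.
#' @export
mannwhitney_u <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  exact <- length(group_a) <= 25 && length(group_b) <= 25 &&
    !any(duplicated(c(group_a, group_b)))
  res <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n_a = length(group_a), n_b = length(group_b),
       method = res$method)
}

#' Fit one binary logistic regression of the suite
#'
#' Maximum-likelihood logistic fit of a [covariate_design()] object, with
#' Wald inference per term: the odds ratio `exp(estimate)`, its 95%
#' confidence interval `exp(estimate +/- z * SE)`, and a two-sided Wald
#' p-value. Rank-deficient designs and (quasi-)separated fits raise
#' errors naming the offending column rather than returning silently
#' unstable estimates.
#'
#' @param design A `"sart_design"` object.
#' @param conf_level Confidence level for the Wald intervals (default
#'   0.95).
#' @param rho_limit Collinearity pass limit forwarded to
#'   [collinearity_check()] for adjusted models.
#' @return An object of class `"sart_logit"`: a list with `terms` (tibble:
#'   `term`, `estimate`, `or`, `ci_low`, `ci_high`, `p_value`),
#'   `model_id`, `predictor`, `outcome`, `n_used`, `converged`,
#'   `loglik`, `max_abs_rho` (NA for model 1) and `conf_level`.
#' @export
fit_logistic <- function(design, conf_level = 0.95, rho_limit = 0.7) {
  stopifnot(inherits(design, "sart_design"))
  fit <- stats::glm(design$formula, data = design$data,
                    family = stats::binomial())
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: column(s) ",
         paste(bad, collapse = ", "), " dropped by the fit",
         call. = FALSE)
  }
  co <- summary(fit)$coefficients
  big <- abs(co[, "Estimate"]) > 15
  mu <- stats::fitted(fit)
  if (any(big) && (any(mu > 1 - 1e-8) || any(mu < 1e-8)))
    stop("separation detected: term(s) ",
         paste(rownames(co)[big], collapse = ", "),
         " perfectly predict the outcome", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- unname(co[, "Estimate"])
  se <- unname(co[, "Std. Error"])
  terms <- tibble::tibble(
    term = rownames(co),
    estimate = est,
    se = se,
    or = exp(est),
    ci_low = exp(est - z * se),
    ci_high = exp(est + z * se),
    p_value = unname(co[, "Pr(>|z|)"])
  )
  max_rho <- if (ncol(design$x) > 2)
    collinearity_check(design, limit = rho_limit)$max_abs_rho else NA_real_
  structure(
    list(terms = terms, model_id = design$model_id,
         predictor = design$predictor, outcome = design$outcome,
         n_used = design$n_used, converged = fit$converged,
         loglik = as.numeric(stats::logLik(fit)),
         max_abs_rho = max_rho, conf_level = conf_level),
    class = "sart_logit")
}

#' @export
print.sart_logit <- function(x, ...) {
  cat("<sart_logit> model ", x$model_id, ", outcome ", x$outcome,
      ", n = ", x$n_used, "\n", sep = "")
  t <- x$terms[x$terms$term != "(Intercept)", ]
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-34s OR %.3f (%.3f-%.3f) p=%.4g\n", t$term[i],
                t$or[i], t$ci_low[i], t$ci_high[i], t$p_value[i]))
  invisible(x)
}

#' Pairwise Spearman collinearity screen
#'
#' Computes all pairwise Spearman rank correlations among the non-intercept
#' columns of a design matrix. The screen passes when the largest absolute
#' off-diagonal correlation stays below the limit.
#'
#' @param design A `"sart_design"` object (or a numeric matrix whose
#'   columns are the independents).
#' @param limit Pass limit on `max |rho|` (default 0.7).
#' @return A list with the correlation matrix `rho`, `max_abs_rho`,
#'   `limit` and the logical `pass`.
#' @export
collinearity_check <- function(design, limit = 0.7) {
  x <- if (inherits(design, "sart_design")) design$x else as.matrix(design)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  if (ncol(x) < 2)
    stop("need at least 2 non-intercept columns", call. = FALSE)
  rho <- stats::cor(x, method = "spearman")
  off <- abs(rho)
  diag(off) <- 0
  max_abs <- max(off)
  list(rho = rho, max_abs_rho = max_abs, limit = limit,
       pass = max_abs < limit)
}

#' Run the five-model logistic suite for one predictor and outcome
#'
#' Fits models 1, 2, 3, 4 and 4a for a single SART predictor and a single
#' binary outcome, recording per-model sample sizes and, for the adjusted
#' models, the collinearity screen.
#'
#' @inheritParams covariate_design
#' @param models Character vector of model ids (default all five).
#' @param ... Passed to [fit_logistic()].
#' @return A named list of `"sart_logit"` objects, class
#'   `"sart_model_suite"`.
#' @export
run_model_suite <- function(table, predictor, outcome,
                            models = c("1", "2", "3", "4", "4a"),
                            baseline_impaired = "drop", ...) {
  fits <- lapply(models, function(m) {
    design <- covariate_design(table, m, predictor, outcome,
                               baseline_impaired = baseline_impaired)
    fit_logistic(design, ...)
  })
  names(fits) <- models
  class(fits) <- "sart_model_suite"
  fits
}

#' @export
print.sart_model_suite <- function(x, ...) {
  f1 <- x[[1]]
  cat("<sart_model_suite> predictor ", f1$predictor, ", outcome ",
      f1$outcome, "\n", sep = "")
  for (m in names(x)) {
    t <- x[[m]]$terms
    row <- t[t$term == f1$predictor, ]
    cat(sprintf("  model %-3s OR %.3f (%.3f-%.3f) p=%.4g  n=%d\n", m,
                row$or, row$ci_low, row$ci_high, row$p_value,
                x[[m]]$n_used))
  }
  invisible(x)
}

#' Compare the three candidate SART predictors for one outcome
#'
#' Runs the full model suite for `bad_performances`, `total_mistakes` and
#' `mistakes_in_good_performances`, and tabulates the predictor's odds
#' ratio, confidence interval and p-value per model side by side, with
#' pairwise confidence-interval overlap flags (non-empty interval
#' intersection) and significance flags at `alpha`. Also reports the mean
#' TUG change per wave interval for the two bad-performance groups (none
#' versus at least one), the two-point analogue of a per-group slope.
#'
#' @inheritParams run_model_suite
#' @param alpha Significance level for the flags (default 0.05).
#' @return A list of class `"sart_predictor_comparison"`: `table` (one row
#'   per model x predictor), `overlap` (one row per model with pairwise
#'   CI-overlap flags), `group_slopes` (named numeric: `good`, `bad`) and
#'   `suites` (the underlying fits).
#' @export
compare_predictors <- function(table, outcome,
                               models = c("1", "2", "3", "4", "4a"),
                               baseline_impaired = "drop",
                               alpha = 0.05, ...) {
  predictors <- c("bad_performances", "total_mistakes",
                  "mistakes_in_good_performances")
  suites <- lapply(predictors, function(p)
    run_model_suite(table, p, outcome, models = models,
                    baseline_impaired = baseline_impaired, ...))
  names(suites) <- predictors

  rows <- dplyr::bind_rows(lapply(predictors, function(p) {
    dplyr::bind_rows(lapply(models, function(m) {
      f <- suites[[p]][[m]]
      t <- f$terms[f$terms$term == p, ]
      tibble::tibble(outcome = outcome, model_id = m, predictor = p,
                     or = unname(t$or), ci_low = unname(t$ci_low),
                     ci_high = unname(t$ci_high),
                     p_value = unname(t$p_value), n_used = f$n_used,
                     significant = unname(t$p_value) < alpha)
    }))
  }))

  overlaps <- function(a, b) a["ci_low"] <= b["ci_high"] &&
    b["ci_low"] <= a["ci_high"]
  overlap <- dplyr::bind_rows(lapply(models, function(m) {
    r <- rows[rows$model_id == m, ]
    get <- function(p) {
      x <- r[r$predictor == p, ]
      c(ci_low = x$ci_low, ci_high = x$ci_high)
    }
    tibble::tibble(
      outcome = outcome, model_id = m,
      bad_vs_total = overlaps(get(predictors[1]), get(predictors[2])),
      bad_vs_good = overlaps(get(predictors[1]), get(predictors[3])),
      total_vs_good = overlaps(get(predictors[2]), get(predictors[3])))
  }))

  gs <- c(good = NA_real_, bad = NA_real_)
  if (all(c("tug_w1", "tug_w3", "bad_performances") %in% names(table))) {
    d <- table$tug_w3 - table$tug_w1
    grp <- table$bad_performances > 0
    gs <- c(good = mean(d[!grp], na.rm = TRUE),
            bad = mean(d[grp], na.rm = TRUE))
  }

  structure(list(table = rows, overlap = overlap, group_slopes = gs,
                 suites = suites, alpha = alpha),
            class = "sart_predictor_comparison")
}

#' @export
print.sart_predictor_comparison <- function(x, ...) {
  cat("<sart_predictor_comparison> outcome ", x$table$outcome[1], "\n",
      sep = "")
  for (m in unique(x$table$model_id)) {
    cat(" model", m, "\n")
    r <- x$table[x$table$model_id == m, ]
    for (i in seq_len(nrow(r)))
      cat(sprintf("   %-30s OR %.3f (%.3f-%.3f) p=%.4g%s\n",
                  r$predictor[i], r$or[i], r$ci_low[i], r$ci_high[i],
                  r$p_value[i], ifelse(r$significant[i], " *", "")))
  }
  if (!anyNA(x$group_slopes))
    cat(sprintf(" TUG change per wave: good-only %.3f s, >=1 bad %.3f s\n",
                x$group_slopes["good"], x$group_slopes["bad"]))
  invisible(x)
}
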